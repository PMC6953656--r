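#' Parameters for Markov clustering of coordinate distances
#'
#' Defaults follow the mcl program: inflation 2, pre-inflation 1 (a no-op),
#' expansion 2. The graph-construction parameters are package choices:
#' points within `edge_radius` degrees are connected with Gaussian-kernel
#' weight `exp(-d^2 / (2 * kernel_bandwidth^2))` and unit self-loops; the
#' radius bounds cluster extent so continental-scale sites cannot form.
#'
#' @param inflation element-wise power applied after each expansion (> 1).
#' @param pre_inflation one-off element-wise power applied before iterating
#'   (> 0).
#' @param expansion matrix-power order (integer >= 2).
#' @param edge_radius neighbourhood radius in degrees.
#' @param kernel_bandwidth Gaussian kernel bandwidth in degrees.
#' @param prune_threshold entries below this are zeroed after inflation.
#' @param max_iter iteration cap.
#' @param convergence_tol max absolute change declaring convergence.
#' @return list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 2, pre_inflation = 1, expansion = 2L,
                       edge_radius = 0.5, kernel_bandwidth = 0.1,
                       prune_threshold = 1e-5, max_iter = 100L,
                       convergence_tol = 1e-6) {
  stopifnot(inflation > 1, pre_inflation > 0, expansion >= 2,
            edge_radius > 0, kernel_bandwidth > 0,
            prune_threshold > 0, prune_threshold < 1,
            max_iter >= 1, convergence_tol > 0)
  structure(list(inflation = inflation, pre_inflation = pre_inflation,
                 expansion = as.integer(expansion),
                 edge_radius = edge_radius,
                 kernel_bandwidth = kernel_bandwidth,
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

# All point pairs within `radius`, found by spatial bucketing so no dense
# n x n distance matrix is ever formed. Returns data.frame(i, j, d), i < j.
radius_pairs <- function(xy, radius) {
  n <- nrow(xy)
  bx <- floor(xy[, 1] / radius)
  by <- floor(xy[, 2] / radius)
  key <- paste(bx, by)
  bucket <- split(seq_len(n), key)
  coord <- do.call(rbind, strsplit(names(bucket), " "))
  bxu <- as.numeric(coord[, 1]); byu <- as.numeric(coord[, 2])
  lookup <- stats::setNames(seq_along(bucket), names(bucket))
  out_i <- vector("list", length(bucket))
  r2 <- radius^2
  for (b in seq_along(bucket)) {
    ids <- bucket[[b]]
    # own bucket plus the 4 lexicographically larger neighbours (each
    # unordered bucket pair visited once)
    nb_keys <- c(paste(bxu[b] + 1, byu[b] - 1), paste(bxu[b] + 1, byu[b]),
                 paste(bxu[b] + 1, byu[b] + 1), paste(bxu[b], byu[b] + 1))
    cand <- unlist(bucket[lookup[nb_keys[nb_keys %in% names(lookup)]]],
                   use.names = FALSE)
    res <- list()
    if (length(ids) > 1) {
      prs <- utils::combn(ids, 2)
      d2 <- (xy[prs[1, ], 1] - xy[prs[2, ], 1])^2 +
            (xy[prs[1, ], 2] - xy[prs[2, ], 2])^2
      keep <- d2 <= r2
      res[[1]] <- data.frame(i = prs[1, keep], j = prs[2, keep],
                             d = sqrt(d2[keep]))
    }
    if (length(cand)) {
      ii <- rep(ids, each = length(cand))
      jj <- rep(cand, times = length(ids))
      d2 <- (xy[ii, 1] - xy[jj, 1])^2 + (xy[ii, 2] - xy[jj, 2])^2
      keep <- d2 <= r2
      res[[2]] <- data.frame(i = pmin(ii[keep], jj[keep]),
                             j = pmax(ii[keep], jj[keep]),
                             d = sqrt(d2[keep]))
    }
    out_i[[b]] <- do.call(rbind, res)
  }
  out <- do.call(rbind, out_i)
  if (is.null(out)) out <- data.frame(i = integer(), j = integer(),
                                      d = numeric())
  out
}

# Core Markov Cluster algorithm on a column-stochastic sparse matrix.
# Returns cluster membership (integer per node) plus a per-iteration trace of
# column-sum deviation from 1 (the stochasticity invariant).
mcl_cluster <- function(M, params) {
  normalize <- function(A) {
    cs <- Matrix::colSums(A)
    if (any(cs == 0)) stop("column with no mass in MCL matrix")
    A %*% Matrix::Diagonal(x = 1 / cs)
  }
  inflate <- function(A, power) {
    A <- as(A, "CsparseMatrix")
    A@x <- A@x^power
    normalize(A)
  }
  prune <- function(A, thr) {
    A <- as(A, "CsparseMatrix")
    A@x[A@x < thr] <- 0
    Matrix::drop0(A)
  }
  col_dev <- function(A) max(abs(Matrix::colSums(A) - 1))

  M <- normalize(M)
  trace <- col_dev(M)
  if (params$pre_inflation != 1) {
    M <- inflate(M, params$pre_inflation)
    trace <- c(trace, col_dev(M))
  }
  for (it in seq_len(params$max_iter)) {
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- inflate(E, params$inflation)
    E <- normalize(prune(E, params$prune_threshold))
    trace <- c(trace, col_dev(E))
    delta <- max(abs(E - M))
    M <- E
    if (delta < params$convergence_tol) break
  }
  # clusters = connected components of the limit matrix's support
  A <- (M != 0) | Matrix::t(M != 0)
  memb <- sparse_components(A)
  list(membership = memb, iterations = it, delta = delta,
       stochastic_dev = trace)
}

# Connected components of a symmetric sparse adjacency pattern (BFS).
sparse_components <- function(A) {
  A <- as(as(A, "nMatrix"), "CsparseMatrix")
  n <- ncol(A)
  ptr <- A@p; idx <- A@i
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- idx[(ptr[v] + 1L):ptr[v + 1L]] + 1L
      if (ptr[v + 1L] == ptr[v]) nb <- integer()
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Group occurrence coordinates into sample sites by Markov clustering
#'
#' Builds a Gaussian-kernel similarity graph over the (optionally snapped and
#' deduplicated) coordinates and runs the Markov Cluster algorithm:
#' column-normalize, one-off pre-inflation, then alternate expansion (matrix
#' power), inflation (element-wise power + renormalization) and pruning until
#' the matrix converges; clusters are the connected components of the limit
#' matrix's support, so every point is assigned.
#'
#' @param coords matrix or data frame of record coordinates (lon/lat columns,
#'   Darwin Core aliases accepted).
#' @param params an [mcl_params()] object.
#' @param snap optional grid size in degrees; coordinates are snapped to this
#'   grid before clustering (records inherit their snapped node's cluster).
#'   Exact duplicates are always collapsed to one graph node. Snapping keeps
#'   the graph small on dense record sets.
#' @return object of class `site_assignment`: list with `site_id` (integer
#'   per input record, contiguous from 0), `sites` (data frame: `site`,
#'   `lat`, `lon` centroid means, `n_records`), and `mcl` diagnostics
#'   (iterations, final delta, per-iteration column-sum deviation).
#' @export
cluster_sites <- function(coords, params = mcl_params(), snap = NULL) {
  p <- as_lonlat(coords)
  if (any(!is.finite(p))) stop("non-finite coordinates")
  key_xy <- if (is.null(snap)) p else round(p / snap) * snap
  key <- paste(key_xy[, 1], key_xy[, 2])
  node_of <- match(key, unique(key))
  nodes <- key_xy[!duplicated(key), , drop = FALSE]
  n <- nrow(nodes)

  if (n == 1L) {
    memb <- 1L
    diag_info <- list(iterations = 0L, delta = 0, stochastic_dev = 0)
  } else {
    ed <- radius_pairs(nodes, params$edge_radius)
    w <- exp(-ed$d^2 / (2 * params$kernel_bandwidth^2))
    M <- Matrix::sparseMatrix(i = c(ed$i, ed$j, seq_len(n)),
                              j = c(ed$j, ed$i, seq_len(n)),
                              x = c(w, w, rep(1, n)), dims = c(n, n))
    res <- mcl_cluster(M, params)
    memb <- res$membership
    diag_info <- res[c("iterations", "delta", "stochastic_dev")]
  }

  memb_rec <- memb[node_of]
  site_id <- as.integer(factor(memb_rec, levels = unique(memb_rec))) - 1L
  sites <- data.frame(
    site = sort(unique(site_id)),
    lat = as.vector(tapply(p[, "lat"], site_id, mean)),
    lon = as.vector(tapply(p[, "lon"], site_id, mean)),
    n_records = as.vector(table(site_id)))
  structure(list(site_id = site_id, sites = sites, mcl = diag_info),
            class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("site_assignment: %d records in %d sites (MCL: %d iterations, max col-sum dev %.2g)\n",
              length(x$site_id), nrow(x$sites), x$mcl$iterations,
              max(x$mcl$stochastic_dev)))
  invisible(x)
}
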