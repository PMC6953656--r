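#' Horn-Morisita dissimilarity between two abundance vectors
#'
#' The abundance-based Horn modification of the Morisita overlap index,
#' valid for non-integer abundances. With totals `X = sum(x)`, `Y = sum(y)`:
#' \deqn{d = 1 - \frac{2 \sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\, X\, Y}}
#' The overlap term is the probability that two individuals, one drawn from
#' each site, are conspecific, normalized by the within-site analogues. The
#' index is symmetric and invariant to proportional rescaling of either
#' vector. The classical Morisita index (integer counts, Simpson-index
#' denominators with the `n(n-1)` correction) is available via
#' `variant = "morisita"`.
#'
#' @param x,y non-negative abundance vectors of equal length with positive
#'   totals.
#' @param variant `"horn"` (default) or `"morisita"`.
#' @return dissimilarity in `[0, 1]`.
#' @export
horn_morisita <- function(x, y, variant = c("horn", "morisita")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (any(x < 0) || any(y < 0)) stop("negative abundance")
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) stop("undefined for empty community")
  cross <- sum(x * y)
  if (variant == "horn") {
    dx <- sum(x^2) / X^2
    dy <- sum(y^2) / Y^2
    sim <- 2 * cross / ((dx + dy) * X * Y)
  } else {
    if (any(x != round(x)) || any(y != round(y)))
      stop("classical Morisita requires integer counts")
    lx <- sum(x * (x - 1)) / (X * (X - 1))
    ly <- sum(y * (y - 1)) / (Y * (Y - 1))
    if (lx + ly == 0) return(1)
    sim <- 2 * cross / ((lx + ly) * X * Y)
  }
  d <- 1 - sim
  min(max(d, 0), 1)
}

#' Pairwise compositional dissimilarity of a community matrix
#'
#' Horn-Morisita dissimilarity over all site pairs, computed with vectorized
#' cross-products; exactly equal to calling [horn_morisita()] per pair.
#'
#' @param cm a [community_matrix()] or plain sites x species abundance matrix
#'   with positive row totals.
#' @param variant passed to [horn_morisita()].
#' @return a symmetric `dist_matrix` (square numeric matrix with zero
#'   diagonal, site ids as dimnames).
#' @export
pairwise_dissimilarity <- function(cm, variant = c("horn", "morisita")) {
  variant <- match.arg(variant)
  m <- if (inherits(cm, "community_matrix")) unclass_cm(cm) else as.matrix(cm)
  if (any(m < 0)) stop("negative abundance")
  tot <- rowSums(m)
  if (any(tot == 0)) stop("undefined for empty community")
  if (variant == "horn") {
    cross <- tcrossprod(m)                        # sum_i x_i y_i for all pairs
    simp <- rowSums(m^2) / tot^2                  # sum x^2 / X^2 per site
    denom <- outer(simp, simp, "+") * outer(tot, tot)
    D <- 1 - 2 * cross / denom
  } else {
    if (any(m != round(m))) stop("classical Morisita requires integer counts")
    cross <- tcrossprod(m)
    lam <- rowSums(m * (m - 1)) / (tot * (tot - 1))
    denom <- outer(lam, lam, "+") * outer(tot, tot)
    D <- ifelse(denom == 0, 1, 1 - 2 * cross / denom)
  }
  D <- pmin(pmax(D, 0), 1)
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  structure(D, class = c("dist_matrix", "matrix"))
}

#' Pairwise geographic distance between site centroids
#'
#' Euclidean distance on raw (lat, lon) decimal-degree pairs by default,
#' matching distance-on-coordinates practice for these models; great-circle
#' (haversine, km) available behind a flag.
#'
#' @param centroids data frame or matrix with `lat` and `lon` columns (or two
#'   columns in that order).
#' @param method `"euclidean"` (degrees) or `"haversine"` (km).
#' @return a symmetric `dist_matrix`.
#' @export
geographic_distance <- function(centroids, method = c("euclidean", "haversine")) {
  method <- match.arg(method)
  cd <- as.data.frame(centroids)
  if (!all(c("lat", "lon") %in% names(cd))) {
    stopifnot(ncol(cd) >= 2)
    names(cd)[1:2] <- c("lat", "lon")
  }
  if (any(!is.finite(cd$lat)) || any(!is.finite(cd$lon)))
    stop("non-finite coordinates")
  if (method == "euclidean") {
    D <- as.matrix(stats::dist(cbind(cd$lat, cd$lon)))
  } else {
    rad <- pi / 180
    lat <- cd$lat * rad; lon <- cd$lon * rad
    dlat <- outer(lat, lat, "-"); dlon <- outer(lon, lon, "-")
    a <- sin(dlat / 2)^2 + outer(cos(lat), cos(lat)) * sin(dlon / 2)^2
    D <- 2 * 6371 * asin(pmin(sqrt(a), 1))
  }
  diag(D) <- 0
  rn <- rownames(cd)
  if (!is.null(rn)) dimnames(D) <- list(rn, rn)
  structure(D, class = c("dist_matrix", "matrix"))
}

# Unfold the lower triangle of a square matrix in the fixed pair order
# (1,2), (1,3), ..., (1,n), (2,3), ... used by every distance-matrix routine
# in the package, so Mantel/MRM vectors align bit-identically across modules.
lower_tri <- function(D) {
  D <- as.matrix(D)
  D[lower.tri(D)]
}

#' Within/between-class contrast of a dissimilarity matrix
#'
#' Mantel-style statistic for the claim "dissimilarity is greater between
#' classes than within": `r` is the Pearson correlation between the unfolded
#' dissimilarities and a 0/1 indicator matrix (1 where the two sites' class
#' labels differ), and `p` is a one-sided (greater) permutation p-value with
#' the add-one correction, permuting labels over sites.
#'
#' @param D a `dist_matrix` of dissimilarities.
#' @param labels class label per site (>= 2 distinct values).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
class_contrast <- function(D, labels, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2) stop("contrast undefined for a single class")
  dv <- lower_tri(D)
  ind <- function(lab) lower_tri(outer(lab, lab, "!="))
  obs <- stats::cor(dv, as.numeric(ind(labels)))
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(dv, as.numeric(ind(labels[sample.int(n)])))
  }, numeric(1)))
  p <- (1 + sum(perm_r >= obs)) / (n_perm + 1)
  list(r = obs, p = p, n_perm = n_perm, seed = seed)
}

#' Write/read a square distance matrix as CSV with a site-id header
#'
#' @param D a `dist_matrix`.
#' @param path CSV path.
#' @return `path` invisibly; `read_dist_matrix()` returns the `dist_matrix`.
#' @export
write_dist_matrix <- function(D, path) {
  D <- as.matrix(D)
  df <- data.frame(site = rownames(D), D, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("dist_matrix", "matrix"))
}
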