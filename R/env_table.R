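#' Assemble the per-site environmental parameter table
#'
#' Extracts every continuous layer at the site centroids (with the
#' progressive coarsening fallback of [extract_at_points()]) and looks up
#' categorical class labels ([classify_points()], no fallback). Sites where
#' any layer stays missing after the fallback is exhausted are excluded and
#' reported, never silently filled.
#'
#' @param sites data frame with `site`, `lat`, `lon` columns (e.g. the
#'   centroid table of a [cluster_sites()] result).
#' @param env_stack named list of continuous [raster_grid()] layers.
#' @param class_grids named list of categorical [raster_grid()] layers
#'   (may be empty).
#' @param max_fallback_factor passed to [extract_at_points()].
#' @return data frame with one row per retained site: `site`, `lat`, `lon`,
#'   one column per env layer, one per class grid; attributes `"excluded"`
#'   (site ids dropped for missingness) and `"provenance"` (matrix of
#'   fallback factors used, sites x layers).
#' @export
build_env_table <- function(sites, env_stack, class_grids = list(),
                            max_fallback_factor = 8) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0) stop("empty site list")
  stopifnot(all(c("site", "lat", "lon") %in% names(sites)),
            length(env_stack) >= 1, !is.null(names(env_stack)))
  pts <- cbind(lon = sites$lon, lat = sites$lat)
  ex <- lapply(env_stack, extract_at_points, points = pts,
               max_fallback_factor = max_fallback_factor)
  vals <- vapply(ex, `[[`, numeric(nrow(sites)), "value")
  vals <- matrix(vals, nrow = nrow(sites),
                 dimnames = list(NULL, names(env_stack)))
  prov <- matrix(vapply(ex, `[[`, integer(nrow(sites)), "factor"),
                 nrow = nrow(sites), dimnames = list(NULL, names(env_stack)))
  miss <- rowSums(matrix(vapply(ex, `[[`, logical(nrow(sites)), "missing"),
                         nrow = nrow(sites))) > 0
  labs <- NULL
  if (length(class_grids)) {
    labs <- vapply(class_grids,
                   function(g) as.numeric(classify_points(g, pts)$label),
                   numeric(nrow(sites)))
    labs <- matrix(labs, nrow = nrow(sites),
                   dimnames = list(NULL, names(class_grids)))
    miss <- miss | rowSums(is.na(labs)) > 0
  }
  cover <- grepl("cover|tree|herb|bare", names(env_stack), ignore.case = TRUE)
  if (any(cover)) {
    v <- vals[!miss, cover, drop = FALSE]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("vegetation-cover layer outside [0, 100]")
  }
  out <- data.frame(site = sites$site, lat = sites$lat, lon = sites$lon,
                    vals, check.names = FALSE)
  if (!is.null(labs)) out <- cbind(out, as.data.frame(labs))
  out <- out[!miss, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            excluded = sites$site[miss],
            provenance = prov[!miss, , drop = FALSE])
}

#' Per-variable absolute-difference distance matrices
#'
#' Builds one site-by-site predictor matrix `|e_i - e_j|` per environmental
#' column — the standard construction of environmental distance predictors
#' for regression on distance matrices.
#'
#' @param env a [build_env_table()] result.
#' @param vars environmental column names to use.
#' @return named list of `dist_matrix` objects aligned to `env$site`.
#' @export
env_distances <- function(env, vars) {
  stopifnot(all(vars %in% names(env)))
  ids <- as.character(env$site)
  lapply(stats::setNames(vars, vars), function(v) {
    D <- abs(outer(env[[v]], env[[v]], "-"))
    dimnames(D) <- list(ids, ids)
    structure(D, class = c("dist_matrix", "matrix"))
  })
}
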