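#' Build the site-pair table for dissimilarity modeling
#'
#' One row per unordered site pair `(i < j)` in the package's fixed unfolding
#' order, holding the observed dissimilarity, a richness-based weight
#' `w_ij = (S_i + S_j) / (2 max_site S)` (down-weighting species-poor pairs,
#' which reduces bias from ad hoc presence data), and each predictor's value
#' at both sites. Latitude and longitude enter as two separate predictors so
#' geographic position is spline-transformed like any environmental gradient.
#'
#' @param D dissimilarity `dist_matrix` aligned with `env`.
#' @param env per-site predictor table ([build_env_table()] result or any
#'   data frame with `site`, `lat`, `lon` and numeric predictor columns).
#' @param richness per-site species richness (positive), aligned with `env`.
#' @param predictors predictor column names; default all numeric columns of
#'   `env` except `site` (includes `lat` and `lon`).
#' @return object of class `site_pair_table`: data frame with columns `i`,
#'   `j` (site ids), `distance`, `weight`, and `<p>.i`/`<p>.j` per predictor;
#'   attributes `"predictors"` and `"sites"` (the per-site predictor table)
#'   support refitting under site-level permutations.
#' @export
build_site_pairs <- function(D, env, richness, predictors = NULL) {
  D <- as.matrix(D)
  env <- as.data.frame(env)
  n <- nrow(env)
  stopifnot(nrow(D) == n, length(richness) == n)
  if (any(richness <= 0)) stop("site with zero richness retained")
  if (is.null(predictors)) {
    num <- vapply(env, is.numeric, logical(1))
    predictors <- setdiff(names(env)[num], "site")
  }
  stopifnot(all(predictors %in% names(env)), length(predictors) >= 1)
  a <- rep(seq_len(n - 1), times = (n - 1):1)
  b <- unlist(lapply(seq_len(n - 1), function(k) seq(k + 1, n)))
  out <- data.frame(i = env$site[a], j = env$site[b],
                    distance = lower_tri(D),
                    weight = (richness[a] + richness[b]) / (2 * max(richness)))
  for (p in predictors) {
    out[[paste0(p, ".i")]] <- env[[p]][a]
    out[[paste0(p, ".j")]] <- env[[p]][b]
  }
  structure(out, predictors = predictors,
            sites = env[, c("site", predictors), drop = FALSE],
            richness = richness,
            class = c("site_pair_table", "data.frame"))
}

# I-spline design matrix of a site-pair table: per predictor p and basis k,
# |I_pk(x_pi) - I_pk(x_pj)|. Knots are taken from (or stored in) `knots`.
gdm_design <- function(pairs, knots) {
  preds <- names(knots)
  cols <- lapply(preds, function(p) {
    xi <- pairs[[paste0(p, ".i")]]
    xj <- pairs[[paste0(p, ".j")]]
    if (is.null(xi) || is.null(xj))
      stop("site-pair table lacks predictor columns for '", p, "'")
    d <- abs(ispline_eval(knots[[p]], xi) - ispline_eval(knots[[p]], xj))
    colnames(d) <- paste0(p, "_", seq_len(ncol(d)))
    d
  })
  do.call(cbind, cols)
}

# Weighted binomial-form deviance with the 0*log(0) = 0 convention.
gdm_deviance <- function(d, mu, w) {
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(w * (t1 + t2))
}

#' Fit a generalized dissimilarity model
#'
#' Models expected compositional dissimilarity as
#' `mu_ij = 1 - exp(-eta_ij)` with linear predictor
#' `eta_ij = b0 + sum_pk b_pk |I_pk(x_pi) - I_pk(x_pj)|` over monotone
#' I-spline bases, all coefficients constrained non-negative so predicted
#' dissimilarity never decreases along any gradient. The weighted
#' binomial-form deviance is minimized by iteratively reweighted least
#' squares with a non-negative least-squares inner solve and step-halving
#' (deviance is monotone non-increasing across iterations); the null deviance
#' comes from the intercept-only model under the same link and weights.
#' Observed dissimilarities of exactly 1 are nudged to `1 - 1e-9` to keep the
#' log terms finite.
#'
#' @param pairs a [build_site_pairs()] result.
#' @param n_splines I-spline basis functions per predictor (default 3).
#' @param max_iter IRLS iteration cap (default 500).
#' @param tol relative deviance-change convergence tolerance (default 1e-8).
#' @return object of class `gdm_model`: `intercept`, `coefficients`
#'   (n_splines x predictors matrix, all >= 0), `knots`, `null_deviance`,
#'   `model_deviance`, `pct_deviance_explained`, `importance` (per-predictor
#'   coefficient sums = I-spline plateau heights), convergence report.
#' @export
fit_gdm <- function(pairs, n_splines = 3, max_iter = 500, tol = 1e-8) {
  stopifnot(inherits(pairs, "site_pair_table"))
  preds <- attr(pairs, "predictors")
  sites <- attr(pairs, "sites")
  d <- pairs$distance
  w <- pairs$weight
  if (any(d < 0 | d > 1)) stop("dissimilarities must lie in [0, 1]")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  d <- pmin(d, 1 - 1e-9)

  knots <- lapply(stats::setNames(preds, preds), function(p) {
    x <- sites[[p]]
    if (max(x) == min(x)) NULL else ispline_knots(x, n_splines)
  })
  # constant predictors contribute no basis; the design may be intercept-only
  knots <- knots[!vapply(knots, is.null, logical(1))]
  X <- cbind(`(Intercept)` = rep(1, length(d)),
             if (length(knots)) gdm_design(pairs, knots))

  eps <- 1e-10
  mu0 <- min(max(stats::weighted.mean(d, w), eps), 1 - eps)
  null_dev <- gdm_deviance(d, mu0, w)
  beta <- c(-log(1 - mu0), rep(0, ncol(X) - 1))
  dev <- gdm_deviance(d, pmin(pmax(1 - exp(-as.vector(X %*% beta)), eps),
                              1 - eps), w)
  trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmax(as.vector(X %*% beta), eps)
    mu <- pmin(pmax(1 - exp(-eta), eps), 1 - eps)
    z <- eta + (d - mu) / (1 - mu)
    W <- w * (1 - mu) / mu
    sw <- sqrt(W)
    prop <- pracma::lsqnonneg(X * sw, z * sw)$x
    # step-halving keeps the deviance monotone non-increasing
    step <- 1
    repeat {
      cand <- beta + step * (prop - beta)
      mu_c <- pmin(pmax(1 - exp(-as.vector(X %*% cand)), eps), 1 - eps)
      dev_c <- gdm_deviance(d, mu_c, w)
      if (dev_c <= dev + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- cand
    trace <- c(trace, dev_c)
    # converged when the deviance stops moving, or is zero for all practical
    # purposes (perfect fit) relative to the null deviance
    if (abs(dev - dev_c) <= tol * max(dev, 1e-12) ||
        dev_c <= 1e-10 * max(null_dev, 1e-12)) {
      dev <- dev_c
      converged <- TRUE
      break
    }
    dev <- dev_c
  }
  if (!converged)
    stop("GDM fit did not converge in ", max_iter,
         " iterations; deviance trace tail: ",
         paste(signif(utils::tail(trace, 5), 8), collapse = ", "))

  coef_mat <- matrix(0, n_splines, length(preds),
                     dimnames = list(paste0("s", seq_len(n_splines)), preds))
  if (length(knots)) {
    sp_coef <- beta[-1]
    names(sp_coef) <- colnames(X)[-1]
    for (p in names(knots))
      coef_mat[, p] <- sp_coef[paste0(p, "_", seq_len(n_splines))]
  }
  structure(list(
    intercept = beta[1],
    coefficients = coef_mat,
    knots = knots,
    n_splines = n_splines,
    predictors = preds,
    null_deviance = null_dev,
    model_deviance = dev,
    # a null deviance of (numerically) zero means nothing to explain
    pct_deviance_explained = if (null_dev <= 1e-12) 0
                             else 100 * (null_dev - dev) / null_dev,
    importance = colSums(coef_mat),
    converged = converged, iterations = it,
    deviance_trace = trace), class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("GDM: %d predictors x %d splines, %.2f%% of null deviance explained (%d IRLS iterations)\n",
              length(x$predictors), x$n_splines, x$pct_deviance_explained,
              x$iterations))
  cat("importance (I-spline plateau heights):\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}

#' Predict dissimilarity for site pairs from a fitted GDM
#'
#' @param model a [fit_gdm()] result.
#' @param pairs a site-pair table containing the model's predictor columns.
#' @return predicted dissimilarities in `[0, 1)`.
#' @export
predict_dissimilarity <- function(model, pairs) {
  X <- cbind(1, if (length(model$knots)) gdm_design(pairs, model$knots))
  cf <- c(model$intercept,
          unlist(lapply(names(model$knots),
                        function(p) model$coefficients[, p])))
  1 - exp(-pmax(as.vector(X %*% cf), 0))
}

#' Permutation significance and importance of GDM predictors
#'
#' For each predictor, its per-site values are permuted across sites (the
#' response and all other predictors fixed), the site-pair table is rebuilt
#' and the model refitted; the p-value is the add-one-corrected fraction of
#' permutations whose percent deviance explained reaches the observed full
#' model's. Importance is the predictor's fitted coefficient sum (its
#' I-spline plateau height).
#'
#' @param pairs a [build_site_pairs()] result.
#' @param n_splines basis functions per predictor.
#' @param n_perm permutations per predictor (default 100; refits are the
#'   costly step).
#' @param seed integer seed.
#' @param alpha keep/drop significance level (default 0.05).
#' @param model optional pre-fitted full model (refitted if omitted).
#' @return data frame with one row per predictor: `predictor`, `importance`,
#'   `p`, `keep`.
#' @export
predictor_significance <- function(pairs, n_splines = 3, n_perm = 100,
                                   seed = 1, alpha = 0.05, model = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  stopifnot(inherits(pairs, "site_pair_table"))
  sites <- attr(pairs, "sites")
  # the response (pairs$distance) is reused as-is; only predictors permute
  if (is.null(model)) model <- fit_gdm(pairs, n_splines = n_splines)
  obs <- model$pct_deviance_explained
  preds <- attr(pairs, "predictors")
  n <- nrow(sites)
  a <- match(pairs$i, sites$site)
  b <- match(pairs$j, sites$site)
  p_vals <- with_seed(seed, vapply(preds, function(p) {
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample.int(n)
      pp <- pairs
      pp[[paste0(p, ".i")]] <- sites[[p]][perm][a]
      pp[[paste0(p, ".j")]] <- sites[[p]][perm][b]
      attr(pp, "sites") <- local({
        s <- sites; s[[p]] <- s[[p]][perm]; s
      })
      fit <- fit_gdm(pp, n_splines = n_splines)
      if (fit$pct_deviance_explained >= obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_perm + 1)
  }, numeric(1)))
  data.frame(predictor = preds,
             importance = model$importance[preds],
             p = p_vals,
             keep = p_vals <= alpha,
             row.names = NULL)
}

#' Transform environmental rasters to biological space
#'
#' Applies each predictor's fitted monotone transform pixelwise:
#' `f_p(x) = sum_k b_pk I_pk(x)`, the partial ecological distance surface,
#' bounded by `[0, importance_p]`. Latitude/longitude predictors are
#' evaluated on rasters synthesized from the grid geometry. Nodata
#' propagates.
#'
#' @param model a [fit_gdm()] result.
#' @param env_stack named list of [raster_grid()] layers covering the
#'   predictors to transform.
#' @param predictors which predictors to transform; defaults to those with
#'   positive importance.
#' @return named list of transformed `raster_grid` layers.
#' @export
transform_env <- function(model, env_stack, predictors = NULL) {
  if (is.null(predictors))
    predictors <- names(model$importance)[model$importance > 0]
  predictors <- intersect(predictors, names(model$knots))
  if (!length(predictors)) stop("no predictors to transform")
  g1 <- env_stack[[1]]
  ll <- latlon_grids(g1)
  get_grid <- function(p) {
    if (!is.null(env_stack[[p]])) env_stack[[p]]
    else if (p %in% names(ll)) ll[[p]]
    else stop("no raster available for kept predictor '", p, "'")
  }
  lapply(stats::setNames(predictors, predictors), function(p) {
    g <- get_grid(p)
    v <- as.vector(g$values)
    ok <- !is.na(v)
    f <- rep(NA_real_, length(v))
    f[ok] <- as.vector(ispline_eval(model$knots[[p]], v[ok]) %*%
                         model$coefficients[, p])
    raster_grid(matrix(f, nrow(g$values), ncol(g$values)),
                g$xmin, g$ymax, g$xres, g$yres, crs = g$crs)
  })
}

#' PCA-RGB beta-diversity map from transformed layers
#'
#' Principal component analysis over valid pixels of the biological-space
#' layers; the first three components are min-max scaled to `[0, 255]` and
#' assigned to red, green, blue, so color difference between two pixels
#' approximates their predicted compositional dissimilarity. Component signs
#' are fixed (largest-magnitude loading positive) for reproducibility; if
#' fewer than three layers are supplied the stack is padded with zero layers
#' (with a warning) and degenerate components render as 0.
#'
#' @param transformed_stack named list of [transform_env()] output layers.
#' @return object of class `rgb_map`: list of `r`, `g`, `b` [raster_grid()]s
#'   plus PCA `loadings` and `var_explained`.
#' @export
beta_map <- function(transformed_stack) {
  stopifnot(length(transformed_stack) >= 1)
  g1 <- transformed_stack[[1]]
  vals <- vapply(transformed_stack, function(g) as.vector(g$values),
                 numeric(length(g1$values)))
  vals <- matrix(vals, ncol = length(transformed_stack),
                 dimnames = list(NULL, names(transformed_stack)))
  if (ncol(vals) < 3) {
    warning("fewer than 3 layers; padding with zero layers")
    pad <- matrix(0, nrow(vals), 3 - ncol(vals),
                  dimnames = list(NULL, paste0("zero", seq_len(3 - ncol(vals)))))
    vals <- cbind(vals, pad)
  }
  ok <- rowSums(is.na(vals)) == 0
  if (!any(ok)) stop("no valid pixels")
  pc <- stats::prcomp(vals[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$rotation))
  scores <- matrix(0, sum(ok), 3)
  load <- matrix(0, ncol(vals), 3,
                 dimnames = list(colnames(vals), c("PC1", "PC2", "PC3")))
  for (c3 in seq_len(k)) {
    rot <- pc$rotation[, c3]
    if (rot[which.max(abs(rot))] < 0) rot <- -rot
    load[, c3] <- rot
    scores[, c3] <- scale(vals[ok, , drop = FALSE], center = pc$center,
                          scale = FALSE) %*% rot
  }
  channel <- function(c3) {
    s <- scores[, c3]
    r <- range(s)
    v <- rep(NA_real_, length(ok))
    v[ok] <- if (r[1] == r[2]) 0 else (s - r[1]) / (r[2] - r[1]) * 255
    raster_grid(matrix(v, nrow(g1$values), ncol(g1$values)),
                g1$xmin, g1$ymax, g1$xres, g1$yres, crs = g1$crs)
  }
  structure(list(r = channel(1), g = channel(2), b = channel(3),
                 loadings = load,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "rgb_map")
}

#' Write an RGB beta-diversity map
#'
#' Three ESRI ASCII grids (one per channel) and, when the `png` package is
#' available, a PNG preview with nodata rendered transparent.
#'
#' @param map a [beta_map()] result.
#' @param prefix output path prefix; writes `<prefix>_r.asc` etc. and
#'   `<prefix>.png`.
#' @return character vector of files written, invisibly.
#' @export
write_rgb_map <- function(map, prefix) {
  files <- c(paste0(prefix, "_r.asc"), paste0(prefix, "_g.asc"),
             paste0(prefix, "_b.asc"))
  write_ascii_grid(map$r, files[1])
  write_ascii_grid(map$g, files[2])
  write_ascii_grid(map$b, files[3])
  if (requireNamespace("png", quietly = TRUE)) {
    arr <- array(0, c(nrow(map$r$values), ncol(map$r$values), 4))
    arr[, , 1] <- map$r$values / 255
    arr[, , 2] <- map$g$values / 255
    arr[, , 3] <- map$b$values / 255
    arr[, , 4] <- !is.na(map$r$values)
    arr[is.na(arr)] <- 0
    f <- paste0(prefix, ".png")
    png::writePNG(arr, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Serialize / restore a fitted GDM as structured JSON text
#'
#' @param model a [fit_gdm()] result.
#' @param path output path.
#' @return `path` invisibly; `read_gdm_model()` returns the `gdm_model`.
#' @export
write_gdm_model <- function(model, path) {
  payload <- list(intercept = model$intercept,
                  coefficients = as.data.frame(model$coefficients),
                  knots = model$knots,
                  n_splines = model$n_splines,
                  predictors = model$predictors,
                  null_deviance = model$null_deviance,
                  model_deviance = model$model_deviance,
                  pct_deviance_explained = model$pct_deviance_explained,
                  importance = as.list(model$importance),
                  converged = model$converged,
                  iterations = model$iterations)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_gdm_model
#' @export
read_gdm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- as.matrix(p$coefficients)
  rownames(cf) <- paste0("s", seq_len(nrow(cf)))
  structure(list(intercept = p$intercept, coefficients = cf,
                 knots = lapply(p$knots, as.numeric),
                 n_splines = p$n_splines, predictors = p$predictors,
                 null_deviance = p$null_deviance,
                 model_deviance = p$model_deviance,
                 pct_deviance_explained = p$pct_deviance_explained,
                 importance = unlist(p$importance),
                 converged = p$converged, iterations = p$iterations),
            class = "gdm_model")
}
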