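#' Mantel test between two distance matrices
#'
#' Pearson correlation of the unfolded lower triangles, with a one-sided
#' (greater) permutation p-value obtained by simultaneous row/column
#' permutation of the response matrix, add-one corrected.
#'
#' @param Dy,Dx square distance matrices of equal size.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(Dy, Dx, n_perm = 999, seed = 1) {
  Dy <- as.matrix(Dy); Dx <- as.matrix(Dx)
  stopifnot(all(dim(Dy) == dim(Dx)), nrow(Dy) == ncol(Dy))
  n <- nrow(Dy)
  y <- lower_tri(Dy); x <- lower_tri(Dx)
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("zero variance in a distance matrix; Mantel r undefined")
  obs <- stats::cor(y, x)
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(n)
    stats::cor(lower_tri(Dy[pm, pm]), x)
  }, numeric(1)))
  list(r = obs, p = (1 + sum(perm_r >= obs)) / (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

# OLS on unfolded lower triangles; returns coefficients, fitted stats and
# t-statistics. Shared by the observed fit and every permutation refit.
fit_unfolded <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear predictors: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df <- length(y) - ncol(X)
  sigma2 <- sse / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  list(coef = as.vector(beta), se = se, t = as.vector(beta) / se,
       r_squared = 1 - sse / sst)
}

#' Multiple regression on distance matrices
#'
#' Ordinary least squares of the unfolded response distances on one or more
#' unfolded predictor distance matrices. Inference is by response
#' permutation: rows and columns of `Dy` are permuted simultaneously
#' (predictors fixed) and the model refitted; the overall p-value comes from
#' the permutation null of R-squared, per-coefficient p-values from the nulls
#' of |t|. Predictors are z-standardized on the unfolded scale by default so
#' coefficient magnitudes are comparable.
#'
#' @param Dy response `dist_matrix`.
#' @param predictors named list of predictor `dist_matrix` objects.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param standardize z-standardize unfolded predictors (default `TRUE`).
#' @return object of class `mrm_result`: coefficients (intercept first),
#'   `r_squared`, `p_overall`, per-coefficient `p_coef`, `n_perm`, `seed`.
#' @export
mrm <- function(Dy, predictors, n_perm = 999, seed = 1, standardize = TRUE) {
  stopifnot(length(predictors) >= 1, !is.null(names(predictors)))
  Dy <- as.matrix(Dy)
  n <- nrow(Dy)
  for (p in predictors)
    if (!all(dim(as.matrix(p)) == n)) stop("non-conformable predictor matrix")
  y <- lower_tri(Dy)
  Xp <- vapply(predictors, lower_tri, numeric(length(y)))
  Xp <- matrix(Xp, ncol = length(predictors),
               dimnames = list(NULL, names(predictors)))
  if (standardize) {
    s <- apply(Xp, 2, stats::sd)
    if (any(s == 0))
      stop("zero variance in predictor(s): ",
           paste(colnames(Xp)[s == 0], collapse = ", "))
    Xp <- scale(Xp)
  }
  X <- cbind(`(Intercept)` = 1, Xp)
  obs <- fit_unfolded(y, X)
  perm <- with_seed(seed, {
    r2 <- numeric(n_perm)
    tt <- matrix(0, n_perm, ncol(X))
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      f <- fit_unfolded(lower_tri(Dy[pm, pm]), X)
      r2[i] <- f$r_squared
      tt[i, ] <- abs(f$t)
    }
    list(r2 = r2, tt = tt)
  })
  p_overall <- (1 + sum(perm$r2 >= obs$r_squared)) / (n_perm + 1)
  p_coef <- (1 + colSums(perm$tt >= matrix(abs(obs$t), n_perm, ncol(X),
                                           byrow = TRUE))) / (n_perm + 1)
  structure(list(coefficients = stats::setNames(obs$coef, colnames(X)),
                 r_squared = obs$r_squared, p_overall = p_overall,
                 p_coef = stats::setNames(p_coef, colnames(X)),
                 t = stats::setNames(obs$t, colnames(X)),
                 n_perm = n_perm, seed = seed, standardize = standardize),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM: r-squared = %.4f (p = %.4g, %d permutations)\n",
              x$r_squared, x$p_overall, x$n_perm))
  print(data.frame(coefficient = x$coefficients, t = x$t, p = x$p_coef))
  invisible(x)
}

#' Nested-model comparison of distance-matrix regressions
#'
#' Fits the four standard nested models — geographic distance alone, plus the
#' climate set, plus the vegetation set, plus both — and tabulates R-squared
#' and overall permutation p for each, in the shape of a model-comparison
#' table of compositional dissimilarity regressions.
#'
#' @param Dy response `dist_matrix`.
#' @param geographic geographic-distance `dist_matrix`.
#' @param climate_set,vegetation_set named lists of predictor `dist_matrix`
#'   objects (may be empty).
#' @param n_perm,seed,standardize passed to [mrm()].
#' @return data frame with columns `model`, `r_squared`, `p`.
#' @export
model_comparison <- function(Dy, geographic, climate_set, vegetation_set,
                             n_perm = 999, seed = 1, standardize = TRUE) {
  models <- list(
    "dissimilarity ~ geographic" = list(geographic = geographic),
    "dissimilarity ~ geographic + climate" =
      c(list(geographic = geographic), climate_set),
    "dissimilarity ~ geographic + vegetation" =
      c(list(geographic = geographic), vegetation_set),
    "dissimilarity ~ geographic + climate + vegetation" =
      c(list(geographic = geographic), climate_set, vegetation_set))
  res <- lapply(models, function(pr)
    mrm(Dy, pr, n_perm = n_perm, seed = seed, standardize = standardize))
  data.frame(model = names(models),
             r_squared = vapply(res, `[[`, numeric(1), "r_squared"),
             p = vapply(res, `[[`, numeric(1), "p_overall"),
             row.names = NULL)
}
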