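#' Knot vector for a monotone I-spline basis
#'
#' Knots are placed at evenly spaced percentiles of the observed predictor
#' values — for the default of 3 basis functions, at the 0th, 50th and 100th
#' percentiles — the conventional choice for dissimilarity modeling.
#'
#' @param x observed predictor values at the sites.
#' @param n_splines number of basis functions (= number of knots, >= 2).
#' @return numeric knot vector of length `n_splines` (non-decreasing,
#'   min < max).
#' @export
ispline_knots <- function(x, n_splines = 3) {
  stopifnot(n_splines >= 2)
  k <- stats::quantile(x, probs = seq(0, 1, length.out = n_splines),
                       names = FALSE, na.rm = TRUE)
  if (k[1] >= k[n_splines]) stop("constant predictor: degenerate knot range")
  k
}

#' Evaluate a monotone I-spline basis
#'
#' Ramsay-type I-splines of order 3 (piecewise-cubic integrals of quadratic
#' M-splines): each basis function is non-decreasing, 0 at or below the
#' minimum knot and 1 at or above the maximum knot, so a non-negative
#' combination is a monotone transform with plateau height equal to the
#' coefficient sum. Implemented through the classical B-spline identity
#' `I_i(x) = sum_{j > i} B_j(x)` on boundary-augmented knots (B-splines
#' evaluated with `splines::splineDesign`); the steep leading basis of the
#' full family is dropped so the basis count equals the knot count. Inputs
#' are clamped to the knot range.
#'
#' @param knots knot vector from [ispline_knots()].
#' @param x values to evaluate at.
#' @param order spline order (default 3; the only order used in the package).
#' @return matrix `length(x)` x `length(knots)` of basis values in `[0, 1]`.
#' @export
ispline_eval <- function(knots, x, order = 3) {
  K <- length(knots)
  a <- knots[1]; b <- knots[K]
  if (a >= b) stop("constant predictor: degenerate knot range")
  ord <- order + 1                       # B-spline order = I-spline order + 1
  inner <- knots[-c(1, K)]
  eps <- 1e-9 * (b - a)
  inner <- pmin(pmax(inner, a + eps), b - eps)
  aug <- c(rep(a, ord), inner, rep(b, ord))
  xc <- pmin(pmax(x, a), b)
  B <- splines::splineDesign(aug, xc, ord = ord)
  n_b <- ncol(B)
  # right-to-left cumulative sums: S[, j] = sum_{k >= j} B[, k]
  S <- B
  if (n_b > 1) for (j in (n_b - 1):1) S[, j] <- S[, j] + S[, j + 1]
  out <- S[, (n_b - K + 1):n_b, drop = FALSE]
  colnames(out) <- paste0("s", seq_len(K))
  out
}
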