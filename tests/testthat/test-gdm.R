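test_that("site-pair table has the right shape, weights, and ordering", {
  set.seed(109)
  n <- 5
  env <- data.frame(site = letters[1:n], lat = runif(n), lon = runif(n),
                    x = runif(n))
  D <- structure(random_dist(n), class = c("dist_matrix", "matrix"))
  rich <- c(10, 30, 50, 20, 40)
  pairs <- build_site_pairs(D, env, rich)
  expect_equal(nrow(pairs), n * (n - 1) / 2)
  # hand-computed weights: (S_i + S_j) / (2 max S)
  expect_equal(pairs$weight[pairs$i == "a" & pairs$j == "c"], 0.6)
  expect_equal(pairs$weight[pairs$i == "b" & pairs$j == "c"], 0.8)
  # distances align with the package's fixed unfolding order
  expect_equal(pairs$distance, D[lower.tri(D)])
  # lat and lon are predictors by default
  expect_true(all(c("lat.i", "lon.i", "x.j") %in% names(pairs)))
  expect_equal(build_site_pairs(D, env, rep(7, n))$weight, rep(1, n * (n - 1) / 2))
  expect_error(build_site_pairs(D, env, c(0, rich[-1])), "zero richness")
})

test_that("null data give a null model: zero coefficients, zero deviance explained", {
  n <- 8
  env <- data.frame(site = 1:n, lat = rep(1, n), lon = rep(2, n),
                    x = rep(3, n))
  D <- matrix(0.4, n, n); diag(D) <- 0
  dimnames(D) <- list(1:n, 1:n)
  pairs <- build_site_pairs(structure(D, class = c("dist_matrix", "matrix")),
                            env, rep(5, n))
  m <- fit_gdm(pairs)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$pct_deviance_explained, 0, tolerance = 1e-6)
  expect_equal(1 - exp(-m$intercept), 0.4, tolerance = 1e-8)
})

test_that("noise-free generative data are inverted exactly", {
  nf <- noise_free_pairs(n_sites = 40, beta = c(0.8, 0.5, 0.3),
                         intercept = 0.1, seed = 1)
  m <- fit_gdm(nf$pairs)
  expect_lt(abs(m$importance[["x"]] - sum(nf$beta)), 1e-3)
  expect_lt(abs(m$intercept - nf$intercept), 1e-3)
  expect_lt(m$model_deviance, 1e-6 * m$null_deviance)
  expect_true(all(m$coefficients >= 0))
  # prediction reproduces the training dissimilarities through the link
  pred <- predict_dissimilarity(m, nf$pairs)
  expect_lt(max(abs(pred - nf$pairs$distance)), 1e-6)
})

test_that("fitted deviance beats random search and a generic box optimizer", {
  for (case in 1:6) {
    pairs <- tiny_gdm_instance(n_sites = 6, n_pred = 2, seed = case)
    m <- fit_gdm(pairs)
    preds <- attr(pairs, "predictors")
    kn <- lapply(setNames(preds, preds),
                 function(p) ispline_knots(attr(pairs, "sites")[[p]], 3))
    X <- cbind(1, betascape:::gdm_design(pairs, kn))
    d <- pmin(pairs$distance, 1 - 1e-9); w <- pairs$weight
    devfun <- function(b) {
      mu <- pmin(pmax(1 - exp(-as.vector(X %*% b)), 1e-10), 1 - 1e-10)
      oracle_gdm_deviance(d, mu, w)
    }
    # random feasible draws never beat the fit
    set.seed(case * 100)
    draws <- matrix(runif(1e4 * ncol(X), 0, 1.5), ncol = ncol(X))
    best_draw <- min(apply(draws, 1, devfun))
    expect_lte(m$model_deviance, best_draw + 1e-9)
    # box-constrained optimizer with restarts agrees to 1e-6 relative
    best_opt <- Inf
    for (r in 1:20) {
      start <- runif(ncol(X), 0, 0.5)
      o <- suppressWarnings(stats::optim(start, devfun, method = "L-BFGS-B",
                                         lower = 0, control = list(maxit = 500)))
      best_opt <- min(best_opt, o$value)
    }
    expect_lte(m$model_deviance, best_opt * (1 + 1e-6) + 1e-9)
  }
})

test_that("predictions respect the link and monotonicity", {
  nf <- noise_free_pairs(seed = 2)
  m <- fit_gdm(nf$pairs)
  # identical sites -> mu = 1 - exp(-intercept)
  p0 <- nf$pairs[1, ]
  p0$x.j <- p0$x.i
  expect_equal(predict_dissimilarity(m, p0), 1 - exp(-m$intercept),
               tolerance = 1e-12)
  # growing the predictor difference never decreases mu
  base <- nf$pairs[3, ]
  xs <- seq(base$x.i, max(attr(nf$pairs, "sites")$x), length.out = 20)
  mus <- vapply(xs, function(v) {
    pp <- base; pp$x.j <- v
    predict_dissimilarity(m, pp)
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-12))
  expect_true(all(mus >= 0 & mus < 1))
  expect_error(predict_dissimilarity(m, nf$pairs[, c("i", "j", "distance",
                                                     "weight")]),
               "lacks predictor")
})

test_that("percent deviance explained ignores row order and predictor labels", {
  pairs <- tiny_gdm_instance(n_sites = 7, n_pred = 2, seed = 99)
  m1 <- fit_gdm(pairs)
  perm <- sample(nrow(pairs))
  pairs2 <- pairs[perm, ]
  attr(pairs2, "predictors") <- attr(pairs, "predictors")
  attr(pairs2, "sites") <- attr(pairs, "sites")
  class(pairs2) <- class(pairs)
  m2 <- fit_gdm(pairs2)
  expect_equal(m1$pct_deviance_explained, m2$pct_deviance_explained,
               tolerance = 1e-6)
})

test_that("duplicating a predictor cannot reduce deviance explained", {
  pairs <- tiny_gdm_instance(n_sites = 8, n_pred = 1, seed = 7)
  m1 <- fit_gdm(pairs)
  env <- attr(pairs, "sites")
  env$p1_copy <- env$p1
  env$lat <- 0; env$lon <- 0  # unused
  D <- matrix(0, 8, 8); D[lower.tri(D)] <- pairs$distance
  D <- D + t(D); dimnames(D) <- list(env$site, env$site)
  pairs2 <- build_site_pairs(structure(D, class = c("dist_matrix", "matrix")),
                             env, attr(pairs, "richness"),
                             predictors = c("p1", "p1_copy"))
  m2 <- fit_gdm(pairs2)
  expect_lte(m2$model_deviance, m1$model_deviance + 1e-6 * m1$null_deviance)
})

test_that("significance flags a generative driver and clears pure noise", {
  nf <- noise_free_pairs(n_sites = 25, seed = 31)
  env <- attr(nf$pairs, "sites")
  set.seed(32)
  env$noise <- rnorm(nrow(env))
  D <- matrix(0, 25, 25); D[lower.tri(D)] <- nf$pairs$distance
  D <- D + t(D); dimnames(D) <- list(env$site, env$site)
  pairs <- build_site_pairs(structure(D, class = c("dist_matrix", "matrix")),
                            env, rep(10, 25), predictors = c("x", "noise"))
  sig <- predictor_significance(pairs, n_perm = 49, seed = 33)
  expect_true(sig$keep[sig$predictor == "x"])
  expect_false(sig$keep[sig$predictor == "noise"])
  expect_gt(sig$importance[sig$predictor == "x"],
            sig$importance[sig$predictor == "noise"])
  expect_error(predictor_significance(pairs, n_perm = 0), "n_perm")
})

test_that("raster transforms match direct basis evaluation and bounds", {
  nf <- noise_free_pairs(seed = 8)
  m <- fit_gdm(nf$pairs)
  v <- matrix(seq(0, 10, length.out = 16), 4, 4)
  v[2, 2] <- NA
  g <- raster_grid(v, 0, 4, 1)
  tr <- transform_env(m, list(x = g))
  expect_named(tr, "x")
  f <- tr$x$values
  expect_true(is.na(f[2, 2]))
  # pixelwise oracle: evaluate the basis directly on the valid pixels
  want <- as.vector(ispline_eval(m$knots$x, v[!is.na(v)]) %*%
                      m$coefficients[, "x"])
  expect_equal(f[!is.na(v)], want, tolerance = 1e-12)
  expect_true(all(f >= 0 & f <= m$importance[["x"]] + 1e-12, na.rm = TRUE))
  # constant raster -> constant transform
  gc <- raster_grid(matrix(4.2, 3, 3), 0, 3, 1)
  trc <- transform_env(m, list(x = gc))
  expect_equal(max(trc$x$values) - min(trc$x$values), 0)
  expect_error(transform_env(m, list(unrelated = gc), predictors = "x"),
               "no raster available")
})

test_that("PCA-RGB maps are deterministic with full channel span", {
  set.seed(113)
  mk <- function(v) raster_grid(matrix(v, 5, 5), 0, 5, 1)
  grad <- matrix(rep(seq(0, 1, length.out = 5), each = 5), 5, 5)
  flat1 <- mk(rnorm(25)); flat2 <- flat1
  map <- beta_map(list(a = flat1, b = flat2, c = mk(grad)))
  expect_true(all(range(map$r$values) == c(0, 255)))
  # identical input pixels share identical colors
  stacked <- cbind(as.vector(flat1$values), as.vector(flat2$values),
                   as.vector(grad))
  dup <- which(duplicated(stacked) | duplicated(stacked, fromLast = TRUE))
  if (length(dup) >= 2) {
    cols <- cbind(as.vector(map$r$values), as.vector(map$g$values),
                  as.vector(map$b$values))
    expect_equal(cols[dup[1], ], cols[dup[2], ])
  }
  map2 <- beta_map(list(a = flat1, b = flat2, c = mk(grad)))
  expect_identical(map$r$values, map2$r$values)
  expect_identical(map$loadings, map2$loadings)
  # two identical layers + one gradient: hue varies only along the gradient
  # (the gradient runs across columns, so colors are constant within columns)
  gmap <- beta_map(list(a = mk(grad), b = mk(grad), c = mk(grad * 2)))
  expect_true(all(apply(gmap$r$values, 2, function(r) max(r) - min(r)) < 1e-9))
  expect_warning(beta_map(list(a = mk(grad))), "padding")
})

test_that("GDM models round-trip through their JSON serialization", {
  nf <- noise_free_pairs(seed = 5)
  m <- fit_gdm(nf$pairs)
  f <- tempfile(fileext = ".json")
  write_gdm_model(m, f)
  m2 <- read_gdm_model(f)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(unname(m2$coefficients), unname(m$coefficients),
               tolerance = 1e-12)
  expect_equal(m2$knots$x, unname(m$knots$x), tolerance = 1e-12)
  expect_equal(predict_dissimilarity(m2, nf$pairs),
               predict_dissimilarity(m, nf$pairs), tolerance = 1e-10)
})
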