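# Shared small fixtures, built once per test run.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_world(extent = c(0, 8, 44, 52), grid_shape = c(16, 16),
                               n_env_vars = 2, n_classes = 3, seed = 11)
    cache
  }
})

# A site-pair table generated from a known 1-predictor I-spline model with
# intercept 0.1 and no noise (the generative-inversion scenario).
noise_free_pairs <- function(n_sites = 40, beta = c(0.8, 0.5, 0.3),
                             intercept = 0.1, seed = 1) {
  set.seed(seed)
  env <- data.frame(site = seq_len(n_sites),
                    lat = runif(n_sites), lon = runif(n_sites),
                    x = sort(runif(n_sites, 0, 10)))
  kn <- ispline_knots(env$x, length(beta))
  f <- as.vector(ispline_eval(kn, env$x) %*% beta)
  D <- 1 - exp(-(intercept + abs(outer(f, f, "-"))))
  diag(D) <- 0
  dimnames(D) <- list(env$site, env$site)
  pairs <- build_site_pairs(structure(D, class = c("dist_matrix", "matrix")),
                            env, richness = rep(10, n_sites),
                            predictors = "x")
  list(pairs = pairs, beta = beta, intercept = intercept, knots = kn)
}

# Grid-cell sites: tally sampled records directly into pixels (bypassing the
# clustering stage) so tests of the modeling layers run on known site units.
pixel_site_data <- function(fx, min_records = 50) {
  g1 <- fx$world$env_stack[[1]]
  occ <- fx$occurrences
  cells <- cell_from_xy(g1, cbind(occ$decimalLongitude, occ$decimalLatitude))
  nc <- ncol(g1$values)
  pix <- (cells[, "row"] - 1L) * nc + cells[, "col"]
  keep_pix <- as.integer(names(which(table(pix) >= min_records)))
  sel <- pix %in% keep_pix
  species <- sort(unique(occ$species))
  m <- table(factor(pix[sel], levels = keep_pix),
             factor(occ$species[sel], levels = species))
  m <- matrix(as.integer(m), nrow = length(keep_pix),
              dimnames = list(as.character(keep_pix), species))
  ctr <- xy_from_cell(g1, cbind(row = (keep_pix - 1L) %/% nc + 1L,
                                col = (keep_pix - 1L) %% nc + 1L))
  env <- data.frame(site = rownames(m), lat = ctr[, "lat"], lon = ctr[, "lon"])
  for (v in names(fx$world$env_stack))
    env[[v]] <- extract_at_points(fx$world$env_stack[[v]], ctr)$value
  cm <- structure(m, class = c("community_matrix", "matrix", "array"))
  D <- pairwise_dissimilarity(cm)
  G <- geographic_distance(env[, c("lat", "lon")])
  dimnames(G) <- dimnames(D)
  list(cm = cm, env = env, richness = rowSums(m > 0), D = D, G = G)
}

# Random tiny GDM instance (for optimizer-oracle comparisons).
tiny_gdm_instance <- function(n_sites = 6, n_pred = 2, seed = 1) {
  set.seed(seed)
  env <- data.frame(site = seq_len(n_sites),
                    lat = runif(n_sites), lon = runif(n_sites))
  preds <- paste0("p", seq_len(n_pred))
  for (p in preds) env[[p]] <- runif(n_sites, 0, 5)
  D <- random_dist(n_sites) * 0.9 + 0.05
  diag(D) <- 0
  build_site_pairs(structure(D, class = c("dist_matrix", "matrix")), env,
                   richness = sample(5:20, n_sites, replace = TRUE),
                   predictors = preds)
}
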