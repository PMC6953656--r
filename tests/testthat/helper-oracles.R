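# Independent naive oracles, deliberately written as plain loops / direct
# formulas so they share no code path with the package implementations.

# Horn-Morisita by explicit summation loops.
naive_horn <- function(x, y) {
  X <- 0; Y <- 0; cross <- 0; sx2 <- 0; sy2 <- 0
  for (i in seq_along(x)) {
    X <- X + x[i]; Y <- Y + y[i]
    cross <- cross + x[i] * y[i]
    sx2 <- sx2 + x[i]^2
    sy2 <- sy2 + y[i]^2
  }
  1 - 2 * cross / ((sx2 / X^2 + sy2 / Y^2) * X * Y)
}

# Pairwise dissimilarity by a double loop over site pairs.
naive_pairwise <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) D[i, j] <- naive_horn(m[i, ], m[j, ])
  }
  D
}

# OLS by explicit normal equations.
normal_eq_fit <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(coef = as.vector(beta), r_squared = r2)
}

# Weighted binomial-form GDM deviance, written directly from the formula.
oracle_gdm_deviance <- function(d, mu, w) {
  s <- 0
  for (k in seq_along(d)) {
    t1 <- if (d[k] > 0) d[k] * log(d[k] / mu[k]) else 0
    t2 <- if (d[k] < 1) (1 - d[k]) * log((1 - d[k]) / (1 - mu[k])) else 0
    s <- s + w[k] * (t1 + t2)
  }
  2 * s
}

# Brute-force fixed point of the community filters, applying the two rules in
# the given order per pass until nothing changes.
oracle_filter_fixed_point <- function(m, min_sites, min_obs,
                                      order = c("species_first", "sites_first")) {
  order <- match.arg(order)
  repeat {
    changed <- FALSE
    step_species <- function() {
      keep <- colSums(m > 0) >= min_sites
      if (any(!keep)) { m <<- m[, keep, drop = FALSE]; changed <<- TRUE }
    }
    step_sites <- function() {
      keep <- rowSums(m) >= min_obs
      if (any(!keep)) { m <<- m[keep, , drop = FALSE]; changed <<- TRUE }
    }
    if (order == "species_first") { step_species(); step_sites() }
    else { step_sites(); step_species() }
    if (!changed) break
    if (nrow(m) == 0 || ncol(m) == 0) break
  }
  m
}

# Connected components of a thresholded distance graph (union-find); MCL must
# refine or equal this partition for well-separated clouds.
oracle_threshold_components <- function(xy, radius) {
  n <- nrow(xy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Strip community_matrix class and attributes for plain-matrix comparison.
unclass_cm_for_test <- function(cm) {
  m <- cm
  attr(m, "centroids") <- NULL
  attr(m, "filter_report") <- NULL
  class(m) <- c("matrix", "array")
  m
}

# Small random community matrix with positive row totals.
random_community <- function(n_sites, n_species) {
  m <- matrix(rpois(n_sites * n_species, lambda = 2), n_sites, n_species)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  rownames(m) <- as.character(seq_len(n_sites) - 1L)
  colnames(m) <- paste0("sp", seq_len(n_species))
  m
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(seq_len(n), seq_len(n))
  m
}
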