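# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# All generators route randomness through this so identical (config, seed)
# pairs are bit-identical regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Gaussian low-pass filter of a matrix via separable banded smoothing
# matrices with edge renormalization.
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > 3 * sigma] <- 0
    sweep(k, 1, rowSums(k), "/")
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Min-max rescale to [lo, hi]; constant input maps to the midpoint.
rescale01 <- function(x, lo = 0, hi = 1) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) return(x * 0 + (lo + hi) / 2)
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}
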