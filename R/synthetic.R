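#' Generate a synthetic world: environmental surfaces plus region classes
#'
#' Builds a stack of spatially smooth continuous environmental surfaces
#' (low-pass-filtered Gaussian noise superimposed on a monotone latitudinal
#' gradient, rescaled to variable-specific ranges) and one or two categorical
#' region grids obtained by k-means on pixel coordinates and environmental
#' values (coordinates weighted up so regions come out spatially coherent).
#' The result stands in for bioclimate/vegetation rasters and
#' ecoregion/climate-class maps when validating the analysis chain end to
#' end with known ground truth.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param grid_shape `c(rows, cols)`, at least 8 x 8.
#' @param n_env_vars number of continuous surfaces (>= 1). The first five are
#'   named `temp_like`, `precip_like`, `elev_like`, `treecover_like`,
#'   `herb_like` with ranges resembling those variables (degrees C, mm, m,
#'   percent cover); further surfaces are unit-range `envNN`.
#' @param n_classes number of region labels in `class_grid` (>= 1).
#' @param seed integer; same seed reproduces the world bit-identically.
#' @param gradient_only if `TRUE`, surfaces are pure latitudinal gradients
#'   (strictly monotone in the row index), no noise.
#' @param smoothness Gaussian smoothing bandwidth in pixels.
#' @param n_climes classes in the secondary (coarser, climate-like) class
#'   grid; `0` suppresses it.
#' @return an object of class `synthetic_world`: list with `extent`,
#'   `grid_shape`, `env_stack` (named list of [raster_grid()]),
#'   `class_grid`, `clime_grid` (or `NULL`), `seed`.
#' @export
generate_world <- function(extent, grid_shape, n_env_vars = 5, n_classes = 6,
                           seed = 1, gradient_only = FALSE, smoothness = 2,
                           n_climes = max(0L, ceiling(n_classes / 2))) {
  stopifnot(length(extent) == 4, length(grid_shape) == 2)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent: zero or negative width/height")
  if (any(grid_shape < 8)) stop("grid_shape must be at least 8 x 8")
  if (n_env_vars < 1) stop("need at least one environmental variable")
  if (n_classes < 1) stop("need at least one class")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  xres <- (extent[2] - extent[1]) / nc
  yres <- (extent[4] - extent[3]) / nr

  canon <- c(temp_like = NA, precip_like = NA, elev_like = NA,
             treecover_like = NA, herb_like = NA)
  ranges <- list(temp_like = c(-5, 25), precip_like = c(0, 2000),
                 elev_like = c(0, 2500), treecover_like = c(0, 100),
                 herb_like = c(0, 100))
  nm <- c(names(canon), sprintf("env%02d", seq_len(max(0, n_env_vars - 5)) + 5))
  nm <- nm[seq_len(n_env_vars)]

  env_stack <- with_seed(seed, {
    lapply(stats::setNames(nm, nm), function(v) {
      grad <- matrix(seq(1, 0, length.out = nr), nr, nc)   # north high
      if (gradient_only) {
        surf <- grad
      } else {
        gw <- stats::runif(1, 0.6, 1.4)
        noise <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
        surf <- gw * grad + rescale01(noise) # noise and gradient on comparable scales
      }
      rg <- if (v %in% names(ranges)) ranges[[v]] else c(0, 1)
      raster_grid(rescale01(surf, rg[1], rg[2]),
                  xmin = extent[1], ymax = extent[4], xres = xres, yres = yres)
    })
  })

  make_classes <- function(k, sub_seed) {
    if (k == 1L) return(raster_grid(matrix(0L, nr, nc), extent[1], extent[4],
                                    xres, yres))
    sc <- function(x) { s <- stats::sd(x); if (s == 0) x * 0 else (x - mean(x)) / s }
    feats <- cbind(
      3 * sc(as.vector(row(env_stack[[1]]$values))),
      3 * sc(as.vector(col(env_stack[[1]]$values))),
      vapply(env_stack, function(g) sc(as.vector(g$values)),
             numeric(nr * nc)))
    km <- with_seed(sub_seed, stats::kmeans(feats, centers = k, nstart = 5,
                                            iter.max = 50))
    lab <- km$cluster
    lab <- as.integer(factor(lab, levels = unique(lab))) - 1L # contiguous from 0
    raster_grid(matrix(lab, nr, nc), extent[1], extent[4], xres, yres)
  }
  class_grid <- make_classes(as.integer(n_classes), seed + 1L)
  clime_grid <- if (n_climes >= 1) make_classes(as.integer(n_climes), seed + 2L)
                else NULL

  structure(list(extent = extent, grid_shape = c(nr, nc),
                 env_stack = env_stack, class_grid = class_grid,
                 clime_grid = clime_grid, seed = as.integer(seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d x %d pixels, %d env vars (%s), %d classes, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], length(x$env_stack),
              paste(names(x$env_stack), collapse = ", "),
              length(unique(as.vector(x$class_grid$values))), x$seed))
  invisible(x)
}

#' Generate a species pool with Gaussian niches and spatial range discs
#'
#' Each species has a niche optimum drawn uniformly within the observed range
#' of every environmental variable, a strictly positive niche breadth per
#' variable, a peak abundance rate, and a hard circular dispersal range
#' (center + radius, degrees). Expected abundance at a pixel is
#' `max_intensity * exp(-sum_v (e_v - opt_v)^2 / (2 breadth_v^2))` inside the
#' range disc and 0 outside — the simplest generative model combining
#' environmental filtering with dispersal limitation.
#'
#' @param world a [generate_world()] result.
#' @param n_species number of species (>= 1).
#' @param seed integer seed.
#' @param breadth_frac range (fractions of each variable's observed range)
#'   from which niche breadths are drawn.
#' @param radius_frac range (fractions of the extent half-diagonal) from
#'   which range radii are drawn.
#' @return an object of class `species_pool`.
#' @export
generate_species_pool <- function(world, n_species, seed = 1,
                                  breadth_frac = c(0.15, 0.5),
                                  radius_frac = c(0.4, 1.0)) {
  stopifnot(inherits(world, "synthetic_world"), n_species >= 1)
  env_rng <- vapply(world$env_stack, function(g) range(g$values, na.rm = TRUE),
                    numeric(2))
  nv <- length(world$env_stack)
  ext <- world$extent
  half_diag <- sqrt((ext[2] - ext[1])^2 + (ext[4] - ext[3])^2) / 2
  with_seed(seed, {
    opt <- vapply(seq_len(nv), function(v)
      stats::runif(n_species, env_rng[1, v], env_rng[2, v]), numeric(n_species))
    bre <- vapply(seq_len(nv), function(v)
      stats::runif(n_species, breadth_frac[1], breadth_frac[2]) *
        (env_rng[2, v] - env_rng[1, v]), numeric(n_species))
    opt <- matrix(opt, n_species, nv,
                  dimnames = list(NULL, names(world$env_stack)))
    bre <- matrix(bre, n_species, nv,
                  dimnames = list(NULL, names(world$env_stack)))
    structure(list(
      species = sprintf("sp%03d", seq_len(n_species)),
      niche_optimum = opt,
      niche_breadth = bre,
      max_intensity = stats::rlnorm(n_species, meanlog = 0, sdlog = 0.5),
      range_center = cbind(lon = stats::runif(n_species, ext[1], ext[2]),
                           lat = stats::runif(n_species, ext[3], ext[4])),
      range_radius = stats::runif(n_species, radius_frac[1], radius_frac[2]) *
        half_diag,
      seed = as.integer(seed)), class = "species_pool")
  })
}

#' Expected (noise-free) abundance of every species at every pixel
#'
#' @param world a [generate_world()] result.
#' @param pool a [generate_species_pool()] result.
#' @return matrix of expected abundances, pixels x species; pixel `p` is grid
#'   cell `(row, col)` with `p = (row - 1) * ncols + col` (row-major), and the
#'   cell index table is attached as attribute `"cells"`.
#' @export
expected_abundance <- function(world, pool) {
  g1 <- world$env_stack[[1]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  cells <- cbind(row = rep(seq_len(nr), each = nc),
                 col = rep(seq_len(nc), times = nr))
  ctr <- xy_from_cell(g1, cells)
  env <- vapply(world$env_stack, function(g) g$values[cells], numeric(nrow(cells)))
  n_sp <- length(pool$species)
  lam <- matrix(0, nrow(cells), n_sp, dimnames = list(NULL, pool$species))
  # pixel containing each species' range center (kept in-range even at radius 0)
  home <- cell_from_xy(g1, pool$range_center)
  for (s in seq_len(n_sp)) {
    q <- rowSums(sweep(sweep(env, 2, pool$niche_optimum[s, ], "-")^2,
                       2, 2 * pool$niche_breadth[s, ]^2, "/"))
    d <- sqrt((ctr[, "lon"] - pool$range_center[s, "lon"])^2 +
              (ctr[, "lat"] - pool$range_center[s, "lat"])^2)
    inr <- d <= pool$range_radius[s]
    inr[(home[s, "row"] - 1L) * nc + home[s, "col"]] <- TRUE
    lam[, s] <- pool$max_intensity[s] * exp(-q) * inr
  }
  attr(lam, "cells") <- cells
  lam
}

#' Two-patch sampling-effort surface
#'
#' Emulates geographically uneven recording effort: one half of the extent is
#' sampled `ratio` times more intensively than the other.
#'
#' @param world a [generate_world()] result.
#' @param ratio effort ratio between the high and low patch (default 10).
#' @param split `"lon"` (west half high) or `"lat"` (north half high).
#' @return a [raster_grid()] of relative effort.
#' @export
effort_map <- function(world, ratio = 10, split = c("lon", "lat")) {
  split <- match.arg(split)
  g1 <- world$env_stack[[1]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  v <- matrix(1, nr, nc)
  if (split == "lon") v[, seq_len(floor(nc / 2))] <- ratio
  else v[seq_len(floor(nr / 2)), ] <- ratio
  raster_grid(v, g1$xmin, g1$ymax, g1$xres, g1$yres)
}

#' Sample GBIF-like occurrence records from a synthetic world
#'
#' Records are drawn pixel-first (effort-weighted multinomial over pixels,
#' restricted to pixels where at least one species has positive expected
#' abundance), then species-within-pixel (multinomial over expected
#' abundances), and finally the coordinate is jittered uniformly within the
#' pixel so records are not grid-aligned.
#'
#' @param world a [generate_world()] result.
#' @param pool a [generate_species_pool()] result.
#' @param effort a [raster_grid()] of relative effort matching the world grid.
#' @param n_records number of records to draw (>= 1).
#' @param seed integer seed.
#' @return data frame with columns `species`, `decimalLatitude`,
#'   `decimalLongitude`.
#' @export
sample_occurrences <- function(world, pool, effort, n_records, seed = 1) {
  stopifnot(n_records >= 1)
  g1 <- world$env_stack[[1]]
  if (!same_geometry(g1, effort)) stop("effort grid geometry mismatch")
  if (any(effort$values < 0, na.rm = TRUE)) stop("negative effort")
  lam <- expected_abundance(world, pool)
  cells <- attr(lam, "cells")
  eff <- effort$values[cells]
  eff[is.na(eff)] <- 0
  w <- eff * (rowSums(lam) > 0)
  if (all(w == 0))
    stop("effort is zero everywhere that any species has support")
  with_seed(seed, {
    pix <- sample.int(length(w), n_records, replace = TRUE, prob = w)
    tab <- table(pix)
    idx <- as.integer(names(tab))
    sp_of <- integer(n_records)
    ord <- order(pix)
    pos <- 1L
    for (k in seq_along(idx)) {
      n_k <- as.integer(tab[k])
      draws <- sample.int(ncol(lam), n_k, replace = TRUE, prob = lam[idx[k], ])
      sp_of[ord[pos:(pos + n_k - 1L)]] <- draws
      pos <- pos + n_k
    }
    r <- cells[pix, "row"]; cc <- cells[pix, "col"]
    lon <- g1$xmin + (cc - 1L + stats::runif(n_records)) * g1$xres
    lat <- g1$ymax - (r - 1L + stats::runif(n_records)) * g1$yres
    data.frame(species = pool$species[sp_of],
               decimalLatitude = lat, decimalLongitude = lon)
  })
}

#' Ground-truth dissimilarity between two pixels
#'
#' Horn-Morisita dissimilarity computed on the expected (noise-free)
#' abundance vectors of two grid cells — the oracle against which estimates
#' from sampled records are compared.
#'
#' @param world a [generate_world()] result.
#' @param pool a [generate_species_pool()] result.
#' @param cellA,cellB integer `c(row, col)` pairs.
#' @return dissimilarity in `[0, 1]`.
#' @export
true_pair_dissimilarity <- function(world, pool, cellA, cellB) {
  g1 <- world$env_stack[[1]]
  nr <- nrow(g1$values); nc <- ncol(g1$values)
  chk <- function(cell) {
    if (cell[1] < 1 || cell[1] > nr || cell[2] < 1 || cell[2] > nc)
      stop("cell outside grid extent")
    as.integer((cell[1] - 1L) * nc + cell[2])
  }
  lam <- expected_abundance(world, pool)
  a <- lam[chk(cellA), ]; b <- lam[chk(cellB), ]
  if (sum(a) == 0 || sum(b) == 0)
    stop("dissimilarity undefined: cell with all-zero expected abundance")
  horn_morisita(a, b)
}

#' Write occurrence records as a Darwin-Core-style CSV
#'
#' @param table data frame with `species`, `decimalLatitude`,
#'   `decimalLongitude` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(table, path) {
  utils::write.csv(table[, c("species", "decimalLatitude", "decimalLongitude")],
                   path, row.names = FALSE)
  invisible(path)
}

#' The packaged fixture world
#'
#' One complete small scenario used throughout the test suite: a 24 x 24
#' grid over 12 x 12 degrees, 5 environmental variables, 6 ecoregion-like and
#' 3 climate-like classes, 40 species, two-patch (10:1) sampling effort, and
#' 20,000 occurrence records.
#'
#' @param seed integer seed (default 42).
#' @param n_records number of records (default 20000).
#' @return list with `world`, `pool`, `effort`, `occurrences`.
#' @export
fixture_world <- function(seed = 42, n_records = 20000) {
  world <- generate_world(extent = c(0, 12, 40, 52), grid_shape = c(24, 24),
                          n_env_vars = 5, n_classes = 6, n_climes = 3,
                          seed = seed)
  pool <- generate_species_pool(world, n_species = 40, seed = seed + 10L)
  eff <- effort_map(world, ratio = 10)
  occ <- sample_occurrences(world, pool, eff, n_records, seed = seed + 20L)
  list(world = world, pool = pool, effort = eff, occurrences = occ)
}
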