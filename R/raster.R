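#' Georeferenced raster grid
#'
#' Lightweight in-memory container for a single-band, north-up raster in
#' geographic coordinates. Row 1 is the northernmost row; cell values are
#' stored as a plain matrix with `NA` marking nodata. The affine transform is
#' restricted to the north-up, axis-aligned case (offsets plus positive pixel
#' sizes), which is all the package's extraction and mapping steps need.
#'
#' The cell-lookup convention is half-open: pixel `(r, c)` covers
#' `[xmin + (c-1)*xres, xmin + c*xres)` in longitude and
#' `(ymax - r*yres, ymax - (r-1)*yres]` running south from the top edge, so a
#' point lying exactly on an interior edge belongs to the pixel east/south of
#' that edge. Points on the extreme east/south boundary of the extent are
#' assigned to the last pixel so the closed extent is fully covered.
#'
#' @param values numeric or integer matrix, row 1 = north.
#' @param xmin west edge (decimal degrees).
#' @param ymax north edge (decimal degrees).
#' @param xres,yres pixel width and height in degrees (positive).
#' @param crs free-text coordinate system tag.
#' @param nodata sentinel written to/read from disk for `NA` cells.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymax, xres, yres = xres,
                        crs = "EPSG:4326", nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.finite(xres) || !is.finite(yres) || xres <= 0 || yres <= 0)
    stop("pixel sizes must be positive and finite")
  if (!is.finite(xmin) || !is.finite(ymax))
    stop("grid origin must be finite")
  if (any(values == nodata, na.rm = TRUE))
    stop("nodata sentinel collides with a data value; choose another sentinel")
  g <- structure(
    list(values = values, xmin = xmin, ymax = ymax,
         xres = xres, yres = yres, crs = crs, nodata = nodata),
    class = "raster_grid")
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  e <- grid_extent(x)
  cat(sprintf("raster_grid: %d x %d pixels, extent [%g, %g] x [%g, %g], res %g x %g (%s)\n",
              nrow(x$values), ncol(x$values), e[1], e[2], e[3], e[4],
              x$xres, x$yres, x$crs))
  cat(sprintf("  values: min %g, max %g, %d nodata cells\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Geographic extent of a grid
#'
#' @param g a `raster_grid`.
#' @return numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
grid_extent <- function(g) {
  c(xmin = g$xmin,
    xmax = g$xmin + ncol(g$values) * g$xres,
    ymin = g$ymax - nrow(g$values) * g$yres,
    ymax = g$ymax)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$xres - b$xres) < tol && abs(a$yres - b$yres) < tol
}

# Normalize point input to a 2-column matrix (lon, lat). Accepts a matrix or
# a data frame with lon/lat columns under common aliases.
as_lonlat <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(cbind(lon = as.numeric(points[, 1]), lat = as.numeric(points[, 2])))
  }
  pd <- as.data.frame(points)
  lon_alias <- intersect(c("lon", "longitude", "decimalLongitude", "x"), names(pd))
  lat_alias <- intersect(c("lat", "latitude", "decimalLatitude", "y"), names(pd))
  if (!length(lon_alias) || !length(lat_alias))
    stop("points need lon/lat columns (aliases: lon/longitude/decimalLongitude/x, ",
         "lat/latitude/decimalLatitude/y)")
  cbind(lon = as.numeric(pd[[lon_alias[1]]]), lat = as.numeric(pd[[lat_alias[1]]]))
}

#' Row/column of the pixel containing each point
#'
#' Half-open convention as documented in [raster_grid()]. Points outside the
#' closed extent are an error.
#'
#' @param g a `raster_grid`.
#' @param points matrix or data frame of lon/lat coordinates.
#' @return integer matrix with columns `row`, `col`.
#' @export
cell_from_xy <- function(g, points) {
  p <- as_lonlat(points)
  e <- grid_extent(g)
  if (any(!is.finite(p))) stop("non-finite point coordinates")
  tol <- 1e-9
  out_x <- p[, "lon"] < e["xmin"] - tol | p[, "lon"] > e["xmax"] + tol
  out_y <- p[, "lat"] < e["ymin"] - tol | p[, "lat"] > e["ymax"] + tol
  if (any(out_x | out_y)) {
    i <- which(out_x | out_y)[1]
    stop(sprintf("point %d (%.6g, %.6g) outside grid extent", i,
                 p[i, "lon"], p[i, "lat"]))
  }
  col <- floor((p[, "lon"] - g$xmin) / g$xres) + 1L
  row <- floor((g$ymax - p[, "lat"]) / g$yres) + 1L
  col <- pmin(pmax(col, 1L), ncol(g$values))
  row <- pmin(pmax(row, 1L), nrow(g$values))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Pixel-center coordinates
#'
#' @param g a `raster_grid`.
#' @param cells integer matrix with columns `row`, `col`.
#' @return matrix with columns `lon`, `lat` of pixel centers.
#' @export
xy_from_cell <- function(g, cells) {
  cells <- rbind(cells)
  cbind(lon = g$xmin + (cells[, "col"] - 0.5) * g$xres,
        lat = g$ymax - (cells[, "row"] - 0.5) * g$yres)
}

#' Coarsen a grid by an integer factor (nearest valid neighbor)
#'
#' Each coarse pixel aggregates a `factor` x `factor` block of source pixels
#' (truncated at the south/east edges). Its value is taken from the block's
#' constituent pixel nearest to the coarse pixel center, restricted to pixels
#' holding data; the coarse pixel is nodata only when the whole block is.
#' This "nearest valid neighbor" rule preserves the nearest-neighbor contract
#' (every coarse value is one of its constituents) while guaranteeing that a
#' block with any data yields data, which is what progressive-fallback
#' extraction needs.
#'
#' @param g a `raster_grid`.
#' @param factor integer >= 1.
#' @return a `raster_grid` with pixel size multiplied by `factor`.
#' @export
coarsen_grid <- function(g, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(g)
  nr <- nrow(g$values); nc <- ncol(g$values)
  cnr <- ceiling(nr / factor); cnc <- ceiling(nc / factor)
  out <- matrix(NA_real_, cnr, cnc)
  for (r in seq_len(cnr)) {
    rows <- ((r - 1L) * factor + 1L):min(r * factor, nr)
    rc <- (r - 1L) * factor + (factor + 1) / 2     # block center, source row units
    for (c in seq_len(cnc)) {
      cols <- ((c - 1L) * factor + 1L):min(c * factor, nc)
      block <- g$values[rows, cols, drop = FALSE]
      ok <- which(!is.na(block), arr.ind = TRUE)
      if (nrow(ok) == 0L) next
      cc <- (c - 1L) * factor + (factor + 1) / 2
      d2 <- (rows[ok[, 1]] - rc)^2 + (cols[ok[, 2]] - cc)^2
      pick <- ok[which.min(d2), , drop = FALSE]
      out[r, c] <- block[pick[1, 1], pick[1, 2]]
    }
  }
  raster_grid(out, g$xmin, g$ymax, g$xres * factor, g$yres * factor,
              crs = g$crs, nodata = g$nodata)
}

#' Extract raster values at points with progressive coarsening fallback
#'
#' The primary value is that of the pixel containing each point. Where that
#' pixel is nodata the grid is coarsened by integer factors 2, 3, ... up to
#' `max_fallback_factor` (nearest-valid-neighbor resampling, see
#' [coarsen_grid()]) and the first valid value found is used; the factor is
#' recorded as provenance. Points still unresolved at the maximum factor get
#' an explicit missing flag, never a silent fill.
#'
#' @param g a `raster_grid`.
#' @param points matrix or data frame of lon/lat coordinates.
#' @param max_fallback_factor largest coarsening factor tried (default 8).
#' @return data frame with columns `value`, `factor`, `missing`.
#' @export
extract_at_points <- function(g, points, max_fallback_factor = 8) {
  p <- as_lonlat(points)
  cells <- cell_from_xy(g, p)
  value <- as.numeric(g$values[cbind(cells[, "row"], cells[, "col"])])
  fac <- rep(1L, nrow(p))
  todo <- which(is.na(value))
  f <- 2L
  while (length(todo) && f <= max_fallback_factor) {
    cg <- coarsen_grid(g, f)
    ccells <- cell_from_xy(cg, p[todo, , drop = FALSE])
    v <- cg$values[cbind(ccells[, "row"], ccells[, "col"])]
    hit <- !is.na(v)
    value[todo[hit]] <- v[hit]
    fac[todo[hit]] <- f
    todo <- todo[!hit]
    f <- f + 1L
  }
  missing <- is.na(value)
  fac[missing] <- NA_integer_
  data.frame(value = value, factor = fac, missing = missing)
}

#' Per-pixel median composite of a raster stack
#'
#' Median over grids of identical geometry, ignoring nodata; a pixel is
#' nodata in the composite only if it is nodata in every input. With an even
#' number of valid values the median is the mean of the two central ones.
#'
#' @param grids list of `raster_grid` with identical geometry.
#' @return a `raster_grid`.
#' @export
median_composite <- function(grids) {
  stopifnot(length(grids) >= 1)
  g1 <- grids[[1]]
  for (g in grids[-1])
    if (!same_geometry(g1, g)) stop("raster geometry mismatch in composite")
  arr <- vapply(grids, function(g) g$values,
                matrix(0, nrow(g1$values), ncol(g1$values)))
  dim(arr) <- c(length(g1$values), length(grids))
  med <- apply(arr, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  })
  raster_grid(matrix(med, nrow(g1$values), ncol(g1$values)),
              g1$xmin, g1$ymax, g1$xres, g1$yres, crs = g1$crs,
              nodata = g1$nodata)
}

#' Class labels of the pixels containing points
#'
#' Direct pixel lookup on a categorical grid; no coarsening fallback (class
#' grids are assumed exhaustive). Nodata class pixels yield `NA` plus a
#' missing flag.
#'
#' @param class_grid integer-labelled `raster_grid`.
#' @param points matrix or data frame of lon/lat coordinates.
#' @return data frame with columns `label`, `missing`.
#' @export
classify_points <- function(class_grid, points) {
  cells <- cell_from_xy(class_grid, points)
  lab <- class_grid$values[cbind(cells[, "row"], cells[, "col"])]
  data.frame(label = lab, missing = is.na(lab))
}

#' Synthesize latitude/longitude rasters matching a grid's geometry
#'
#' Used when geographic position itself is a model predictor that must be
#' transformed pixelwise like any environmental layer.
#'
#' @param g a `raster_grid`.
#' @return named list of two `raster_grid`s, `lat` and `lon`.
#' @export
latlon_grids <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  lat <- matrix(g$ymax - (seq_len(nr) - 0.5) * g$yres, nr, nc)
  lon <- matrix(g$xmin + (seq_len(nc) - 0.5) * g$xres, nr, nc, byrow = TRUE)
  list(lat = raster_grid(lat, g$xmin, g$ymax, g$xres, g$yres, crs = g$crs),
       lon = raster_grid(lon, g$xmin, g$ymax, g$xres, g$yres, crs = g$crs))
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text, GDAL-readable interchange format (requires square pixels).
#' `NA` cells are written as the grid's nodata sentinel.
#'
#' @param g a `raster_grid` with `xres == yres`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  if (abs(g$xres - g$yres) > 1e-12)
    stop("ESRI ASCII grids require square pixels")
  e <- grid_extent(g)
  v <- g$values
  v[is.na(v)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.12g", e["xmin"]),
               sprintf("yllcorner %.12g", e["ymin"]),
               sprintf("cellsize %.12g", g$xres),
               sprintf("NODATA_value %.12g", g$nodata)), con)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.12g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any ESRI ASCII grid.
#' @param crs coordinate system tag to attach.
#' @return a `raster_grid`.
#' @export
read_ascii_grid <- function(path, crs = "EPSG:4326") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  v <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  v[v == nodata] <- NA_real_
  raster_grid(v, xmin = hdr$xllcorner,
              ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
              xres = hdr$cellsize, yres = hdr$cellsize,
              crs = crs, nodata = nodata)
}
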