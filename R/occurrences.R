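#' Read a Darwin-Core-style occurrence CSV
#'
#' Reads species/latitude/longitude columns (common Darwin Core aliases
#' accepted), drops rows with unparseable or out-of-range coordinates or an
#' empty species identifier, and reports what was dropped — rows are never
#' silently lost.
#'
#' @param path CSV file path.
#' @param aliases named list of accepted column names for `species`, `lat`,
#'   `lon` (first match wins).
#' @return list with `table` (data frame: `species`, `decimalLatitude`,
#'   `decimalLongitude`) and `report` (named counts: `n_read`, `n_kept`,
#'   `n_dropped_coord`, `n_dropped_species`).
#' @export
read_occurrences <- function(path,
                             aliases = list(
                               species = c("species", "scientificName", "taxon"),
                               lat = c("decimalLatitude", "lat", "latitude"),
                               lon = c("decimalLongitude", "lon", "longitude"))) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(role) {
    hit <- intersect(aliases[[role]], names(raw))
    if (!length(hit))
      stop(sprintf("missing required column for '%s' (accepted: %s)",
                   role, paste(aliases[[role]], collapse = ", ")))
    hit[1]
  }
  sp <- as.character(raw[[pick("species")]])
  lat <- suppressWarnings(as.numeric(raw[[pick("lat")]]))
  lon <- suppressWarnings(as.numeric(raw[[pick("lon")]]))
  bad_sp <- is.na(sp) | sp == ""
  bad_co <- !is.finite(lat) | !is.finite(lon) |
    lat < -90 | lat > 90 | lon < -180 | lon > 180
  keep <- !bad_sp & !bad_co
  list(table = data.frame(species = sp[keep], decimalLatitude = lat[keep],
                          decimalLongitude = lon[keep]),
       report = c(n_read = nrow(raw), n_kept = sum(keep),
                  n_dropped_coord = sum(bad_co & !bad_sp),
                  n_dropped_species = sum(bad_sp)))
}

#' Remove records in 0.1-degree cells straddling a class boundary
#'
#' Records are binned by their coordinates rounded to one decimal place
#' (cells of roughly 5 km half-width). A bin is treated as a boundary bin —
#' and all its records removed — when the categorical grid is not uniform
#' under it. Two readings of "not uniform" are provided: `"cell"` (default)
#' probes the class grid at the bin's four corners and center, which is
#' record-independent; `"records"` compares the classes under the actual
#' record coordinates in the bin.
#'
#' @param table occurrence data frame (`species`, `decimalLatitude`,
#'   `decimalLongitude`).
#' @param class_grid categorical [raster_grid()] covering all records.
#' @param rule `"cell"` or `"records"`.
#' @return list with `table` (retained records), `n_removed`, and
#'   `boundary_bins` (count).
#' @export
remove_boundary_records <- function(table, class_grid,
                                    rule = c("cell", "records")) {
  rule <- match.arg(rule)
  if (nrow(table) == 0)
    return(list(table = table, n_removed = 0L, boundary_bins = 0L))
  ext <- grid_extent(class_grid)
  lon <- table$decimalLongitude; lat <- table$decimalLatitude
  outside <- lon < ext["xmin"] | lon > ext["xmax"] |
             lat < ext["ymin"] | lat > ext["ymax"]
  if (any(outside))
    stop("records outside class grid extent (rows ",
         paste(utils::head(which(outside), 5), collapse = ", "), ")")
  rlat <- round(lat, 1); rlon <- round(lon, 1)
  bin <- paste(rlat, rlon)
  ub <- !duplicated(bin)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  is_boundary_bin <- vapply(which(ub), function(k) {
    if (rule == "cell") {
      px <- clamp(rlon[k] + c(0, -0.05, -0.05, 0.05, 0.05),
                  ext["xmin"], ext["xmax"])
      py <- clamp(rlat[k] + c(0, -0.05, 0.05, -0.05, 0.05),
                  ext["ymin"], ext["ymax"])
    } else {
      sel <- bin == bin[k]
      px <- lon[sel]; py <- lat[sel]
    }
    cls <- classify_points(class_grid, cbind(px, py))$label
    length(unique(cls[!is.na(cls)])) > 1
  }, logical(1))
  bad_bins <- bin[ub][is_boundary_bin]
  drop <- bin %in% bad_bins
  list(table = table[!drop, , drop = FALSE],
       n_removed = sum(drop), boundary_bins = length(bad_bins))
}

#' Tally records into a site-by-species community matrix
#'
#' @param table occurrence data frame.
#' @param assignment a [cluster_sites()] result covering every record.
#' @return a `community_matrix`: integer matrix (sites x species, site ids as
#'   row names) carrying the site centroid table as attribute `"centroids"`.
#' @export
build_community_matrix <- function(table, assignment) {
  stopifnot(inherits(assignment, "site_assignment"),
            nrow(table) == length(assignment$site_id))
  sites <- sort(unique(assignment$site_id))
  species <- sort(unique(table$species))
  m <- table(factor(assignment$site_id, levels = sites),
             factor(table$species, levels = species))
  m <- matrix(as.integer(m), nrow = length(sites),
              dimnames = list(as.character(sites), species))
  structure(m, class = c("community_matrix", class(m)),
            centroids = assignment$sites)
}

unclass_cm <- function(cm) {
  m <- cm
  attr(m, "centroids") <- NULL
  attr(m, "filter_report") <- NULL
  class(m) <- setdiff(class(m), "community_matrix")
  m
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species, %d records\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Iteratively filter sparse species and under-sampled sites
#'
#' Removes species occurring at fewer than `min_sites_per_species` sites and
#' sites with total abundance below `min_obs_per_site`, repeating both rules
#' until a fixed point is reached, so the output is guaranteed to satisfy
#' both thresholds simultaneously. Default thresholds (30 sites per species,
#' 300 observations per site) are those used for continental-scale record
#' sets; scale them down for smaller data.
#'
#' @param cm a [build_community_matrix()] result.
#' @param min_sites_per_species minimum number of occupied sites per species.
#' @param min_obs_per_site minimum total abundance per site.
#' @return filtered `community_matrix` with attribute `"filter_report"` (data
#'   frame of per-pass removal counts).
#' @export
filter_matrix <- function(cm, min_sites_per_species = 30,
                          min_obs_per_site = 300) {
  stopifnot(min_sites_per_species >= 1, min_obs_per_site >= 1)
  cent <- attr(cm, "centroids")
  m <- unclass_cm(cm)
  report <- data.frame(pass = integer(), species_removed = integer(),
                       sites_removed = integer())
  pass <- 0L
  repeat {
    pass <- pass + 1L
    sp_keep <- colSums(m > 0) >= min_sites_per_species
    m2 <- m[, sp_keep, drop = FALSE]
    site_keep <- rowSums(m2) >= min_obs_per_site
    m2 <- m2[site_keep, , drop = FALSE]
    report <- rbind(report, data.frame(pass = pass,
                                       species_removed = sum(!sp_keep),
                                       sites_removed = sum(!site_keep)))
    changed <- any(!sp_keep) || any(!site_keep)
    m <- m2
    if (!changed) break
    if (nrow(m) == 0 || ncol(m) == 0) stop("no data survive filters")
  }
  if (nrow(m) == 0 || ncol(m) == 0) stop("no data survive filters")
  if (!is.null(cent)) cent <- cent[cent$site %in% as.integer(rownames(m)), ]
  structure(m, class = c("community_matrix", "matrix", "array"),
            centroids = cent, filter_report = report)
}

#' Write a community matrix (and its site table) as CSV
#'
#' Matrix CSV has the site id in the first column and species ids as header,
#' matching the deposited site-by-species table shape; the site table CSV has
#' columns `site`, `lat`, `lon`, `n_records`.
#'
#' @param cm a `community_matrix`.
#' @param path matrix CSV path.
#' @param site_path optional site-table CSV path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path, site_path = NULL) {
  m <- unclass_cm(cm)
  utils::write.csv(data.frame(site = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  if (!is.null(site_path))
    utils::write.csv(attr(cm, "centroids"), site_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_matrix
#' @param site_path site-table CSV written alongside, if available.
#' @export
read_community_matrix <- function(path, site_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  cent <- if (!is.null(site_path)) utils::read.csv(site_path) else NULL
  structure(m, class = c("community_matrix", "matrix", "array"),
            centroids = cent)
}
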