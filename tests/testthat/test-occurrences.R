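write_occ_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

test_that("occurrence reading validates coordinates and reports drops", {
  f <- write_occ_csv(data.frame(species = c("a", "b", "a"),
                                decimalLatitude = c(10, 20, -30),
                                decimalLongitude = c(1, 2, 3)))
  r <- read_occurrences(f)
  expect_equal(nrow(r$table), 3)
  expect_equal(unname(r$report["n_read"] - r$report["n_kept"]), 0)

  f2 <- write_occ_csv(data.frame(species = c("a", "b"),
                                 decimalLatitude = c(95, 20),
                                 decimalLongitude = c(1, 2)))
  r2 <- read_occurrences(f2)
  expect_equal(nrow(r2$table), 1)
  expect_equal(unname(r2$report["n_dropped_coord"]), 1)

  f3 <- write_occ_csv(data.frame(species = character(),
                                 decimalLatitude = numeric(),
                                 decimalLongitude = numeric()))
  r3 <- read_occurrences(f3)
  expect_equal(nrow(r3$table), 0)

  f4 <- write_occ_csv(data.frame(species = "a", decimalLatitude = 1))
  expect_error(read_occurrences(f4), "decimalLongitude")

  # Darwin Core aliases accepted
  f5 <- write_occ_csv(data.frame(scientificName = "a", lat = 5, lon = 6))
  expect_equal(read_occurrences(f5)$table$species, "a")
})

test_that("boundary bins straddling two classes are removed", {
  # vertical class boundary at lon = 0
  cl <- raster_grid(cbind(matrix(0L, 20, 10), matrix(1L, 20, 10)),
                    xmin = -1, ymax = 1, xres = 0.1)
  tab <- data.frame(species = c("a", "b", "c"),
                    decimalLatitude = c(0.52, 0.52, 0.04),
                    decimalLongitude = c(-0.54, 0.56, 0.04))
  out <- remove_boundary_records(tab, cl)
  # the record at lon 0.04 rounds to bin lon 0.0 whose corners straddle the
  # boundary; the others sit in uniform bins
  expect_equal(out$n_removed, 1)
  expect_equal(out$table$species, c("a", "b"))

  uni <- raster_grid(matrix(2L, 20, 20), xmin = -1, ymax = 1, xres = 0.1)
  out2 <- remove_boundary_records(tab, uni)
  expect_equal(out2$n_removed, 0)
  expect_identical(out2$table, tab)

  empty <- tab[0, ]
  expect_equal(nrow(remove_boundary_records(empty, cl)$table), 0)

  far <- data.frame(species = "x", decimalLatitude = 5, decimalLongitude = 0)
  expect_error(remove_boundary_records(far, cl), "outside")
})

test_that("record-based boundary rule keys on actual record classes", {
  cl <- raster_grid(cbind(matrix(0L, 20, 10), matrix(1L, 20, 10)),
                    xmin = -1, ymax = 1, xres = 0.1)
  # two records in the same 0.1-degree bin but on opposite sides of lon 0
  tab <- data.frame(species = c("a", "b"),
                    decimalLatitude = c(0.5, 0.5),
                    decimalLongitude = c(-0.01, 0.01))
  expect_equal(remove_boundary_records(tab, cl, rule = "records")$n_removed, 2)
  # a single record near the boundary is kept under the record rule ...
  one <- tab[2, ]
  expect_equal(remove_boundary_records(one, cl, rule = "records")$n_removed, 0)
  # ... but removed under the cell rule
  expect_equal(remove_boundary_records(one, cl, rule = "cell")$n_removed, 1)
})

test_that("community matrix tallies records exactly and conserves totals", {
  tab <- data.frame(species = c("x", "x", "y", "x", "y", "y", "y"),
                    decimalLatitude = c(1, 1, 1, 5, 5, 9, 9),
                    decimalLongitude = c(1, 1, 1, 5, 5, 9, 9))
  ass <- cluster_sites(tab)
  cm <- build_community_matrix(tab, ass)
  expect_equal(sum(cm), nrow(tab))                    # conservation
  expect_equal(dim(cm), c(3L, 2L))
  # hand tally: site of (1,1) has 2 x + 1 y; (5,5) 1 x + 1 y; (9,9) 2 y
  expect_equal(as.vector(unclass_cm_for_test(cm)), c(2, 1, 0, 1, 1, 2))
  # two records, same site and species -> single entry of 2
  t2 <- tab[1:2, ]
  cm2 <- build_community_matrix(t2, cluster_sites(t2))
  expect_equal(as.vector(cm2[1, "x"]), 2L)
})

test_that("filtering reaches the documented fixed point on a toy matrix", {
  # 4 sites x 3 species; thresholds (2 sites/species, 3 records/site):
  # species C occurs at 1 site -> dropped; site 4 then totals 2 -> dropped
  m <- matrix(c(3, 0, 0,
                2, 1, 0,
                1, 2, 0,
                1, 1, 4), 4, 3, byrow = TRUE,
              dimnames = list(as.character(1:4), c("A", "B", "C")))
  cm <- structure(m, class = c("community_matrix", "matrix", "array"))
  got <- filter_matrix(cm, min_sites_per_species = 2, min_obs_per_site = 3)
  expect_equal(rownames(got), c("1", "2", "3"))
  expect_equal(colnames(got), c("A", "B"))
  expect_equal(unclass_cm_for_test(got),
               oracle_filter_fixed_point(m, 2, 3))
  # already-clean matrices and (1,1) thresholds are no-ops
  clean <- matrix(2, 3, 2, dimnames = list(as.character(1:3), c("A", "B")))
  ccm <- structure(clean, class = c("community_matrix", "matrix", "array"))
  expect_equal(unclass_cm_for_test(filter_matrix(ccm, 2, 3)), clean)
  expect_equal(unclass_cm_for_test(filter_matrix(ccm, 1, 1)), clean)
  expect_error(filter_matrix(ccm, 10, 1000), "no data survive")
})

test_that("filter fixed point is order-invariant and matches brute force", {
  set.seed(31)
  for (rep in 1:25) {
    m <- random_community(sample(4:10, 1), sample(3:8, 1))
    ms <- sample(1:3, 1); mo <- sample(2:6, 1)
    o1 <- oracle_filter_fixed_point(m, ms, mo, "species_first")
    o2 <- oracle_filter_fixed_point(m, ms, mo, "sites_first")
    cm <- structure(m, class = c("community_matrix", "matrix", "array"))
    got <- tryCatch(filter_matrix(cm, ms, mo), error = function(e) e)
    if (nrow(o1) == 0 || ncol(o1) == 0) {
      expect_s3_class(got, "error")
    } else {
      expect_equal(unclass_cm_for_test(got), o1)
      expect_equal(unclass_cm_for_test(got), o2)
    }
  }
})
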