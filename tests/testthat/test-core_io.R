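test_that("Esri ASCII rasters read, mask nodata and round-trip exactly", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "g.asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "NODATA_value -9999",
               "1 2 3", "1 -9999 3", "-9999 2 3"), p)
  g <- read_raster(p, "categorical")
  expect_s3_class(g, "land_cover_grid")
  expect_equal(sum(g$mask), 7)
  expect_equal(g$codes[1, ], c(1L, 2L, 3L))
  expect_true(is.na(g$codes[2, 2]))

  # full-grid identity read
  p2 <- file.path(tmp, "full.asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 5", "1 1 2", "2 2 2", "3 3 3"), p2)
  g2 <- read_raster(p2, "categorical")
  expect_equal(sum(g2$mask), 9)
  expect_equal(g2$cell_size_m, 5)

  # round trip, categorical and continuous
  p3 <- file.path(tmp, "rt.asc")
  write_raster(g, p3)
  g3 <- read_raster(p3, "categorical")
  expect_identical(g3$codes, g$codes)
  expect_identical(g3$mask, g$mask)

  dem <- elevation_grid(matrix(c(1.25, -2.5, 3.75, 0.125), 2, 2), 12.5)
  p4 <- file.path(tmp, "dem.asc")
  write_raster(dem, p4)
  dem2 <- read_raster(p4, "continuous")
  expect_equal(dem2$elevation_m, dem$elevation_m)
  expect_equal(dem2$cell_size_m, 12.5)
})

test_that("raster errors are explicit", {
  tmp <- withr::local_tempdir()
  expect_error(read_raster(file.path(tmp, "nope.asc"), "categorical"),
               "not found")
  p <- file.path(tmp, "bad.asc")
  writeLines(c("ncols 2", "nrows 2", "1 2 3"), p) # wrong cell count
  expect_error(read_raster(p, "continuous", cell_size_m = 1), "expected 4")
  p2 <- file.path(tmp, "nocell.asc")
  writeLines(c("ncols 2", "nrows 1", "1 2"), p2)
  expect_error(read_raster(p2, "continuous"), "cell_size_m")
  expect_no_error(read_raster(p2, "continuous", cell_size_m = 10))
  p3 <- file.path(tmp, "frac.asc")
  writeLines(c("ncols 2", "nrows 1", "cellsize 1", "1.5 2"), p3)
  expect_error(read_raster(p3, "categorical"), "non-integer")
})

test_that("panoramas round-trip through PPM/PGM with sidecars", {
  tmp <- withr::local_tempdir()
  set.seed(42)
  rgb <- array(sample(0:255, 5 * 4 * 3, replace = TRUE), dim = c(5, 4, 3))
  sky <- matrix(c(rep(TRUE, 8), rep(FALSE, 12)), 5, 4)
  labels <- matrix(sample(1:6, 20, replace = TRUE), 5, 4)
  im <- panorama(rgb, sky_mask = sky, layer_labels = labels)
  p <- file.path(tmp, "pano.ppm")
  write_panorama(im, p)
  im2 <- read_panorama(p)
  expect_equal(im2$rgb, im$rgb)
  expect_identical(im2$sky_mask, im$sky_mask)
  expect_equal(im2$layer_labels, im$layer_labels,
               ignore_attr = "storage.mode")
})

test_that("read_reviews cleans empty text and validates targets", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "rev.csv")
  write.csv(data.frame(park_id = c("A", "A", "A"),
                       target = c("landscape", "park", "park"),
                       text = c("nice", "", "ok")),
            p, row.names = FALSE)
  r <- read_reviews(p)
  expect_equal(nrow(r), 2)
  expect_equal(attr(r, "n_dropped"), 1)

  # duplicates retained
  write.csv(data.frame(park_id = "A", target = "park",
                       text = c("same", "same")), p, row.names = FALSE)
  expect_equal(nrow(read_reviews(p)), 2)

  write.csv(data.frame(park_id = "A", target = c("park", "garden"),
                       text = c("x", "y")), p, row.names = FALSE)
  expect_error(read_reviews(p), "garden")
  expect_error(read_reviews(p), "row 2")
})

test_that("review volumes built from the published counts match them", {
  t5 <- waterscape_fixture("table5")
  rows <- do.call(rbind, lapply(seq_len(nrow(t5)), function(i) {
    sp <- scene_spec(review_spec = list(
      n_landscape = t5$n_landscape[i], n_park = t5$n_park[i],
      pos_frac_landscape = 0.7, pos_frac_park = 0.4))
    gen_reviews(sp, t5$park_id[i])
  }))
  totals <- table(rows$park_id[rows$target == "park"])
  expect_equal(as.integer(totals[t5$park_id]), t5$n_park)
  ls_totals <- table(rows$park_id[rows$target == "landscape"])
  expect_equal(as.integer(ls_totals[t5$park_id]), t5$n_landscape)
})

test_that("run_config validates invariants and round-trips as JSON", {
  expect_error(run_config(thermal_thresholds = c(5, 2)))
  expect_error(run_config(coupling_weights = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(run_config(kde_bandwidth_m = -1))
  cfg <- run_config(seed = 99L, cell_size_m = 15)
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "cfg.json")
  write_run_config(cfg, p)
  cfg2 <- read_run_config(p)
  expect_equal(cfg2$seed, 99L)
  expect_equal(cfg2$cell_size_m, 15)
  expect_equal(cfg2$normalization_bounds, cfg$normalization_bounds)
  expect_equal(cfg2$hemeroby_degrees, cfg$hemeroby_degrees)
})
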