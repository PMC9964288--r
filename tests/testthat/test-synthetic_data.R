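test_that("generators are pure functions of the spec", {
  sp <- scene_spec(seed = 7L, shape = c(40L, 40L))
  expect_identical(gen_landcover(sp)$codes, gen_landcover(sp)$codes)
  t1 <- gen_terrain(sp); t2 <- gen_terrain(sp)
  expect_identical(t1$dem$elevation_m, t2$dem$elevation_m)
  hv1 <- gen_heat_and_visitors(sp); hv2 <- gen_heat_and_visitors(sp)
  expect_identical(hv1$visitors$points, hv2$visitors$points)
  expect_identical(hv1$snapshots[[1]]$values, hv2$snapshots[[1]]$values)
})

test_that("land cover hits the requested class proportions", {
  uni <- scene_spec(class_codes = 5L, class_proportions = 1,
                    shape = c(20L, 20L))
  expect_true(all(gen_landcover(uni)$codes == 5L))

  sp <- scene_spec(seed = 3L, shape = c(200L, 200L),
                   class_codes = c(1L, 2L, 9L),
                   class_proportions = c(0.5, 0.3, 0.2))
  lc <- gen_landcover(sp)
  props <- as.numeric(table(lc$codes)) / length(lc$codes)
  expect_equal(props, c(0.5, 0.3, 0.2), tolerance = 0.02)
  expect_equal(shannon_diversity(lc), 1.0297, tolerance = 0.02)

  expect_error(scene_spec(class_proportions = c(0.7, 0.2)), "sum to 1")
  expect_error(scene_spec(class_codes = 1:3,
                          class_proportions = c(0.5, 0.5)), "mismatch")
})

test_that("terrain hits the target relief exactly; green volume closed form", {
  flat <- scene_spec(relief_m = 0, shape = c(30L, 30L))
  tf <- gen_terrain(flat)
  expect_equal(relief_amplitude(tf$dem), 0)

  sp <- scene_spec(seed = 5L, relief_m = 7, shape = c(50L, 50L))
  tr <- gen_terrain(sp)
  expect_equal(relief_amplitude(tr$dem), 7)

  # uniform 3 m canopy (spread 0): volume = cells * dd^2 * 3
  spc <- scene_spec(seed = 2L, shape = c(30L, 30L), cell_size_m = 0.5,
                    canopy_height_m = c(3, 0))
  lc <- gen_landcover(spc)
  tc <- gen_terrain(spc, lc)
  n_veg <- sum(tc$dsm$vegetation_mask)
  expect_equal(green_volume(tc$dsm, tc$dem), n_veg * 0.25 * 3)
  expect_equal(tc$truth$green_volume_m3, n_veg * 0.25 * 3)
})

test_that("panoramas carry exact ground truth", {
  sp <- scene_spec(sky_fraction = 0.3, pano_shape = c(90L, 60L))
  im <- gen_panorama(sp)
  expect_equal(sky_fraction(im), 0.3)

  allsky <- gen_panorama(scene_spec(sky_fraction = 1,
                                    pano_shape = c(12L, 10L)))
  expect_equal(layer_superposition(build_layer_matrix(allsky)), 1)

  gray <- lapply(default_palette(), function(x) rep(mean(x), 3))
  gim <- gen_panorama(scene_spec(sky_fraction = 0.3, palette = gray))
  expect_equal(colorfulness(gim), 0)
})

test_that("reviews hit target counts and emotional values", {
  allpos <- scene_spec(review_spec = list(
    n_landscape = 20L, n_park = 50L,
    pos_frac_landscape = 1, pos_frac_park = 0.5))
  rv <- gen_reviews(allpos, "P")
  s <- summarize_park(rv)
  expect_equal(s$landscape_emotional_value, 10)
  expect_equal(s$n_landscape, 20)
  expect_equal(s$n_park, 50)

  qcp <- scene_spec(review_spec = list(
    n_landscape = 410L, n_park = 1376L,
    pos_frac_landscape = 0.72, pos_frac_park = 0.193))
  sq <- summarize_park(gen_reviews(qcp, "QCP"))
  expect_equal(sq$relative_evaluation_rate, 29.8)

  half <- scene_spec(review_spec = list(
    n_landscape = 100L, n_park = 300L,
    pos_frac_landscape = 0.5, pos_frac_park = 0.5))
  sh <- summarize_park(gen_reviews(half, "H"))
  expect_equal(sh$landscape_emotional_value, 5)
  expect_equal(sh$park_emotional_value, 5)

  expect_error(scene_spec(review_spec = list(
    n_landscape = 10L, n_park = 0L,
    pos_frac_landscape = 1, pos_frac_park = 1)), "at least one")
})

test_that("heat bumps and visitors behave as constructed", {
  # wide strong bump -> high grade at this park, flat park grades low
  hot <- scene_spec(seed = 9L, shape = c(40L, 40L),
                    heat_spec = list(centers = matrix(c(0.5, 0.5), ncol = 2),
                                     intensities = 8, sigma_frac = 0.8,
                                     n_snapshots = 3L))
  hv <- gen_heat_and_visitors(hot)
  tm <- thermal_mean(hv$snapshots)
  expect_equal(thermal_grade(tm), "high")
  expect_true(all(vapply(hv$snapshots, function(s)
    all(s$values >= 1 & s$values <= 8), logical(1))))

  cold <- scene_spec(seed = 9L, shape = c(20L, 20L),
                     heat_spec = list(centers = matrix(numeric(0), ncol = 2),
                                      intensities = numeric(0),
                                      sigma_frac = 0.2, n_snapshots = 2L),
                     n_visitors = 120L)
  hvc <- gen_heat_and_visitors(cold)
  expect_equal(thermal_mean(hvc$snapshots), 1)
  expect_equal(thermal_grade(thermal_mean(hvc$snapshots)), "low")

  kde <- kernel_density(hv$visitors, bandwidth_m = 30)
  expect_equal(kde$integral, hot$n_visitors, tolerance = 0.01)

  expect_error(gen_heat_and_visitors(scene_spec(
    heat_spec = list(centers = matrix(c(0.5, 0.5), ncol = 2),
                     intensities = 12, sigma_frac = 0.2,
                     n_snapshots = 1L))), "\\[1, 8\\]")
})

test_that("full-pipeline parameter recovery on a generated scene", {
  spec <- scene_spec(seed = 31L, shape = c(80L, 80L),
                     class_codes = c(1L, 5L, 9L, 10L),
                     class_proportions = c(0.4, 0.3, 0.2, 0.1),
                     relief_m = 9, sky_fraction = 0.25,
                     pano_shape = c(80L, 160L),
                     canopy_height_m = c(4, 0),
                     n_visitors = 150L)
  scene <- gen_scene(list(PKA = spec))
  dir <- withr::local_tempdir()
  write_scene(scene, dir)
  back <- read_scene(dir)$PKA

  # class proportions within 0.02
  props <- as.numeric(table(back$landcover$codes)) / 80^2
  expect_equal(props, c(0.4, 0.3, 0.2, 0.1), tolerance = 0.02)
  # sky fraction and relief exact, green volume exact
  expect_equal(sky_fraction(back$panoramas[[1]]), 0.25)
  expect_equal(relief_amplitude(back$dem), 9)
  expect_equal(green_volume(back$dsm, back$dem),
               scene$PKA$truth$green_volume_m3)
  # visitor count conserved through the KDE surface
  kde <- kernel_density(back$visitors, bandwidth_m = 40)
  expect_equal(kde$integral, 150, tolerance = 0.01)
})
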