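test_that("Shannon diversity matches closed forms and the summation oracle", {
  g <- land_cover_grid(matrix(c(1, 1, 2, 2), 2, 2), 10)
  expect_equal(shannon_diversity(g), log(2))

  g1 <- land_cover_grid(matrix(1L, 3, 3), 10)
  expect_equal(shannon_diversity(g1), 0)

  # proportions (0.5, 0.3, 0.2): frozen oracle value -sum(p log p)
  g3 <- grid_with_counts(c(50, 30, 20))
  expect_equal(shannon_diversity(g3), 1.02965301406457, tolerance = 1e-12)
  expect_equal(round(shannon_diversity(g3), 4), 1.0297)

  # vegetation filter: non-vegetation classes excluded
  g4 <- grid_with_counts(c(50, 50, 100), codes = c(1L, 2L, 10L))
  expect_equal(shannon_diversity(g4, vegetation_classes = 1:9), log(2))

  expect_error(
    shannon_diversity(land_cover_grid(matrix(10L, 2, 2), 10),
                      vegetation_classes = 1:9), "undefined")
})

test_that("Shannon/evenness are invariant to relabeling and rescaling", {
  g <- grid_with_counts(c(40, 35, 25), codes = c(3L, 6L, 9L))
  relabeled <- land_cover_grid(
    matrix(c("3" = 7L, "6" = 1L, "9" = 4L)[as.character(g$codes)],
           nrow(g$codes)), g$cell_size_m)
  expect_equal(shannon_diversity(relabeled), shannon_diversity(g))
  rescaled <- land_cover_grid(g$codes, g$cell_size_m * 3)
  expect_equal(shannon_diversity(rescaled), shannon_diversity(g))
  H <- shannon_diversity(g)
  expect_gte(H, 0); expect_lte(H, log(3))
  expect_true(pielou_evenness(H, 3) >= 0 && pielou_evenness(H, 3) <= 1)
})

test_that("Pielou evenness", {
  g <- land_cover_grid(matrix(c(1, 2, 3, 1, 2, 3), 2, 3), 10)
  expect_equal(pielou_evenness(shannon_diversity(g), 3), 1)
  expect_equal(pielou_evenness(0, 5), 0)
  # oracle: H/ln3 = 0.93723..., rounds to 0.9372
  expect_equal(round(pielou_evenness(1.02965301406457, 3), 4), 0.9372)
  expect_error(pielou_evenness(0.5, 1), "undefined")
})

test_that("hemeroby index: closed forms and error on unmapped classes", {
  tab <- hemeroby_table(c("1" = 4L, "2" = 1L), h = 4L)
  all_h <- land_cover_grid(matrix(1L, 4, 4), 10)
  expect_equal(hemeroby_index(all_h, tab), 1)
  all_1 <- land_cover_grid(matrix(2L, 4, 4), 10)
  expect_equal(hemeroby_index(all_1, tab), 1 / 4)
  half <- land_cover_grid(matrix(c(1L, 2L), 4, 4), 10)
  expect_equal(hemeroby_index(half, tab), 0.625)
  expect_error(hemeroby_index(land_cover_grid(matrix(9L, 2, 2), 10), tab),
               "9")
  # bounds: HI in [1/h, 1]
  set.seed(5)
  rnd <- land_cover_grid(matrix(sample(1:2, 36, TRUE), 6, 6), 10)
  hi <- hemeroby_index(rnd, tab)
  expect_gte(hi, 1 / 4); expect_lte(hi, 1)
})

test_that("fragmentation equals patches per hectare", {
  # one uniform park of 1 ha (10x10 cells of 10 m)
  g <- land_cover_grid(matrix(1L, 10, 10), 10)
  expect_equal(fragmentation_index(g), 1.0)
  # two disjoint same-class blobs in 1 ha
  m <- matrix(2L, 10, 10)
  m[1:2, 1:2] <- 1L
  m[8:9, 8:9] <- 1L
  g2 <- land_cover_grid(m, 10)
  counts <- fragmentation_index(g2, per_class = TRUE)
  expect_equal(unname(counts[["1"]]), 2)
  # diagonal touching counts as one patch (8-neighbourhood)
  d <- matrix(1L, 3, 3); d[1, 1] <- 2L; d[3, 3] <- 2L; d[2, 2] <- 2L
  gd <- land_cover_grid(d, 10)
  expect_equal(unname(fragmentation_index(gd, per_class = TRUE)[["2"]]), 1)
  expect_error(fragmentation_index(
    land_cover_grid(matrix(1L, 2, 2), 10,
                    mask = matrix(FALSE, 2, 2))), "empty")
})

test_that("fragmentation matches the brute-force flood-fill oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:20, 1)
    codes <- matrix(sample(1:2, n * n, TRUE), n, n)
    mask <- matrix(runif(n * n) > 0.15, n, n)
    if (!any(mask)) next
    g <- land_cover_grid(codes, 10, mask = mask)
    got <- fragmentation_index(g) * (sum(mask) * 100 / 1e4)
    expect_equal(got, oracle_patch_count(codes, mask),
                 info = paste("seed", seed))
  }
  # one larger case at the spec's 50x50 bound
  set.seed(99)
  codes <- matrix(sample(1:3, 2500, TRUE, prob = c(.5, .3, .2)), 50, 50)
  g <- land_cover_grid(codes, 10)
  got <- fragmentation_index(g) * (2500 * 100 / 1e4)
  expect_equal(got, oracle_patch_count(codes, g$mask))
})

test_that("canopy density is a plain cell ratio with containment check", {
  plot <- matrix(TRUE, 4, 4)
  expect_equal(canopy_density(plot, plot), 1)
  half <- plot; half[, 1:2] <- FALSE
  expect_equal(canopy_density(half, plot), 0.5)
  expect_equal(canopy_density(matrix(FALSE, 4, 4), plot), 0)
  outside <- matrix(FALSE, 4, 4); outside[1, 1] <- TRUE
  small_plot <- matrix(TRUE, 4, 4); small_plot[1, 1] <- FALSE
  expect_error(canopy_density(outside, small_plot), "outside")
})
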