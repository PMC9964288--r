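#' Synthetic scene specification
#'
#' Describes one park's synthetic world with known ground truth: a
#' patchy categorical land cover, a terrain with a target relief, a
#' canopy surface, banded panoramas, review texts with target emotional
#' values, heat snapshots and visitor points. Every generator is a pure
#' function of the spec (which carries the seed), so scenes are exactly
#' reproducible.
#'
#' Defaults emulate the reference field campaign: a 100 x 100 grid of
#' 10 m cells (the land-use product's accuracy), six cover classes
#' dominated by vegetation, a patchiness radius of 3 cells, 7 m of
#' relief, 6 m mean canopy height, 30% visible sky, and review/heat
#' volumes typical of a mid-sized riverside park.
#'
#' @param seed integer RNG seed.
#' @param shape `c(nrows, ncols)` of the rasters.
#' @param cell_size_m raster cell size (m).
#' @param class_codes integer codes of the cover classes (vegetation
#'   classes use codes 1-9; 10 = water, 11 = hardscape).
#' @param class_proportions simplex vector over `class_codes`.
#' @param patchiness Gaussian smoothing radius in cells controlling patch
#'   size.
#' @param relief_m target relief amplitude (m), hit exactly.
#' @param canopy_height_m `c(mean, spread)` of canopy heights (m) on
#'   vegetated cells; spread 0 gives a uniform canopy.
#' @param sky_fraction target sky share of each panorama (exact to one
#'   pixel row).
#' @param pano_shape `c(height, width)` of panoramas.
#' @param n_panoramas panoramas per park.
#' @param palette named list: layer class -> RGB triple in `[0, 255]`.
#' @param review_spec list(`n_landscape`, `n_park`, `pos_frac_landscape`,
#'   `pos_frac_park`): counts (landscape-targeted reviews are a subset of
#'   the park total) and positive-text fractions; the default scorer's
#'   expected emotional value is `10 * pos_frac`.
#' @param heat_spec list(`centers` (k x 2, grid-fraction coords),
#'   `intensities` (peak heights on the 1-8 scale), `sigma_frac` (bump
#'   width as a fraction of the grid extent), `n_snapshots`).
#' @param n_visitors visitor point count.
#' @param behavior_spec list(`recreation_time_h`, `recreation_number`,
#'   `recreation_frequency`, `purposes`).
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(
    seed = 1L,
    shape = c(100L, 100L),
    cell_size_m = 10,
    class_codes = c(1L, 2L, 5L, 9L, 10L, 11L),
    class_proportions = c(0.25, 0.20, 0.15, 0.20, 0.10, 0.10),
    patchiness = 3,
    relief_m = 7,
    canopy_height_m = c(6, 2),
    sky_fraction = 0.3,
    pano_shape = c(90L, 180L),
    n_panoramas = 3L,
    palette = default_palette(),
    review_spec = list(n_landscape = 60L, n_park = 200L,
                       pos_frac_landscape = 0.7, pos_frac_park = 0.45),
    heat_spec = list(centers = matrix(c(0.5, 0.5), ncol = 2),
                     intensities = 6, sigma_frac = 0.15,
                     n_snapshots = 9L),
    n_visitors = 200L,
    behavior_spec = list(recreation_time_h = 1.5,
                         recreation_number = 500L,
                         recreation_frequency = 2L,
                         purposes = "viewing;walking;running;chatting")) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (length(class_proportions) != length(class_codes))
    stop("class count mismatch between codes and proportions")
  if (sky_fraction < 0 || sky_fraction > 1)
    stop("sky_fraction must lie in [0, 1]")
  if (relief_m < 0) stop("relief must be nonnegative")
  if (review_spec$n_landscape < 0 || review_spec$n_park < 1)
    stop("review counts must be nonnegative with at least one park review")
  spec <- as.list(environment())
  structure(spec, class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_palette <- function() {
  list(sky = c(135, 206, 235), canopy = c(34, 139, 34),
       understory = c(107, 142, 35), ground = c(139, 119, 101),
       water = c(70, 130, 180), hardscape = c(128, 128, 128))
}

#' Vegetation class codes of the reference classification
#'
#' Codes 1-9: the nine vegetation-structure classes (four arbor forests,
#' four shrub forests, grassland); 10 = water, 11 = hardscape.
#' @return integer vector `1:9`.
#' @export
vegetation_codes <- function() 1:9

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

gaussian_smooth <- function(m, radius) {
  if (radius <= 0) return(m)
  r <- max(1L, ceiling(3 * radius))
  k <- stats::dnorm(-r:r, sd = radius)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  # replicate padding then separable convolution via shifted sums
  pad_rows <- m[c(rep(1, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * pad_rows[(i - 1) + seq_len(nr), , drop = FALSE]
  pad_cols <- out[, c(rep(1, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out2 <- out2 + k[i] * pad_cols[, (i - 1) + seq_len(nc), drop = FALSE]
  out2
}

#' Generate a patchy categorical land cover
#'
#' Thresholds a smoothed Gaussian noise field at its empirical rank
#' quantiles, so class cell counts match the spec proportions exactly (up
#' to integer rounding) while smoothing yields contiguous,
#' Fragstats-like patches.
#'
#' @param spec a [scene_spec()].
#' @return a [land_cover_grid()].
#' @export
gen_landcover <- function(spec) {
  with_seed(spec$seed + 101L, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    field <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                             spec$patchiness)
    n <- nr * nc
    ranks <- rank(field, ties.method = "first")
    cuts <- round(cumsum(spec$class_proportions) * n)
    cuts[length(cuts)] <- n
    idx <- findInterval(ranks, c(0, cuts), left.open = TRUE)
    codes <- matrix(spec$class_codes[idx], nr, nc)
    land_cover_grid(codes, cell_size_m = spec$cell_size_m)
  })
}

#' Generate co-registered terrain and canopy surface
#'
#' The DEM is a smoothed random field rescaled so [relief_amplitude()]
#' equals `spec$relief_m` exactly; the DSM adds canopy heights (normal
#' with the spec mean/spread, truncated at 0.5 m) on vegetated cells.
#'
#' @param spec a [scene_spec()].
#' @param landcover optional [land_cover_grid()] supplying the vegetation
#'   mask (codes in [vegetation_codes()]); defaults to [gen_landcover()]
#'   of the same spec.
#' @return list: `dem` ([elevation_grid()]), `dsm` ([surface_grid()]),
#'   `truth` (list with `relief_m`, `green_volume_m3`, `canopy_mask`).
#' @export
gen_terrain <- function(spec, landcover = NULL) {
  if (is.null(landcover)) landcover <- gen_landcover(spec)
  with_seed(spec$seed + 202L, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    field <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                             max(spec$patchiness, 2))
    rng <- range(field)
    dem_m <- if (spec$relief_m == 0 || rng[1] == rng[2]) {
      matrix(0, nr, nc)
    } else {
      (field - rng[1]) / (rng[2] - rng[1]) * spec$relief_m
    }
    veg <- matrix(landcover$codes %in% vegetation_codes(), nr, nc) &
      landcover$mask
    heights <- matrix(0, nr, nc)
    mu <- spec$canopy_height_m[1]; sdv <- spec$canopy_height_m[2]
    h <- if (sdv > 0) stats::rnorm(sum(veg), mu, sdv) else rep(mu, sum(veg))
    heights[veg] <- pmax(0.5, h)
    dsm_m <- dem_m + heights
    dem <- elevation_grid(dem_m, spec$cell_size_m)
    dsm <- surface_grid(dsm_m, spec$cell_size_m, vegetation_mask = veg)
    list(dem = dem, dsm = dsm,
         truth = list(relief_m = spec$relief_m,
                      green_volume_m3 = sum(spec$cell_size_m^2 *
                                              heights[veg]),
                      canopy_mask = veg))
  })
}

#' Generate a banded panorama with ground truth
#'
#' Top rows are sky (share exact to one row), the remainder is split into
#' canopy / understory / ground bands colored from the palette. The
#' ground-truth sky mask and layer labels ride along, so segmentation-free
#' testing of C5/C6/C9 is possible.
#'
#' @param spec a [scene_spec()].
#' @param index panorama index (varies band proportions deterministically).
#' @return a [panorama()].
#' @export
gen_panorama <- function(spec, index = 1L) {
  h <- spec$pano_shape[1]; w <- spec$pano_shape[2]
  n_sky <- round(spec$sky_fraction * h)
  rest <- h - n_sky
  # deterministic per-index variation of the non-sky band split
  splits <- c(0.35, 0.30, 0.35) + 0.05 * sin(index + 1:3)
  splits <- splits / sum(splits)
  n_can <- round(splits[1] * rest)
  n_und <- round(splits[2] * rest)
  n_grd <- rest - n_can - n_und
  classes <- layer_classes()
  lab_rows <- c(rep(1L, n_sky), rep(2L, n_can), rep(3L, n_und),
                rep(4L, n_grd))
  labels <- matrix(lab_rows, nrow = h, ncol = w)
  rgb <- array(0, dim = c(h, w, 3))
  for (code in unique(lab_rows)) {
    col <- spec$palette[[classes[code]]]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[labels == code] <- col[ch]
      rgb[, , ch] <- plane
    }
  }
  panorama(rgb, sky_mask = labels == 1L, layer_labels = labels)
}

#' Generate synthetic review records
#'
#' Emits `n_landscape` landscape-targeted rows and `n_park` general park
#' rows per park (the two targets are disjoint). Texts are token
#' sequences, not natural language: a positive text carries one positive
#' lexicon token (default scorer: 10), a negative text one negative token
#' (0), so the expected emotional value is `10 * pos_frac` and the
#' realized one is `10 * round(pos_frac * n) / n`. A neutral filler and a
#' vision-sense term are appended so word-frequency runs see sense hits.
#'
#' @param spec a [scene_spec()].
#' @param park_id park code for the records.
#' @return data.frame with `park_id`, `target`, `text`.
#' @export
gen_reviews <- function(spec, park_id = "PARK") {
  rs <- spec$review_spec
  make_texts <- function(n, pos_frac, tag) {
    if (n == 0) return(character(0))
    n_pos <- round(pos_frac * n)
    tokens <- c(rep("pleasant", n_pos), rep("noisy", n - n_pos))
    paste(tokens, "riverbank", if (tag == "landscape") "scenery" else "visit")
  }
  n_ls <- rs$n_landscape
  n_pk <- rs$n_park
  df <- data.frame(
    park_id = park_id,
    target = c(rep("landscape", n_ls), rep("park", n_pk)),
    text = c(make_texts(n_ls, rs$pos_frac_landscape, "landscape"),
             make_texts(n_pk, rs$pos_frac_park, "park")),
    stringsAsFactors = FALSE
  )
  df
}

#' Generate heat snapshots and visitor points
#'
#' Heat snapshots are a base intensity of 1 plus Gaussian bumps at the
#' spec centers, clipped to the `[1, 8]` heat scale, with a small
#' seeded per-snapshot amplitude jitter. Visitor points are drawn from
#' the same bump mixture (uniform when no bumps), truncated to the park
#' extent, so heat and density agree spatially.
#'
#' @param spec a [scene_spec()].
#' @return list: `snapshots` (list of [heat_snapshot()]),
#'   `visitors` ([visitor_points()]).
#' @export
gen_heat_and_visitors <- function(spec) {
  hs <- spec$heat_spec
  if (any(hs$intensities < 1 | hs$intensities > 8))
    stop("bump intensities must lie in [1, 8]")
  with_seed(spec$seed + 303L, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    cs <- spec$cell_size_m
    wx <- nc * cs; wy <- nr * cs
    xc <- (seq_len(nc) - 0.5) * cs
    yc <- wy - (seq_len(nr) - 0.5) * cs   # row 1 = top
    sigma <- hs$sigma_frac * max(wx, wy)
    bump_field <- matrix(0, nr, nc)
    centers <- hs$centers
    for (j in seq_len(nrow(centers))) {
      cxy <- c(centers[j, 1] * wx, centers[j, 2] * wy)
      dx2 <- outer(rep(1, nr), (xc - cxy[1])^2)
      dy2 <- outer((yc - cxy[2])^2, rep(1, nc))
      bump_field <- bump_field +
        (hs$intensities[j] - 1) * exp(-(dx2 + dy2) / (2 * sigma^2))
    }
    snapshots <- lapply(seq_len(hs$n_snapshots), function(k) {
      jitter <- 1 + 0.05 * stats::rnorm(1)
      vals <- pmin(pmax(1 + jitter * bump_field, 1), 8) # matrix first arg
                                                        # keeps dims
      heat_snapshot(vals, timestamp = sprintf("t%02d", k))
    })
    n <- spec$n_visitors
    if (nrow(centers) > 0) {
      wts <- hs$intensities / sum(hs$intensities)
      comp <- sample.int(nrow(centers), n, replace = TRUE, prob = wts)
      px <- stats::rnorm(n, centers[comp, 1] * wx, sigma)
      py <- stats::rnorm(n, centers[comp, 2] * wy, sigma)
    } else {
      px <- stats::runif(n, 0, wx); py <- stats::runif(n, 0, wy)
    }
    pts <- cbind(pmin(pmax(px, 0), wx), pmin(pmax(py, 0), wy))
    list(snapshots = snapshots,
         visitors = visitor_points(pts, park_area_m2 = wx * wy))
  })
}

#' Generate a complete multi-park scene
#'
#' @param specs named list of [scene_spec()] objects, one per park (names
#'   are park ids).
#' @return list of per-park scenes, each holding `landcover`, `dem`,
#'   `dsm`, `panoramas`, `reviews`, `snapshots`, `visitors`, `behavior`
#'   and `truth`.
#' @export
gen_scene <- function(specs) {
  stopifnot(length(specs) > 0, !is.null(names(specs)))
  lapply(stats::setNames(names(specs), names(specs)), function(pk) {
    spec <- specs[[pk]]
    lc <- gen_landcover(spec)
    terr <- gen_terrain(spec, lc)
    panos <- lapply(seq_len(spec$n_panoramas), gen_panorama, spec = spec)
    hv <- gen_heat_and_visitors(spec)
    bs <- spec$behavior_spec
    behavior <- data.frame(park_id = pk,
                           recreation_time_h = bs$recreation_time_h,
                           recreation_number = bs$recreation_number,
                           recreation_frequency = bs$recreation_frequency,
                           purposes = bs$purposes,
                           stringsAsFactors = FALSE)
    list(spec = spec, landcover = lc, dem = terr$dem, dsm = terr$dsm,
         panoramas = panos, reviews = gen_reviews(spec, pk),
         snapshots = hv$snapshots, visitors = hv$visitors,
         behavior = behavior,
         truth = c(terr$truth,
                   list(class_proportions = stats::setNames(
                     spec$class_proportions, spec$class_codes),
                     sky_fraction = round(spec$sky_fraction *
                                            spec$pano_shape[1]) /
                       spec$pano_shape[1],
                     n_visitors = spec$n_visitors)))
  })
}

#' Write a scene to disk / read it back
#'
#' Lays out one subdirectory per park: `landcover.asc`, `dem.asc`,
#' `dsm.asc`, `vegmask.asc`, `heat_<k>.asc`, `pano_<i>.ppm` (+ mask and
#' label sidecars), `visitors.csv`, `behavior.csv`; a scene-level
#' `reviews.csv` pools all parks. Round-trips exactly.
#'
#' @param scene result of [gen_scene()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reviews <- list()
  for (pk in names(scene)) {
    s <- scene[[pk]]
    pd <- file.path(dir, pk)
    dir.create(pd, showWarnings = FALSE)
    write_raster(s$landcover, file.path(pd, "landcover.asc"))
    write_raster(s$dem, file.path(pd, "dem.asc"))
    write_raster(s$dsm, file.path(pd, "dsm.asc"))
    write_raster(matrix(as.integer(s$dsm$vegetation_mask),
                        nrow(s$dsm$surface_m)),
                 file.path(pd, "vegmask.asc"),
                 cell_size_m = s$dsm$cell_size_m)
    for (k in seq_along(s$snapshots))
      write_raster(s$snapshots[[k]]$values, # full precision continuous
                   file.path(pd, sprintf("heat_%02d.asc", k)),
                   cell_size_m = s$landcover$cell_size_m)
    for (i in seq_along(s$panoramas))
      write_panorama(s$panoramas[[i]],
                     file.path(pd, sprintf("pano_%02d.ppm", i)))
    utils::write.csv(data.frame(x = s$visitors$points[, 1],
                                y = s$visitors$points[, 2]),
                     file.path(pd, "visitors.csv"), row.names = FALSE)
    utils::write.csv(s$behavior, file.path(pd, "behavior.csv"),
                     row.names = FALSE)
    reviews[[pk]] <- s$reviews
  }
  utils::write.csv(do.call(rbind, reviews), file.path(dir, "reviews.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @param dir a scene directory written by [write_scene()].
#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  parks <- list.dirs(dir, recursive = FALSE)
  reviews <- if (file.exists(file.path(dir, "reviews.csv"))) {
    read_reviews(file.path(dir, "reviews.csv"))
  } else {
    data.frame(park_id = character(0), target = character(0),
               text = character(0))
  }
  scene <- lapply(stats::setNames(parks, basename(parks)), function(pd) {
    lc <- read_raster(file.path(pd, "landcover.asc"), "categorical")
    dem <- read_raster(file.path(pd, "dem.asc"), "continuous")
    dsm_raw <- read_raster(file.path(pd, "dsm.asc"), "continuous")
    veg <- read_raster(file.path(pd, "vegmask.asc"), "categorical")
    dsm <- surface_grid(dsm_raw$elevation_m, dsm_raw$cell_size_m,
                        vegetation_mask = veg$codes == 1L)
    heats <- sort(list.files(pd, pattern = "^heat_.*\\.asc$",
                             full.names = TRUE))
    snapshots <- lapply(heats, function(p) {
      g <- read_raster(p, "continuous")
      heat_snapshot(g$elevation_m, timestamp = basename(p))
    })
    panos <- lapply(sort(list.files(pd, pattern = "^pano_[0-9]+\\.ppm$",
                                    full.names = TRUE)), read_panorama)
    vis <- utils::read.csv(file.path(pd, "visitors.csv"))
    area <- nrow(lc$codes) * ncol(lc$codes) * lc$cell_size_m^2
    list(landcover = lc, dem = dem, dsm = dsm, panoramas = panos,
         snapshots = snapshots,
         visitors = visitor_points(as.matrix(vis), park_area_m2 = area),
         behavior = utils::read.csv(file.path(pd, "behavior.csv"),
                                    stringsAsFactors = FALSE),
         reviews = reviews[reviews$park_id == basename(pd), ,
                           drop = FALSE])
  })
  scene
}
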