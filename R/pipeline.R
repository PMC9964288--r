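#' Run the full space-psychology-behavior pipeline on a scene directory
#'
#' Reads every park of a scene (see [write_scene()] for the layout),
#' computes the twelve spatial indicators, dimension composites and Jenks
#' grades, the sentiment summary with the rate-emotion regression, the
#' thermal / kernel-density / behavior summaries, and the three-subsystem
#' coupling-coordination table, and writes them as CSVs to `outdir`
#' together with a log of every configuration decision. Any stage failure
#' aborts with the stage name. An empty scene yields empty (header-only)
#' outputs and succeeds.
#'
#' @param scene_dir directory holding the scene.
#' @param outdir output directory (created).
#' @param config a [run_config()].
#' @return invisibly, a list of the result data.frames
#'   (`indicators`, `dimensions`, `sentiment`, `behavior`, `coupling`).
#' @export
run_pipeline <- function(scene_dir, outdir, config = run_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("cell_size_m: %g", config$cell_size_m),
                 sprintf("grading_k: %d", config$grading_k),
                 sprintf("thermal_thresholds: %s",
                         paste(config$thermal_thresholds, collapse = ", ")),
                 sprintf("kde_bandwidth_m: %s",
                         paste(config$kde_bandwidth_m, collapse = "")),
                 sprintf("coupling_weights: %s",
                         paste(signif(config$coupling_weights, 6),
                               collapse = ", ")),
                 "C5 matrix: 6-band vertical-transition tally (package construction)",
                 "aggregator: arithmetic mean")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  scene <- stage("read_scene", read_scene(scene_dir))
  parks <- names(scene)

  empty <- function(cols) stats::setNames(
    data.frame(matrix(nrow = 0, ncol = length(cols))), cols)

  if (length(parks) == 0) {
    res <- list(
      indicators = empty(c("park_id", paste0(indicator_names(), "_raw"))),
      dimensions = empty(c("park_id", "horizontal", "vertical",
                           "three_dimensional", "overall", "grade")),
      sentiment = empty(c("park_id", "n_landscape", "n_park",
                          "relative_evaluation_rate",
                          "landscape_emotional_value",
                          "park_emotional_value",
                          "relative_emotional_value")),
      behavior = empty(c("park_id", "thermal_mean", "thermal_grade",
                         "mean_density", "density_grade",
                         "recreation_time_h")),
      coupling = empty(c("park_id", "C", "T", "D", "level", "label"))
    )
  } else {
    indicators <- stage("spatial_indicators", do.call(rbind, lapply(
      parks, function(pk) spatial_indicators(scene[[pk]], pk, config))))
    norm <- stage("normalize", {
      raw <- indicators
      names(raw) <- sub("_raw$", "", names(raw))
      normalize_indicators(raw, config$normalization_bounds)
    })
    dims <- stage("dimension_scores",
                  dimension_scores(norm, digits = config$rounding$indices))
    dims$grade <- if (nrow(dims) >= config$grading_k &&
                      length(unique(dims$overall)) >= config$grading_k) {
      natural_breaks(dims$overall, config$grading_k)
    } else NA_integer_
    sentiment <- stage("sentiment", {
      reviews <- do.call(rbind, lapply(scene, `[[`, "reviews"))
      summarize_park(reviews, digits = config$rounding$emotions)
    })
    if (nrow(sentiment) >= 3 &&
        !is.na(stats::sd(sentiment$relative_evaluation_rate)) &&
        stats::sd(sentiment$relative_evaluation_rate) > 0) {
      reg <- fit_rate_emotion_regression(sentiment)
      log_lines <- c(log_lines, sprintf(
        "rate-emotion regression: slope %.4f, R2 %.3f, p %.4f, n %d",
        reg$slope, reg$r_squared, reg$p_value, reg$n))
    }
    behavior <- stage("behavior", do.call(rbind, lapply(
      parks, function(pk) behavior_row(scene[[pk]], pk, config))))
    behavior$density_grade <-
      if (nrow(behavior) >= 3 &&
          length(unique(behavior$mean_density)) >= 3) {
        c("high", "medium", "low")[natural_breaks(behavior$mean_density, 3)]
      } else NA_character_
    coupling <- stage("coupling", {
      sub <- data.frame(
        park_id = dims$park_id,
        spatial = dims$overall,
        psychological = sentiment$relative_emotional_value[
          match(dims$park_id, sentiment$park_id)],
        behavioral = behavioral_composite(behavior)[
          match(dims$park_id, behavior$park_id)])
      if (nrow(sub) >= 2 &&
          all(vapply(sub[-1], function(x) length(unique(x)) > 1,
                     logical(1)))) {
        coupling_table(sub, weights = config$coupling_weights)
      } else empty(c("park_id", "C", "T", "D", "level", "label"))
    })
    res <- list(indicators = indicators, dimensions = dims,
                sentiment = sentiment,
                behavior = behavior[c("park_id", "thermal_mean",
                                      "thermal_grade", "mean_density",
                                      "density_grade",
                                      "recreation_time_h")],
                coupling = coupling)
  }
  for (nm in names(res))
    utils::write.csv(res[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  writeLines(log_lines, log_path)
  invisible(res)
}

#' Twelve raw spatial indicators for one park
#'
#' C1 Shannon diversity, C2 Pielou evenness, C3 hemeroby, C4
#' fragmentation (patches/ha), C5 layer superposition, C6 colorfulness,
#' C7 terrain position, C8 profile curvature, C9 sky fraction, C10 green
#' volume *density* (m^3/m^2, so parks of different sizes are
#' comparable), C11 canopy density (cells with DSM-DEM above the config
#' canopy height), C12 relief amplitude (m).
#'
#' @param park one park entry of a [read_scene()] result.
#' @param park_id park code.
#' @param config a [run_config()].
#' @return one-row data.frame `park_id`, `C1_raw` .. `C12_raw`.
#' @export
spatial_indicators <- function(park, park_id, config = run_config()) {
  lc <- park$landcover
  veg_present <- intersect(unique(lc$codes[lc$mask]), vegetation_codes())
  H <- shannon_diversity(lc, vegetation_codes())
  J <- if (length(veg_present) >= 2) pielou_evenness(H, length(veg_present))
       else 0
  hem <- hemeroby_index(lc, hemeroby_table(config$hemeroby_degrees,
                                           config$hemeroby_h))
  frag <- fragmentation_index(lc)
  img <- park_image_metrics(park$panoramas)
  tp <- terrain_position(park$dem)
  pc <- profile_curvature(park$dem)
  vol <- green_volume(park$dsm, park$dem)
  area_m2 <- sum(lc$mask) * lc$cell_size_m^2
  canopy <- (park$dsm$surface_m - park$dem$elevation_m) >
    config$canopy_min_height_m
  cd <- canopy_density(canopy & lc$mask, lc$mask)
  data.frame(park_id = park_id,
             C1_raw = H, C2_raw = J, C3_raw = hem, C4_raw = frag,
             C5_raw = img$C5_raw, C6_raw = img$C6_raw,
             C7_raw = tp$mean, C8_raw = pc$mean,
             C9_raw = img$C9_raw, C10_raw = vol / area_m2,
             C11_raw = cd, C12_raw = relief_amplitude(park$dem))
}

behavior_row <- function(park, park_id, config) {
  tm <- thermal_mean(park$snapshots, digits = config$rounding$thermal)
  lc <- park$landcover
  extent <- c(ncol(lc$codes), nrow(lc$codes)) * lc$cell_size_m
  kde <- kernel_density(
    park$visitors, bandwidth_m = config$kde_bandwidth_m,
    grid = list(xlim = c(0, extent[1]), ylim = c(0, extent[2]),
                nx = 64L, ny = 64L))
  data.frame(park_id = park_id, thermal_mean = tm,
             thermal_grade = thermal_grade(tm, config$thermal_thresholds),
             mean_density = round(kde$mean_density,
                                  config$rounding$thermal),
             density_grade = NA_character_,
             recreation_time_h = park$behavior$recreation_time_h[1])
}

#' Behavioral composite for the coupling model
#'
#' Mean of the min-max scaled thermal means and the min-max scaled mean
#' kernel densities across parks — one number per park summarizing
#' crowd presence.
#'
#' @param behavior data.frame with `thermal_mean` and `mean_density`.
#' @return numeric vector aligned with `behavior` rows.
#' @export
behavioral_composite <- function(behavior) {
  mm <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(0.5, length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  (mm(behavior$thermal_mean) + mm(behavior$mean_density)) / 2
}

#' Packaged reference tables
#'
#' Ships the published reference tables used by the tests and acceptance
#' checks as plain-CSV fixtures: `table3` (normalized indicator values per
#' park), `table4` (dimension composites), `table5` (review counts and
#' emotional values), `table7` (thermal means and grades), `table8`
#' (behavior observations), `table9`-`table12` (coupling coordination for
#' the three-subsystem model and each two-subsystem pair), `parks`
#' (park codes and areas), `levels` (published four-level spatial
#' grading).
#'
#' @param name fixture name, e.g. `"table3"`.
#' @return data.frame.
#' @export
waterscape_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "waterscape")
  if (path == "") stop("unknown fixture: ", name)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
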