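#' Run configuration
#'
#' One bag of every tunable the pipeline uses, with validated invariants.
#' Defaults give a self-consistent run on synthetic scenes: 10 m cells,
#' per-indicator normalization bounds chosen so realistic raw values land
#' inside `[0, 1]`, a 7-degree hemeroby ladder, 4-level spatial grading,
#' heat thresholds at 2 and 5, automatic KDE bandwidth, equal coupling
#' weights, and the published reporting precisions (4 decimals for
#' indices and thermal/density, 1 for emotional values and rates, 3 for
#' coupling quantities).
#'
#' @param cell_size_m raster cell size (m).
#' @param normalization_bounds named list `Ck -> c(min, max)`; indicators
#'   missing from the list use identity bounds `(0, 1)`. `C10` bounds
#'   apply to green-volume *density* (m^3 of canopy volume per m^2 of
#'   park).
#' @param hemeroby_degrees named integer vector: class code -> degree.
#' @param hemeroby_h number of hemeroby degrees.
#' @param grading_k number of spatial grades (Jenks classes).
#' @param thermal_thresholds two strictly increasing heat cut points.
#' @param kde_bandwidth_m bandwidth in metres or `"auto"`.
#' @param canopy_min_height_m DSM-DEM height above which a cell counts as
#'   canopy for C11.
#' @param coupling_weights three nonnegative weights summing to 1.
#' @param rounding named list of reporting decimals per output family.
#' @param seed integer seed recorded with every run.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(
    cell_size_m = 10,
    normalization_bounds = default_bounds(),
    hemeroby_degrees = default_hemeroby_degrees(),
    hemeroby_h = 7L,
    grading_k = 4L,
    thermal_thresholds = c(2, 5),
    kde_bandwidth_m = "auto",
    canopy_min_height_m = 1,
    coupling_weights = rep(1 / 3, 3),
    rounding = list(indices = 4L, emotions = 1L, coupling = 3L,
                    thermal = 4L),
    seed = 1L) {
  stopifnot(cell_size_m > 0, grading_k >= 2,
            length(thermal_thresholds) == 2,
            thermal_thresholds[1] < thermal_thresholds[2])
  if (abs(sum(coupling_weights) - 1) > 1e-9 || any(coupling_weights < 0))
    stop("coupling weights must be nonnegative and sum to 1")
  if (!identical(kde_bandwidth_m, "auto"))
    stopifnot(is.numeric(kde_bandwidth_m), kde_bandwidth_m > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
default_bounds <- function() {
  list(C1 = c(0, log(9)),   # max Shannon over the 9 vegetation classes
       C4 = c(0, 20),       # patches/ha
       C6 = c(0, 150),      # colorfulness rarely exceeds ~110
       C7 = c(-1, 1),       # terrain position (m), flat ~ 0.5
       C8 = c(-0.5, 0.5),   # profile curvature (1/m)
       C10 = c(0, 15),      # canopy volume density (m^3/m^2)
       C12 = c(0, 20))      # relief (m)
}

#' @rdname run_config
#' @export
default_hemeroby_degrees <- function() {
  # 7-degree ladder, natural = 1 ... artificial = 7
  c("1" = 2L, "2" = 2L, "3" = 2L, "4" = 2L,   # arbor forests
    "5" = 3L, "6" = 3L, "7" = 3L, "8" = 3L,   # shrub forests
    "9" = 4L,                                 # grassland
    "10" = 1L,                                # water
    "11" = 7L)                                # hardscape
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return [read_run_config()]: a `run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$normalization_bounds))
    raw$normalization_bounds <- lapply(raw$normalization_bounds,
                                       as.numeric)
  if (!is.null(raw$hemeroby_degrees)) {
    hd <- unlist(raw$hemeroby_degrees)
    storage.mode(hd) <- "integer"
    raw$hemeroby_degrees <- hd
  }
  do.call(run_config, raw)
}

#' @param config a [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  # jsonlite drops names on atomic vectors; keep the class->degree map
  out$hemeroby_degrees <- as.list(out$hemeroby_degrees)
  jsonlite::write_json(out, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
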