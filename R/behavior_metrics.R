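#' Heat snapshot container
#'
#' A gridded crowd-presence snapshot with intensities on the 1-8 heat
#' scale.
#'
#' @param values numeric matrix with values in `[1, 8]` on the mask.
#' @param timestamp label for the capture time.
#' @param mask logical park mask (defaults to non-`NA` cells).
#' @return an object of class `heat_snapshot`.
#' @export
heat_snapshot <- function(values, timestamp = "", mask = NULL) {
  stopifnot(is.matrix(values))
  mask <- check_mask(mask, values)
  v <- values[mask]
  if (any(v < 1 | v > 8))
    stop("heat values must lie in [1, 8] on the park mask")
  structure(list(values = values, timestamp = timestamp, mask = mask),
            class = "heat_snapshot")
}

#' Mean thermal value over a stack of heat snapshots
#'
#' Pools all masked cells of all snapshots and returns their mean; with
#' equal-sized masks this equals the mean of per-snapshot means.
#'
#' @param snapshots list of [heat_snapshot()] objects.
#' @param digits reporting precision (4 decimals, matching published
#'   thermal values); `NA` for unrounded.
#' @return mean thermal value.
#' @export
thermal_mean <- function(snapshots, digits = 4) {
  if (length(snapshots) == 0) stop("no heat snapshots")
  v <- unlist(lapply(snapshots, function(s) s$values[s$mask]))
  m <- mean(v)
  if (is.na(digits)) m else round(m, digits)
}

#' Heat grade from a mean thermal value
#'
#' Thresholds follow the published interval labels exactly: `[1, 2]` is
#' low heat, `(2, 5]` sub heat ("2.0001-5"), `(5, 8]` high heat
#' ("5.0001-8"); the boundary values 2 and 5 belong to the lower grade.
#'
#' @param mean_value thermal mean in `[1, 8]`.
#' @param thresholds two strictly increasing cut points (default
#'   `c(2, 5)`).
#' @return `"low"`, `"sub"` or `"high"`.
#' @export
thermal_grade <- function(mean_value, thresholds = c(2, 5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  if (is.na(mean_value) || mean_value < 1 || mean_value > 8)
    stop("thermal mean out of the [1, 8] heat scale")
  if (mean_value <= thresholds[1]) "low"
  else if (mean_value <= thresholds[2]) "sub"
  else "high"
}

#' Visitor point set
#'
#' @param points two-column matrix/data.frame of planar coordinates (m).
#' @param park_area_m2 park area in square metres.
#' @param persons_per_point how many persons one point represents.
#' @return an object of class `visitor_points`.
#' @export
visitor_points <- function(points, park_area_m2, persons_per_point = 1) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 0,
            park_area_m2 > 0, persons_per_point > 0)
  structure(list(points = points, park_area_m2 = park_area_m2,
                 persons_per_point = persons_per_point),
            class = "visitor_points")
}

#' Gaussian kernel density of visitor points
#'
#' Evaluates a Gaussian kernel density on a regular grid and scales it so
#' the surface integrates to the total number of persons, giving
#' persons/m^2. The default grid extends 5 bandwidths past the point
#' bounding box so that the integral check (mass conservation within 1%)
#' is meaningful; a park-bounded grid truncates boundary mass instead of
#' renormalizing it.
#'
#' @param points a [visitor_points()] with at least one point.
#' @param bandwidth_m kernel standard deviation in metres, or `"auto"`
#'   for Silverman's rule (`sigma * n^(-1/6)` with `sigma` the mean of the
#'   per-axis standard deviations).
#' @param grid list(`xlim`, `ylim`, `nx`, `ny`) or `NULL` for the default
#'   described above (128 x 128).
#' @param park_mask optional logical `ny x nx` matrix restricting the park
#'   summary.
#' @return list: `density` (ny x nx matrix, persons/m^2, row 1 = max y),
#'   `x`, `y` (cell-centre coordinates), `cell_area_m2`, `total_persons`,
#'   `integral` (surface integral in persons), `mean_density` (mean over
#'   the park mask or whole grid).
#' @export
kernel_density <- function(points, bandwidth_m = "auto", grid = NULL,
                           park_mask = NULL) {
  pts <- points$points
  n <- nrow(pts)
  if (n == 0) stop("no visitor points")
  if (identical(bandwidth_m, "auto")) {
    sig <- mean(c(stats::sd(pts[, 1]), stats::sd(pts[, 2])))
    if (!is.finite(sig) || sig == 0) sig <- 1
    bandwidth_m <- sig * n^(-1 / 6)
  }
  stopifnot(is.numeric(bandwidth_m), bandwidth_m > 0)
  h <- bandwidth_m
  if (is.null(grid)) {
    pad <- 5 * h
    grid <- list(xlim = range(pts[, 1]) + c(-pad, pad),
                 ylim = range(pts[, 2]) + c(-pad, pad),
                 nx = 128L, ny = 128L)
  }
  x <- seq(grid$xlim[1], grid$xlim[2], length.out = grid$nx + 1L)
  y <- seq(grid$ylim[1], grid$ylim[2], length.out = grid$ny + 1L)
  xc <- (x[-1] + x[-length(x)]) / 2
  yc <- (y[-1] + y[-length(y)]) / 2
  cell_area <- diff(grid$xlim) / grid$nx * diff(grid$ylim) / grid$ny
  # separable kernel: density = (Kx %*% t(Ky)) summed over points
  kx <- outer(pts[, 1], xc, function(p, g)
    stats::dnorm(g, mean = p, sd = h))        # n x nx
  ky <- outer(pts[, 2], yc, function(p, g)
    stats::dnorm(g, mean = p, sd = h))        # n x ny
  dens <- crossprod(ky, kx)                   # ny x nx, y ascending
  dens <- dens[rev(seq_len(grid$ny)), , drop = FALSE]  # row 1 = max y
  dens <- dens * points$persons_per_point
  total <- n * points$persons_per_point
  mean_density <- if (is.null(park_mask)) mean(dens)
                  else mean(dens[park_mask])
  list(density = dens, x = xc, y = rev(yc), cell_area_m2 = cell_area,
       total_persons = total, integral = sum(dens) * cell_area,
       mean_density = mean_density, bandwidth_m = h)
}

#' Behavior observation summary
#'
#' Maps each recorded activity to one of the five recreation-purpose
#' categories (sightseeing, fitness, social, catering, other), ranks the
#' categories by frequency and reports the mean recreation time.
#'
#' @param records data.frame with columns `park_id`,
#'   `recreation_time_h`, `recreation_number`, `recreation_frequency`,
#'   `purposes` (activity labels separated by `;`).
#' @param purpose_map named character vector: activity label -> category;
#'   defaults to [default_purpose_map()].
#' @param digits precision for the mean time (1 decimal).
#' @return list: `mean_recreation_time_h`, `purpose_ranking` (data.frame
#'   `category`, `count`, descending, lexicographic tie-break),
#'   `n_records`.
#' @export
behavior_summary <- function(records, purpose_map = NULL, digits = 1) {
  if (nrow(records) == 0) stop("no behavior records")
  stopifnot(all(records$recreation_time_h > 0))
  if (is.null(purpose_map)) purpose_map <- default_purpose_map()
  acts <- tolower(trimws(unlist(strsplit(records$purposes, ";"))))
  acts <- acts[acts != ""]
  unmapped <- setdiff(unique(acts), names(purpose_map))
  if (length(unmapped))
    stop("activities missing from the purpose map: ",
         paste(sort(unmapped), collapse = ", "))
  cats <- purpose_map[acts]
  tab <- table(factor(cats, levels = purpose_categories()))
  ranking <- data.frame(category = names(tab), count = as.integer(tab))
  ranking <- ranking[order(-ranking$count, ranking$category), ]
  rownames(ranking) <- NULL
  mt <- mean(records$recreation_time_h)
  list(mean_recreation_time_h = if (is.na(digits)) mt else round(mt, digits),
       purpose_ranking = ranking, n_records = nrow(records))
}

purpose_categories <- function()
  c("sightseeing", "fitness", "social", "catering", "other")

#' Default activity-to-purpose map
#'
#' Covers the activity vocabulary of the packaged behavior-observation
#' fixture; extend or replace for other field forms.
#'
#' @return named character vector.
#' @export
default_purpose_map <- function() {
  c(
    "viewing" = "sightseeing", "sightseeing" = "sightseeing",
    "photography" = "sightseeing", "mountaineering" = "sightseeing",
    "running" = "fitness", "cycling" = "fitness",
    "basketball" = "fitness", "badminton" = "fitness",
    "tennis" = "fitness", "playing table tennis" = "fitness",
    "rope skipping" = "fitness", "taiji" = "fitness",
    "square dancing" = "fitness", "square dance" = "fitness",
    "chatting" = "social", "accompanying the family" = "social",
    "accompanying family" = "social",
    "spending time with family" = "social", "playing cards" = "social",
    "fairs" = "social",
    "eating" = "catering", "picnicking" = "catering",
    "walking" = "other", "walking the dog" = "other",
    "dog walking" = "other", "passage" = "other", "daze" = "other",
    "playing" = "other", "play" = "other"
  )
}
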