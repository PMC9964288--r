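#' Subsystem scores for the coupling model
#'
#' Min-max scales each dimension's park-level composite across parks to
#' `[floor, 1]`, ordered (spatial, psychological, behavioral). The floor
#' (default 0.01) keeps products away from zero, which would annihilate
#' the coupling index. Any 2-column subset gives a two-subsystem model.
#'
#' @param scores data.frame with `park_id` and 2 or 3 numeric columns of
#'   dimension composites.
#' @param floor lower end of the scaled range.
#' @return data.frame: `park_id` plus the scaled `u` columns (same names).
#' @export
subsystem_scores <- function(scores, floor = 0.01) {
  stopifnot("park_id" %in% names(scores))
  ucols <- setdiff(names(scores), "park_id")
  if (!length(ucols) %in% c(2L, 3L))
    stop("need 2 or 3 subsystem columns, got ", length(ucols))
  if (nrow(scores) < 2) stop("min-max scaling needs at least 2 parks")
  out <- scores
  for (nm in ucols) {
    x <- scores[[nm]]
    rng <- range(x)
    if (rng[1] == rng[2])
      stop("constant column '", nm, "': scaling undefined")
    out[[nm]] <- floor + (1 - floor) * (x - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Coupling index C
#'
#' `C = (prod(u) / mean(u)^k)^(1/k)` for `k` subsystems: the ratio of the
#' geometric to the arithmetic mean, in `[0, 1]`, equal to 1 iff all
#' subsystems are equal. A zero subsystem yields `C = 0` with a warning.
#'
#' @param u numeric vector of 2 or 3 subsystem scores in `[0, 1]`.
#' @return real in `[0, 1]`.
#' @export
coupling_degree <- function(u) {
  stopifnot(length(u) %in% c(2L, 3L), all(u >= 0), all(u <= 1))
  if (any(u == 0)) {
    warning("a subsystem score is 0; coupling degree degenerates to 0")
    return(0)
  }
  k <- length(u)
  (prod(u) / mean(u)^k)^(1 / k)
}

#' Coordination index T
#'
#' Weighted average level of the subsystems, `T = sum(w * u)`; equal
#' weights by default.
#'
#' @param u numeric vector of subsystem scores.
#' @param weights nonnegative weights summing to 1 (length of `u`).
#' @return real in `[0, 1]` for `u` in `[0, 1]`.
#' @export
coordination_index <- function(u, weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / length(u), length(u))
  if (length(weights) != length(u))
    stop("weights length must match the number of subsystems")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be nonnegative and sum to 1")
  sum(weights * u)
}

#' Coupling coordination degree D with level and label
#'
#' `D = sqrt(C * T)`, rounded half-even to 3 decimals, then graded on the
#' ten-level ladder with upper-inclusive bins `(0.0, 0.1] -> 1` up to
#' `(0.9, 1.0] -> 10` (`level = ceiling(10 * D)` clipped to `[1, 10]`).
#'
#' @param C coupling index in `[0, 1]`.
#' @param T_ coordination index in `[0, 1]`.
#' @param digits rounding for D (3 decimals, the published precision).
#' @return list: `D`, `level` (1-10), `label`.
#' @export
coupling_coordination <- function(C, T_, digits = 3) {
  if (is.na(C) || is.na(T_) || C < 0 || C > 1 || T_ < 0 || T_ > 1)
    stop("C and T must lie in [0, 1]")
  D <- sqrt(C * T_)
  if (!is.na(digits)) D <- round(D, digits)
  level <- min(10L, max(1L, as.integer(ceiling(10 * D))))
  list(D = D, level = level, label = coordination_ladder()[level])
}

#' The ten-level coordination ladder
#'
#' @return character vector of 10 labels, index = level.
#' @export
coordination_ladder <- function() {
  c("Extreme maladjustment", "Severe maladjustment",
    "Moderate maladjustment", "Mild maladjustment",
    "Near maladjustment", "Poor coordination", "Mild coordination",
    "Moderate coordination", "Good coordination",
    "Excellent coordination")
}

#' Full coupling-coordination table for a set of parks
#'
#' Scales the dimension composites ([subsystem_scores()]), then computes
#' C, T, D, level and label per park.
#'
#' @inheritParams subsystem_scores
#' @param weights coordination weights (default equal).
#' @return data.frame: `park_id`, `C`, `T`, `D`, `level`, `label`,
#'   sorted by descending D.
#' @export
coupling_table <- function(scores, weights = NULL, floor = 0.01) {
  u <- subsystem_scores(scores, floor = floor)
  ucols <- setdiff(names(u), "park_id")
  rows <- lapply(seq_len(nrow(u)), function(i) {
    ui <- as.numeric(u[i, ucols])
    C <- round(coupling_degree(ui), 3)
    T_ <- round(coordination_index(ui, weights), 3)
    cc <- coupling_coordination(C, T_)
    data.frame(park_id = u$park_id[i], C = C, T = T_, D = cc$D,
               level = cc$level, label = cc$label)
  })
  out <- do.call(rbind, rows)
  out[order(-out$D, out$park_id), , drop = FALSE]
}
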