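#' Min-max normalization of raw indicators
#'
#' `value = (raw - min) / (max - min)` per indicator, with config-supplied
#' bounds. Identity bounds `(0, 1)` leave values unchanged, which is how
#' already-normalized reference tables are consumed. Bounds are supplied
#' rather than derived across parks because the published scheme cannot be
#' a cross-park min-max (no column attains both 0 and 1 and one indicator
#' is negative for one park).
#'
#' @param raw data.frame with `park_id` and indicator columns `C1`..`C12`
#'   (raw values).
#' @param bounds named list: indicator name -> `c(min, max)` with
#'   `max > min`. Missing indicators default to identity `(0, 1)`.
#' @return data.frame with `park_id` and normalized `C1`..`C12`.
#' @export
normalize_indicators <- function(raw, bounds = list()) {
  stopifnot("park_id" %in% names(raw))
  ind <- indicator_names()
  missing <- setdiff(ind, names(raw))
  if (length(missing))
    stop("missing indicator column(s): ", paste(missing, collapse = ", "))
  out <- raw[c("park_id", ind)]
  for (nm in ind) {
    b <- bounds[[nm]] %||% c(0, 1)
    if (length(b) != 2 || !(b[2] > b[1]))
      stop("degenerate normalization bounds for ", nm)
    out[[nm]] <- (raw[[nm]] - b[1]) / (b[2] - b[1])
  }
  out
}

indicator_names <- function() paste0("C", 1:12)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dimension composites from the 12 normalized indicators
#'
#' Horizontal = mean(C1..C4), vertical = mean(C5..C8), three-dimensional =
#' mean(C9..C12), overall = mean(C1..C12). Arithmetic means are the
#' default aggregator (they reproduce the published composite values; a
#' geometric mean would collapse under near-zero terrain-position
#' indicators). Values are rounded half-even to `digits` decimals for
#' reporting.
#'
#' @param v data.frame with `park_id` and normalized `C1`..`C12` (one or
#'   more rows), or a bare numeric vector of 12 indicators.
#' @param aggregator `"arithmetic"` (default) or `"geometric"`.
#' @param digits reporting precision (4, matching the published tables);
#'   `NA` for unrounded.
#' @return data.frame: `park_id`, `horizontal`, `vertical`,
#'   `three_dimensional`, `overall`.
#' @export
dimension_scores <- function(v, aggregator = c("arithmetic", "geometric"),
                             digits = 4) {
  aggregator <- match.arg(aggregator)
  if (is.numeric(v) && is.null(dim(v))) {
    v <- as.data.frame(as.list(stats::setNames(v, indicator_names())))
    v$park_id <- "park"
  }
  ind <- indicator_names()
  missing <- setdiff(ind, names(v))
  if (length(missing))
    stop("missing indicator(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(as.matrix(v[ind]))))
    stop("non-finite indicator value(s)")
  agg <- if (aggregator == "arithmetic") {
    function(m) rowMeans(m)
  } else {
    function(m) apply(m, 1L, function(x) {
      if (any(x <= 0)) stop("geometric mean undefined for values <= 0")
      exp(mean(log(x)))
    })
  }
  m <- as.matrix(v[ind])
  out <- data.frame(
    park_id = v$park_id,
    horizontal = agg(m[, 1:4, drop = FALSE]),
    vertical = agg(m[, 5:8, drop = FALSE]),
    three_dimensional = agg(m[, 9:12, drop = FALSE]),
    overall = agg(m)
  )
  if (!is.na(digits))
    out[-1] <- lapply(out[-1], round, digits = digits)
  out
}

#' Jenks natural breaks (exact dynamic programming)
#'
#' Partitions values into `k` contiguous classes minimizing the total
#' within-class sum of squared deviations (the Fisher optimal-partition
#' dynamic program — exact, not the iterative heuristic). Classes are
#' numbered `1` for the highest-value block down to `k` for the lowest,
#' matching a grading where grade 1 is best.
#'
#' @param values numeric vector.
#' @param k number of classes, `1 <= k <=` number of distinct values.
#' @return integer vector of class assignments aligned with `values`.
#' @export
natural_breaks <- function(values, k) {
  stopifnot(is.numeric(values), k >= 1)
  n_distinct <- length(unique(values))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the ", n_distinct, " distinct values")
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  # prefix sums for O(1) within-class SSE
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) { # cells i..j (1-based, inclusive)
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      c_try <- cost[m - 1, i - 1] + sse(i, j)
      if (c_try < cost[m, j]) { cost[m, j] <- c_try; back[m, j] <- i }
    }
  }
  cls_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else back[m, j]
    cls_sorted[i:j] <- m
    j <- i - 1L
  }
  # identical values must share a class: DP on sorted data guarantees
  # contiguity; force ties into the class of their first occurrence
  for (v in unique(x[duplicated(x)]))
    cls_sorted[x == v] <- cls_sorted[which(x == v)[1]]
  cls_sorted <- match(cls_sorted, sort(unique(cls_sorted))) # close any gaps
  cls <- integer(n)
  cls[ord] <- cls_sorted
  # renumber: class 1 = highest block
  max(cls) + 1L - cls
}
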