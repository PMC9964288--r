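#' Review records
#'
#' Reads a review table (CSV, UTF-8, header row) with columns `park_id`,
#' `target` (`"landscape"` for reviews addressing the landscape
#' specifically, `"park"` for general park reviews) and `text`; an
#' optional `score` column carries precomputed sentiment on the 0-10
#' scale. Rows with empty text are dropped and counted, mirroring the
#' cleaning of a raw social-media corpus.
#'
#' @param path CSV file path.
#' @return data.frame of records with attribute `n_dropped`.
#' @export
read_reviews <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  need <- c("park_id", "target", "text")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("review table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!df$target %in% c("landscape", "park"))
  if (length(bad))
    stop("unknown target label '", df$target[bad[1]], "' in row ", bad[1])
  empty <- is.na(df$text) | trimws(df$text) == ""
  out <- df[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(empty)
  out
}

#' Lexicon-based sentiment scoring on the 0-10 scale
#'
#' The default scorer is a transparent stand-in for a full sentiment
#' engine: it tokenizes on whitespace (lower-cased, punctuation stripped),
#' counts positive and negative lexicon hits, and returns
#' `5 + 5 * (pos - neg) / (pos + neg)`, clipped to `[0, 10]`; texts with
#' no hits (including empty text) score the neutral 5. Scores above 5
#' mean positive emotional perception. Any function
#' `(character) -> numeric in [0, 10]` can be plugged in instead, e.g. a
#' CJK-capable engine.
#'
#' @param texts character vector.
#' @param scorer scoring function; defaults to [lexicon_scorer()] with the
#'   packaged lexicons.
#' @return numeric vector of scores in `[0, 10]`.
#' @export
score_sentiment <- function(texts, scorer = NULL) {
  if (is.null(scorer)) scorer <- lexicon_scorer()
  s <- scorer(as.character(texts))
  if (any(s < 0 | s > 10, na.rm = TRUE))
    stop("scorer returned values outside [0, 10]")
  s
}

#' @param positive,negative character vectors of lexicon terms; default to
#'   the packaged English term lists.
#' @param segmenter tokenizer hook, `(character) -> list of token vectors`;
#'   defaults to whitespace splitting (sufficient for Latin-script and
#'   synthetic token text; plug in a CJK segmenter for Chinese).
#' @rdname score_sentiment
#' @export
lexicon_scorer <- function(positive = NULL, negative = NULL,
                           segmenter = NULL) {
  if (is.null(positive)) positive <- default_lexicon("positive")
  if (is.null(negative)) negative <- default_lexicon("negative")
  if (is.null(segmenter)) segmenter <- whitespace_tokens
  force(positive); force(negative)
  function(texts) {
    vapply(segmenter(texts), function(tok) {
      pos <- sum(tok %in% positive)
      neg <- sum(tok %in% negative)
      if (pos + neg == 0) return(5)
      min(10, max(0, 5 + 5 * (pos - neg) / (pos + neg)))
    }, numeric(1))
  }
}

whitespace_tokens <- function(texts) {
  texts[is.na(texts)] <- ""
  strsplit(tolower(gsub("[[:punct:]]", " ", texts)), "\\s+")
}

default_lexicon <- function(which = c("positive", "negative")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("lexicon_", which, ".txt"),
                      package = "waterscape")
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

#' Per-park sentiment summary
#'
#' Review records carry one of two targets: `"landscape"` for reviews of
#' the landscape itself and `"park"` for general park evaluations. The
#' summary reports
#' * `relative_evaluation_rate` = 100 * n_landscape / n_park,
#' * `landscape_emotional_value` = mean score of landscape records,
#' * `park_emotional_value` = mean score of park records,
#' * `relative_emotional_value` = landscape / park emotional value
#'   (computed on unrounded means, then rounded; > 1 means the landscape
#'   attracts positive perception beyond the park baseline).
#' Emotional values and rates are rounded half-even to 1 decimal.
#'
#' @param records data.frame from [read_reviews()]; a `score` column is
#'   used when present, otherwise texts are scored with `scorer`.
#' @param scorer optional scoring function for [score_sentiment()].
#' @param digits reporting precision (1 decimal); `NA` for unrounded.
#' @return data.frame, one row per park: `park_id`, `n_landscape`,
#'   `n_park`, `relative_evaluation_rate`, `landscape_emotional_value`,
#'   `park_emotional_value`, `relative_emotional_value`.
#' @export
summarize_park <- function(records, scorer = NULL, digits = 1) {
  if (nrow(records) == 0) stop("no review records")
  if (is.null(records$score) || all(is.na(records$score)))
    records$score <- score_sentiment(records$text, scorer)
  if (any(records$score < 0 | records$score > 10))
    stop("scores must lie in [0, 10]")
  parks <- unique(records$park_id)
  rows <- lapply(parks, function(pk) {
    rec <- records[records$park_id == pk, , drop = FALSE]
    is_ls <- rec$target == "landscape"
    n_ls <- sum(is_ls)
    n_park <- sum(!is_ls)
    if (n_park == 0) stop("park ", pk, " has zero park evaluations")
    ls_val <- if (n_ls > 0) mean(rec$score[is_ls]) else NA_real_
    pk_val <- mean(rec$score[!is_ls])
    if (pk_val <= 0)
      stop("park ", pk, " has zero park emotional value; ratio undefined")
    data.frame(
      park_id = pk, n_landscape = n_ls, n_park = n_park,
      relative_evaluation_rate = 100 * n_ls / n_park,
      landscape_emotional_value = ls_val,
      park_emotional_value = pk_val,
      relative_emotional_value = ls_val / pk_val
    )
  })
  out <- do.call(rbind, rows)
  if (!is.na(digits)) {
    cols <- c("relative_evaluation_rate", "landscape_emotional_value",
              "park_emotional_value", "relative_emotional_value")
    out[cols] <- lapply(out[cols], round, digits = digits)
  }
  out
}

#' Rate-emotion regression
#'
#' Ordinary least squares of the relative emotional value (emotional
#' perception) on the landscape relative evaluation rate (landscape
#' experience), with the two-sided p-value for the slope. A significant
#' positive slope indicates that stronger landscape experience goes with
#' better emotional perception.
#'
#' @param summaries data.frame with `relative_evaluation_rate` and
#'   `relative_emotional_value` columns (e.g. from [summarize_park()]).
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fit_rate_emotion_regression <- function(summaries) {
  x <- summaries$relative_evaluation_rate
  y <- summaries$relative_emotional_value
  n <- length(x)
  if (n < 3) stop("need at least 3 parks for the regression")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (stats::sd(y) == 0 || nrow(sm$coefficients) < 2) 1
       else sm$coefficients["x", "Pr(>|t|)"]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = p,
       n = n)
}

#' Five-sense word frequencies
#'
#' Counts lexicon-term occurrences per sense (vision, smell, hearing,
#' touch, taste, feeling) across a corpus; term-level output is ranked by
#' count with lexicographic tie-break.
#'
#' @param texts character vector.
#' @param lexicon named list mapping each sense to a character vector of
#'   terms; defaults to the packaged sense lexicon. Term sets must be
#'   disjoint.
#' @param segmenter tokenizer hook as in [lexicon_scorer()].
#' @return list: `by_sense` (named integer vector) and `terms`
#'   (data.frame `sense`, `term`, `count`, ranked).
#' @export
sense_word_frequency <- function(texts, lexicon = NULL, segmenter = NULL) {
  if (is.null(lexicon)) lexicon <- default_sense_lexicon()
  if (length(lexicon) == 0 || all(lengths(lexicon) == 0))
    stop("empty sense lexicon")
  all_terms <- unlist(lexicon, use.names = FALSE)
  if (anyDuplicated(all_terms))
    stop("sense term sets must be disjoint")
  if (is.null(segmenter)) segmenter <- whitespace_tokens
  toks <- unlist(segmenter(texts), use.names = FALSE)
  rows <- do.call(rbind, lapply(names(lexicon), function(sense) {
    terms <- lexicon[[sense]]
    if (length(terms) == 0) return(NULL)
    data.frame(sense = sense, term = terms,
               count = vapply(terms, function(tm) sum(toks == tm),
                              integer(1)),
               row.names = NULL)
  }))
  rows <- rows[order(-rows$count, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  by_sense <- vapply(lexicon, function(terms)
    sum(rows$count[rows$term %in% terms]), numeric(1))
  list(by_sense = by_sense, terms = rows)
}

default_sense_lexicon <- function() {
  path <- system.file("extdata", "lexicon_senses.csv",
                      package = "waterscape")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  split(df$term, df$sense)
}
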