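test_that("default lexicon scorer: neutral, saturated, mixed, symmetric", {
  expect_equal(score_sentiment("concrete path near the gate"), 5)
  expect_equal(score_sentiment(""), 5)
  expect_equal(score_sentiment("beautiful pleasant quiet"), 10)
  expect_equal(score_sentiment("pleasant beautiful quiet noisy"), 7.5)
  expect_equal(score_sentiment("Noisy, dirty!"), 0)   # punctuation/case

  # symmetry: swapping lexicons maps s to 10 - s
  pos <- c("good", "nice"); neg <- c("bad", "grim")
  fwd <- lexicon_scorer(pos, neg)
  rev <- lexicon_scorer(neg, pos)
  texts <- c("good bad bad", "nice nice", "grim", "nothing here")
  expect_equal(score_sentiment(texts, rev),
               10 - score_sentiment(texts, fwd))
})

test_that("park summaries reproduce the published worked examples", {
  # 410 landscape and 1376 park evaluations, emotional values 7.2 and 3.5
  qcp <- data.frame(
    park_id = "QCP",
    target = c(rep("landscape", 410), rep("park", 1376)),
    text = "x",
    score = c(rep(7.2, 410), rep(3.5, 1376)))
  s <- summarize_park(qcp)
  expect_equal(s$relative_evaluation_rate, 29.8)
  expect_equal(s$landscape_emotional_value, 7.2)
  expect_equal(s$park_emotional_value, 3.5)
  expect_equal(s$relative_emotional_value, 2.1)

  # 10 of 28, values 7.8 and 4.5 -> rate 35.7, ratio 1.73 -> 1.7
  ywp <- data.frame(
    park_id = "YWP",
    target = c(rep("landscape", 10), rep("park", 28)),
    text = "x",
    score = c(rep(7.8, 10), rep(4.5, 28)))
  s2 <- summarize_park(ywp)
  expect_equal(s2$relative_evaluation_rate, 35.7)
  expect_equal(s2$relative_emotional_value, 1.7)

  # identical scores for both targets -> ratio exactly 1
  eq <- data.frame(park_id = "P", target = c("landscape", "park"),
                   text = "x", score = 6)
  expect_equal(summarize_park(eq)$relative_emotional_value, 1)

  expect_error(summarize_park(qcp[0, ]), "no review records")
  zero <- data.frame(park_id = "Z", target = c("landscape", "park"),
                     text = "x", score = 0)
  expect_error(summarize_park(zero), "ratio undefined")
})

test_that("relative emotional value > 1 iff landscape beats park baseline", {
  set.seed(13)
  for (i in 1:6) {
    ls_val <- runif(1, 1, 9); pk_val <- runif(1, 1, 9)
    rec <- data.frame(
      park_id = "P", target = c(rep("landscape", 30), rep("park", 70)),
      text = "x", score = c(rep(ls_val, 30), rep(pk_val, 70)))
    s <- summarize_park(rec, digits = NA)
    expect_equal(s$relative_emotional_value > 1, ls_val > pk_val)
  }
  # published fixture: exactly 9 of 12 parks exceed 1
  t5 <- waterscape_fixture("table5")
  expect_equal(sum(t5$relative_emotional_value > 1), 9)
})

test_that("rate-emotion regression agrees with the correlation oracle", {
  coll <- data.frame(relative_evaluation_rate = c(10, 20, 30, 40),
                     relative_emotional_value = c(1, 2, 3, 4))
  r <- suppressWarnings(fit_rate_emotion_regression(coll)) # perfect fit
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 0.1)

  flat <- data.frame(relative_evaluation_rate = c(10, 20, 30),
                     relative_emotional_value = c(2, 2, 2))
  rf <- suppressWarnings(fit_rate_emotion_regression(flat))
  expect_equal(rf$slope, 0)
  expect_equal(rf$r_squared, 0)

  set.seed(4)
  for (i in 1:3) {
    n <- sample(4:12, 1)
    df <- data.frame(relative_evaluation_rate = runif(n, 5, 45),
                     relative_emotional_value = runif(n, 0.3, 3))
    fit <- fit_rate_emotion_regression(df)
    expect_equal(fit$r_squared,
                 cor(df$relative_evaluation_rate,
                     df$relative_emotional_value)^2)
    expect_true(fit$p_value > 0 && fit$p_value <= 1)
    expect_equal(fit$n, n)
  }
  expect_error(fit_rate_emotion_regression(coll[1:2, ]), "at least 3")
})

test_that("five-sense word frequencies match hand counts", {
  lex <- list(vision = c("scenery", "colorful"),
              smell = c("fragrance"),
              hearing = c("birdsong"),
              touch = character(0), taste = character(0),
              feeling = c("happy"))
  z <- sense_word_frequency(character(0), lex)
  expect_true(all(z$by_sense == 0))

  four <- sense_word_frequency(rep("scenery", 4), lex)
  expect_equal(unname(four$by_sense["vision"]), 4)
  expect_equal(sum(four$by_sense), 4)

  corpus <- c("colorful scenery and fragrance", "happy birdsong, happy!",
              "scenery scenery")
  wf <- sense_word_frequency(corpus, lex)
  expect_equal(unname(wf$by_sense[c("vision", "smell", "hearing",
                                    "feeling")]),
               c(4, 1, 1, 2))
  # ranked terms, lexicographic tie-break on equal counts
  expect_equal(wf$terms$term[1], "scenery")
  tied <- wf$terms[wf$terms$count == 1, ]
  expect_equal(tied$term, sort(tied$term))

  expect_error(sense_word_frequency("x", list(vision = character(0))),
               "empty")
  expect_error(
    sense_word_frequency("x", list(vision = "dup", smell = "dup")),
    "disjoint")
})
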