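test_that("the packaged word fixture loads with the expected composition", {
  wl <- load_word_list(word_fixture_path())
  expect_s3_class(wl, "word_list")
  expect_equal(nrow(wl), 200L)
  expect_equal(unname(attr(wl, "counts")), c(100L, 100L))
  expect_true(all(wl$odor_rating >= 1 & wl$odor_rating <= 10))
})

test_that("word-list validation catches bad input and accepts empty lists", {
  f <- tempfile(fileext = ".csv")
  header <- paste(c("label", "is_odor", "is_living", "is_food", "syllables",
                    "frequency", "concreteness", "arousal", "imageability",
                    "valence", "odor_rating"), collapse = ",")
  writeLines(header, f)
  empty <- load_word_list(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "counts")), c(0L, 0L))

  writeLines(c(header, "rose,TRUE,TRUE,FALSE,1,3,7,4,7,6,11"), f)
  expect_error(load_word_list(f), "odor_rating rating 11")

  writeLines(c(header, "rose,TRUE,TRUE,FALSE,1,3,7,4,7,6,8",
               "rose,FALSE,FALSE,FALSE,1,3,7,4,7,6,2"), f)
  expect_error(load_word_list(f), "duplicate")

  g <- tempfile(fileext = ".csv")
  writeLines("label,is_odor", g)
  expect_error(load_word_list(g), "missing required columns")
})

test_that("trial sequences follow the paradigm structure and are seeded", {
  wl <- synthetic_word_list()
  tt <- make_trial_sequence(wl, 100L, 100L, seed = 1L)
  expect_equal(nrow(tt), 300L)
  expect_equal(length(unique(tt$word)), 200L)
  expect_equal(sum(tt$presentation == 2L), 100L)
  expect_true(all(diff(tt$onset_s) >= 2.2 - 1e-12))
  expect_true(all(diff(tt$onset_s) <= 2.8 + 1e-12))
  # repeats occur strictly after their first presentation
  for (w in unique(tt$word[tt$presentation == 2L])[1:10]) {
    idx <- which(tt$word == w)
    expect_equal(tt$presentation[idx], c(1L, 2L))
  }
  expect_identical(make_trial_sequence(wl, 100L, 100L, seed = 1L), tt)
  expect_false(identical(make_trial_sequence(wl, 100L, 100L, seed = 2L), tt))

  all_once <- make_trial_sequence(wl, 200L, 0L, seed = 1L)
  expect_equal(nrow(all_once), 200L)
  expect_true(all(all_once$presentation == 1L))

  expect_error(make_trial_sequence(wl, 150L, 100L, seed = 1L),
               "need 250 words")

  lagged <- make_trial_sequence(wl, 10L, 5L, seed = 3L, min_lag = 2L)
  for (w in unique(lagged$word[lagged$presentation == 2L])) {
    expect_gte(diff(which(lagged$word == w)), 2L)
  }
})

test_that("first-presentation ranks are uniform over seeded sequences", {
  wl <- synthetic_word_list()
  target <- wl$label[c(1, 75, 150)]
  n_seq <- 600L
  ranks <- matrix(NA_integer_, n_seq, length(target))
  for (i in seq_len(n_seq)) {
    tt <- make_trial_sequence(wl, 100L, 100L, seed = 10000L + i)
    first <- tt[tt$presentation == 1L, ]
    ranks[i, ] <- match(target, first$word)
  }
  # a word is presented in 150 of 200 draws; conditional on being drawn its
  # first-presentation rank among the 200 first presentations is uniform
  for (j in seq_along(target)) {
    r <- ranks[!is.na(ranks[, j]), j]
    bins <- cut(r, breaks = seq(0, 200, by = 20))
    expect_gt(stats::chisq.test(table(bins))$p.value, 0.001)
  }
})

test_that("summary-statistic t-tests match closed forms and item data", {
  odor <- summary_stat_ttest(5.6, 1.8, 100, 1.5, 0.5, 100)
  expect_lt(odor$p, 0.0001)
  expect_equal(odor$df, 198)

  same <- summary_stat_ttest(3.0, 1.0, 50, 3.0, 1.0, 50)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  freq <- summary_stat_ttest(4.9, 7.1, 100, 6.1, 6.4, 100)
  expect_equal(freq$t, -1.2554, tolerance = 1e-4)
  expect_equal(freq$df, 198)
  expect_equal(freq$p, 0.2108, tolerance = 1e-3)

  # degenerate: zero variance, unequal means
  expect_warning(deg <- summary_stat_ttest(1, 0, 10, 2, 0, 10),
                 "zero variance")
  expect_equal(deg$p, 0)

  # agreement with an item-level pooled t-test on data with those moments
  n <- 30
  x <- 5 + 1.3 * sqrt((n - 1) / n) * rep_len(c(-1, 1), n)
  y <- 4.2 + 0.7 * sqrt((n - 1) / n) * rep_len(c(-1, 1), n)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  mine <- summary_stat_ttest(mean(x), sd(x), n, mean(y), sd(y), n)
  expect_equal(mine$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(mine$p, tt$p.value, tolerance = 1e-10)

  # Welch variant agrees with t.test default
  tw <- stats::t.test(x, y)
  minew <- summary_stat_ttest(mean(x), sd(x), n, mean(y), sd(y), n,
                              welch = TRUE)
  expect_equal(minew$t, unname(tw$statistic), tolerance = 1e-10)
  expect_equal(minew$df, unname(tw$parameter), tolerance = 1e-10)
})

test_that("property matching reports matched properties and the odor contrast", {
  wl <- synthetic_word_list()
  cmp <- compare_word_properties(wl)
  matched <- cmp[cmp$property != "odor_rating", ]
  expect_true(all(matched$p > 0.2))
  expect_lt(cmp$p[cmp$property == "odor_rating"], 1e-10)

  # control words duplicating odor words' values -> all t = 0
  dup <- wl
  for (col in c("syllables", "frequency", "concreteness", "arousal",
                "imageability", "valence", "odor_rating")) {
    dup[[col]][!dup$is_odor] <- dup[[col]][dup$is_odor]
  }
  cmp0 <- compare_word_properties(dup)
  expect_true(all(abs(cmp0$t) < 1e-12))

  # a property entirely missing is flagged absent, not an error
  wl2 <- wl
  wl2$arousal <- NA_real_
  cmp2 <- compare_word_properties(wl2)
  expect_false(cmp2$present[cmp2$property == "arousal"])
  expect_true(all(cmp2$present[cmp2$property != "arousal"]))

  # shifted odor rating dominates; other properties stay matched
  set.seed(99)
  syn <- wl
  syn$odor_rating <- pmin(10, pmax(1, 3 + 4 * syn$is_odor + rnorm(200)))
  cmp3 <- compare_word_properties(as_word_list(syn))
  expect_lt(cmp3$p[cmp3$property == "odor_rating"], 1e-10)
  expect_true(all(cmp3$p[!cmp3$property %in% "odor_rating"] > 0.05))
})
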