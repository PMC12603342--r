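# Word stimuli: loading, validation, property matching, trial sequences.

WORD_COLUMNS <- c("label", "is_odor", "is_living", "is_food", "syllables",
                  "frequency", "concreteness", "arousal", "imageability",
                  "valence", "odor_rating")
RATING_COLUMNS <- c("concreteness", "arousal", "imageability", "valence",
                    "odor_rating")

#' Load and validate a word-property table
#'
#' Reads a CSV of object words with category flags (odor-related vs control,
#' living, food) and psycholinguistic properties (syllable count, corpus
#' frequency per million, and 1-10 ratings for concreteness, arousal,
#' imageability, valence, plus the mean odor-relatedness rating).
#'
#' @param path path to a UTF-8 CSV with the columns
#'   `label, is_odor, is_living, is_food, syllables, frequency, concreteness,
#'   arousal, imageability, valence, odor_rating`.
#' @return a `word_list` data frame (one row per word) with attribute
#'   `counts` giving the number of odor-related and control words.
#' @export
load_word_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(WORD_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("word list is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_word_list(df[WORD_COLUMNS])
}

#' Validate a data frame of word properties
#'
#' @param df data frame with the `word_list` columns.
#' @return validated `word_list` object.
#' @export
as_word_list <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("is_odor", "is_living", "is_food")) {
    df[[col]] <- as.logical(df[[col]])
  }
  if (nrow(df) > 0L) {
    if (anyDuplicated(df$label)) {
      dup <- df$label[duplicated(df$label)][1L]
      stop(sprintf("duplicate word label '%s'", dup), call. = FALSE)
    }
    if (any(is.na(df$is_odor))) {
      stop("is_odor must be TRUE/FALSE for every word", call. = FALSE)
    }
    bad_syll <- which(!is.na(df$syllables) & df$syllables < 1)
    if (length(bad_syll) > 0L) {
      stop(sprintf("row %d ('%s'): syllables must be >= 1",
                   bad_syll[1L], df$label[bad_syll[1L]]), call. = FALSE)
    }
    bad_freq <- which(!is.na(df$frequency) & df$frequency < 0)
    if (length(bad_freq) > 0L) {
      stop(sprintf("row %d ('%s'): frequency must be >= 0",
                   bad_freq[1L], df$label[bad_freq[1L]]), call. = FALSE)
    }
    for (col in RATING_COLUMNS) {
      bad <- which(!is.na(df[[col]]) & (df[[col]] < 1 | df[[col]] > 10))
      if (length(bad) > 0L) {
        stop(sprintf("row %d ('%s'): %s rating %.3g outside [1, 10]",
                     bad[1L], df$label[bad[1L]], col, df[[col]][bad[1L]]),
             call. = FALSE)
      }
    }
  }
  class(df) <- c("word_list", "data.frame")
  attr(df, "counts") <- c(odor = sum(df$is_odor), control = sum(!df$is_odor))
  df
}

#' @export
print.word_list <- function(x, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("word_list: %d words (%d odor-related, %d control)\n",
              nrow(x), cts[["odor"]], cts[["control"]]))
  invisible(x)
}

#' Deterministic synthetic word-property list
#'
#' Builds a synthetic 200-word list (100 odor-related, 100 control) whose
#' per-group means and sample SDs of syllable count, frequency, concreteness,
#' arousal, imageability, valence and odor rating equal a fixed set of target
#' moments typical of a property-matched German object-word pool. Each
#' symmetric property uses a two-point construction (half the group at
#' m - s*sqrt((n-1)/n), half at m + s*sqrt((n-1)/n)) so the sample moments are
#' exact; frequency, which must stay non-negative under a large SD, uses a
#' skewed two-point construction with 5 high-value items per group. Category
#' flags mark more odor words as living (60 vs 40) and food-related
#' (50 vs 10), mimicking the natural confound between odor sources and
#' living/food categories.
#'
#' @return a `word_list` with 200 rows.
#' @export
synthetic_word_list <- function() {
  n <- 100L
  sym_points <- function(m, s) {
    d <- s * sqrt((n - 1) / n)
    rep_len(c(m - d, m + d), n)
  }
  skew_points <- function(m, s, k = 5L) {
    d_hi <- s * sqrt((n - 1) * (n - k) / (k * n))
    lo <- m - k * d_hi / (n - k)
    c(rep(m + d_hi, k), rep(lo, n - k))
  }
  grp <- function(prefix, is_odor, syl, freq, conc, aro, img, val, odr,
                  n_living, n_food) {
    data.frame(
      label = sprintf("%s_%03d", prefix, seq_len(n)),
      is_odor = is_odor,
      is_living = seq_len(n) <= n_living,
      is_food = seq_len(n) <= n_food,
      syllables = sym_points(syl[1], syl[2]),
      frequency = skew_points(freq[1], freq[2]),
      concreteness = sym_points(conc[1], conc[2]),
      arousal = sym_points(aro[1], aro[2]),
      imageability = sym_points(img[1], img[2]),
      valence = sym_points(val[1], val[2]),
      odor_rating = sym_points(odr[1], odr[2]),
      stringsAsFactors = FALSE
    )
  }
  odor <- grp("odor", TRUE, c(2.1, 0.9), c(4.9, 7.1), c(6.7, 0.8),
              c(3.7, 0.8), c(6.5, 0.9), c(5.4, 1.1), c(5.6, 1.8), 60L, 50L)
  ctrl <- grp("control", FALSE, c(2.2, 0.6), c(6.1, 6.4), c(6.8, 0.8),
              c(3.6, 0.9), c(6.6, 0.8), c(5.3, 0.7), c(1.5, 0.5), 40L, 10L)
  as_word_list(rbind(odor, ctrl))
}

#' Path to the packaged synthetic word-property fixture
#' @return file path of the installed CSV.
#' @export
word_fixture_path <- function() {
  system.file("extdata", "word_properties_synthetic.csv",
              package = "odorunits", mustWork = TRUE)
}

#' Two-sided unpaired t-test from summary statistics
#'
#' Student (pooled-variance) two-sample t-test computed from group means, SDs
#' and sizes, as used for checking that stimulus groups are matched on
#' psycholinguistic properties. Set `welch = TRUE` for the unequal-variance
#' (Welch-Satterthwaite) form.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param welch use Welch's correction instead of pooled variance.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
summary_stat_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                               welch = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    warning("both groups have zero variance with unequal means; p set to 0")
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Property-matching t-tests between odor-related and control words
#'
#' One two-sided unpaired t-test per psycholinguistic property (item-level
#' values, odor vs control group), plus the odor-rating contrast. No
#' multiplicity correction is applied: this is a matching check, not
#' inference, and each property is reported at its raw p.
#'
#' @param words a `word_list`.
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return data frame with one row per property: group means/SDs, `t`, `df`,
#'   `p`, and `present` (FALSE when a property is entirely missing).
#' @export
compare_word_properties <- function(words, welch = FALSE) {
  stopifnot(inherits(words, "word_list"))
  if (sum(words$is_odor) == 0L || sum(!words$is_odor) == 0L) {
    stop("both odor-related and control words are required", call. = FALSE)
  }
  props <- c("syllables", "frequency", "concreteness", "arousal",
             "imageability", "valence", "odor_rating")
  rows <- lapply(props, function(p) {
    x <- words[[p]][words$is_odor]
    y <- words[[p]][!words$is_odor]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      return(data.frame(property = p, mean_odor = NA_real_,
                        sd_odor = NA_real_, mean_control = NA_real_,
                        sd_control = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, present = FALSE))
    }
    tt <- summary_stat_ttest(mean(x), stats::sd(x), length(x),
                             mean(y), stats::sd(y), length(y), welch = welch)
    data.frame(property = p, mean_odor = mean(x), sd_odor = stats::sd(x),
               mean_control = mean(y), sd_control = stats::sd(y),
               t = tt$t, df = tt$df, p = tt$p, present = TRUE)
  })
  do.call(rbind, rows)
}

#' Build a randomized continuous-recognition trial sequence
#'
#' Draws `n_once` words to be shown once and `n_twice` words to be shown
#' twice from the word list, and arranges the `n_once + 2*n_twice`
#' presentations in uniformly random order (so every repeat necessarily
#' follows its first presentation). Onsets follow the paradigm timing: each
#' word is displayed for 0.5 s followed by a post-stimulus interval drawn
#' uniformly from [1.7, 2.3] s.
#'
#' @param words a `word_list`.
#' @param n_once,n_twice number of words shown once resp. twice.
#' @param seed integer seed (required: the sequence is part of the design).
#' @param display_s stimulus display duration in seconds.
#' @param isi_range_s post-stimulus interval range in seconds.
#' @param lead_in_s time of the first onset from session start.
#' @param min_lag,max_lag optional bounds (in trials) on the spacing between
#'   a word's first and second presentation; NULL leaves the lag free.
#' @param extra_delay_s optional per-trial extra delay (scalar or vector of
#'   length n trials) appended to the inter-onset interval, e.g. to model
#'   slow-response screens.
#' @return a `trial_table` data frame with columns `trial_index, onset_s,
#'   word, is_odor, is_living, is_food, presentation`.
#' @export
make_trial_sequence <- function(words, n_once = 100L, n_twice = 100L,
                                seed, display_s = 0.5,
                                isi_range_s = c(1.7, 2.3), lead_in_s = 1.0,
                                min_lag = NULL, max_lag = NULL,
                                extra_delay_s = NULL) {
  stopifnot(inherits(words, "word_list"), n_once >= 0L, n_twice >= 0L)
  if (n_once + n_twice > nrow(words)) {
    stop(sprintf("need %d words but the list has only %d",
                 n_once + n_twice, nrow(words)), call. = FALSE)
  }
  n_trials <- n_once + 2L * n_twice
  with_seed(seed, {
    chosen <- sample(nrow(words), n_once + n_twice)
    once_idx <- chosen[seq_len(n_once)]
    twice_idx <- chosen[n_once + seq_len(n_twice)]
    tokens <- c(once_idx, rep(twice_idx, 2L))
    ord <- NULL
    for (attempt in seq_len(1000L)) {
      cand <- sample(tokens)
      if (is.null(min_lag) && is.null(max_lag)) {
        ord <- cand
        break
      }
      pos2 <- vapply(twice_idx, function(w) diff(which(cand == w)), numeric(1))
      ok <- TRUE
      if (!is.null(min_lag)) ok <- ok && all(pos2 >= min_lag)
      if (!is.null(max_lag)) ok <- ok && all(pos2 <= max_lag)
      if (ok) {
        ord <- cand
        break
      }
    }
    if (is.null(ord)) {
      stop("could not satisfy the repeat-lag constraints in 1000 attempts",
           call. = FALSE)
    }
    presentation <- as.integer(stats::ave(ord, ord, FUN = seq_along))
    ioi <- display_s + stats::runif(n_trials, isi_range_s[1], isi_range_s[2])
    if (!is.null(extra_delay_s)) {
      ioi <- ioi + rep_len(extra_delay_s, n_trials)
    }
    onsets <- lead_in_s + c(0, cumsum(ioi[-n_trials]))
    out <- data.frame(
      trial_index = seq_len(n_trials),
      onset_s = onsets,
      word = words$label[ord],
      is_odor = words$is_odor[ord],
      is_living = words$is_living[ord],
      is_food = words$is_food[ord],
      presentation = presentation,
      stringsAsFactors = FALSE
    )
    class(out) <- c("trial_table", "data.frame")
    out
  })
}
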