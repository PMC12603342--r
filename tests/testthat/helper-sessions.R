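# Shared fixtures: scaled-down synthetic sessions and hand-built spike sets.

# A small session (30 units, 60 trials) for fast structural tests.
small_config <- function(seed = 1L,
                         units_per_region = c(amygdala = 10L,
                                              hippocampus = 8L,
                                              entorhinal = 4L,
                                              parahippocampal = 4L,
                                              piriform = 4L),
                         n_once = 20L, n_twice = 20L, ...) {
  synthetic_config(units_per_region = units_per_region,
                   n_once = n_once, n_twice = n_twice, seed = seed, ...)
}

small_session <- function(seed = 1L, ...) {
  simulate_session(small_config(seed = seed, ...))
}

small_tensor <- function(seed = 1L, ...) {
  s <- small_session(seed = seed, ...)
  suppressMessages(rate_tensor(bin_spike_counts(s, s$trials)))
}

# Deterministic one-unit session: spikes at given onset-relative times on
# each of n trials, onsets 10 s apart.
relative_spike_session <- function(rel_times, n_trials = 2L,
                                   region = "amygdala") {
  onsets <- 10 * seq_len(n_trials)
  trials <- data.frame(trial_index = seq_len(n_trials), onset_s = onsets,
                       word = sprintf("w%02d", seq_len(n_trials)),
                       is_odor = rep_len(c(TRUE, FALSE), n_trials),
                       is_living = FALSE, is_food = FALSE,
                       presentation = 1L)
  class(trials) <- c("trial_table", "data.frame")
  spikes <- sort(as.vector(outer(rel_times, onsets, `+`)))
  list(spikes = list(u1 = spikes),
       units = data.frame(unit_id = "u1", region = region),
       trials = trials)
}

# Build a cell_means object directly from a matrix (units x 2T).
cells_from_matrix <- function(Y, region, scheme = "odor", T_ = ncol(Y) / 2) {
  structure(list(Y = Y, unit_id = sprintf("u%03d", seq_len(nrow(Y))),
                 region = factor(region), scheme = scheme,
                 levels = c(scheme, paste0("non-", scheme)), T_ = T_),
            class = "cell_means")
}

# Independent split-plot oracle: base aov() with explicit Error strata.
aov_split_plot_oracle <- function(Y, region, T_ = ncol(Y) / 2) {
  N <- nrow(Y)
  df <- expand.grid(unit = seq_len(N), cat = 1:2, time = seq_len(T_))
  df$y <- Y[cbind(df$unit, (df$cat - 1L) * T_ + df$time)]
  df$region <- factor(region[df$unit])
  df$unit <- factor(df$unit)
  df$cat <- factor(df$cat)
  df$time <- factor(df$time)
  fit <- summary(stats::aov(y ~ region * cat * time +
                              Error(unit / (cat * time)), data = df))
  get_F <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(REGION = get_F("Error: unit", "region"),
    CAT = get_F("Error: unit:cat", "cat"),
    CAT_REGION = get_F("Error: unit:cat", "region:cat"),
    TIME = get_F("Error: unit:time", "time"),
    TIME_REGION = get_F("Error: unit:time", "region:time"),
    CAT_TIME = get_F("Error: unit:cat:time", "cat:time"),
    CAT_TIME_REGION = get_F("Error: unit:cat:time", "region:cat:time"))
}

expect_anova_matches_oracle <- function(Y, region, tol = 1e-8) {
  mine <- mixed_anova(cells_from_matrix(Y, region))
  oracle <- aov_split_plot_oracle(Y, region)
  get <- function(e) mine$F[mine$effect == e]
  expect_equal(get("REGION"), unname(oracle["REGION"]), tolerance = tol)
  expect_equal(get("ODOR"), unname(oracle["CAT"]), tolerance = tol)
  expect_equal(get("ODOR:REGION"), unname(oracle["CAT_REGION"]),
               tolerance = tol)
  expect_equal(get("TIME"), unname(oracle["TIME"]), tolerance = tol)
  expect_equal(get("TIME:REGION"), unname(oracle["TIME_REGION"]),
               tolerance = tol)
  expect_equal(get("ODOR:TIME"), unname(oracle["CAT_TIME"]),
               tolerance = tol)
  expect_equal(get("ODOR:TIME:REGION"),
               unname(oracle["CAT_TIME_REGION"]), tolerance = tol)
}
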