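test_that("spike counts land in the correct half-open windows", {
  ses <- relative_spike_session(c(0.1, 0.6, 0.6, 1.9), n_trials = 1L)
  counts <- bin_spike_counts(ses$spikes, ses$trials,
                             first_presentation_only = TRUE)
  expect_equal(as.vector(counts[1, 1, ]), c(0, 1, 2, 0, 1))

  # boundary spike at exactly +0.5 s belongs to [0.5, 1.0)
  ses2 <- relative_spike_session(0.5, n_trials = 1L)
  counts2 <- bin_spike_counts(ses2$spikes, ses2$trials)
  expect_equal(as.vector(counts2[1, 1, ]), c(0, 0, 1, 0, 0))

  # baseline spike
  ses3 <- relative_spike_session(-0.1, n_trials = 1L)
  counts3 <- bin_spike_counts(ses3$spikes, ses3$trials)
  expect_equal(as.vector(counts3[1, 1, ]), c(1, 0, 0, 0, 0))

  # no spikes at all
  ses4 <- relative_spike_session(numeric(0), n_trials = 3L)
  counts4 <- bin_spike_counts(ses4$spikes, ses4$trials)
  expect_true(all(counts4 == 0))
})

test_that("second presentations are excluded when requested", {
  s <- small_session(seed = 2)
  c_first <- bin_spike_counts(s, s$trials, first_presentation_only = TRUE)
  c_all <- bin_spike_counts(s, s$trials, first_presentation_only = FALSE)
  expect_equal(dim(c_first)[2], sum(s$trials$presentation == 1L))
  expect_equal(dim(c_all)[2], nrow(s$trials))
})

test_that("window binning never counts more spikes than exist", {
  s <- small_session(seed = 4)
  counts <- bin_spike_counts(s, s$trials, first_presentation_only = FALSE)
  per_unit <- apply(counts, 1L, sum)
  expect_true(all(per_unit <= lengths(s$spikes)))
})

test_that("count-to-rate conversion uses trials and true window duration", {
  expect_equal(mean_rate_per_window(200, 200, 0.5), 2.0)
  expect_equal(mean_rate_per_window(0, 200, 0.5), 0)
  expect_equal(mean_rate_per_window(80, 200, 0.2), 2.0)
  expect_error(mean_rate_per_window(10, 0, 0.5), "n_trials")
})

test_that("the minimum-rate filter keeps units reaching threshold anywhere", {
  fake_rt <- function(mean_rates) {
    m <- do.call(rbind, mean_rates)
    rownames(m) <- names(mean_rates)
    counts <- array(0L, dim = c(nrow(m), 1L, 5L),
                    dimnames = list(names(mean_rates), NULL, NULL))
    structure(list(counts = counts, mean_rate = m, threshold_hz = 2.0),
              class = "rate_tensor")
  }
  rt <- fake_rt(list(uA = c(1, 1, 2.5, 1, 1),     # peaks above threshold
                     uB = rep(1.9, 5),            # below everywhere
                     uC = c(2.0, 0, 0, 0, 0)))    # exactly at threshold
  expect_identical(apply_rate_filter(rt), c("uA", "uC"))
  expect_identical(apply_rate_filter(rt, threshold_hz = 0),
                   c("uA", "uB", "uC"))
  expect_identical(apply_rate_filter(rt, threshold_hz = 10), character(0))

  # end to end: a unit whose deterministic rates are (0, 2, 4, 2, 2) Hz
  rel <- c(0.25, 0.6, 0.65, 1.2, 1.7)  # 1,2,1,1 spikes in the post windows
  ses <- relative_spike_session(rel, n_trials = 4L)
  rte <- suppressMessages(rate_tensor(bin_spike_counts(ses$spikes,
                                                       ses$trials)))
  expect_equal(unname(rte$mean_rate[1, ]), c(0, 2, 4, 2, 2))
  expect_true(rte$units$retained[1])
})

test_that("the uniform half-second conversion option rescales the baseline", {
  ses <- relative_spike_session(c(-0.1, 0.2), n_trials = 4L)
  rt_dur <- suppressMessages(rate_tensor(bin_spike_counts(ses$spikes,
                                                          ses$trials)))
  rt_half <- suppressMessages(
    rate_tensor(bin_spike_counts(ses$spikes, ses$trials),
                baseline_conversion = "half_second"))
  expect_equal(rt_dur$mean_rate[1, 1], 5.0)   # 1 spike / 0.2 s
  expect_equal(rt_half$mean_rate[1, 1], 2.0)  # 1 spike x2 rule
  expect_equal(rt_dur$mean_rate[1, 2], rt_half$mean_rate[1, 2])
})

test_that("z-scoring normalizes against baseline statistics", {
  # baseline rates {10, 0} Hz across 2 trials -> mu_b = 5 Hz, sigma_b =
  # sqrt(50); a post window whose rate is 5 Hz must map to z = 0
  onsets <- c(10, 20)
  trials <- data.frame(trial_index = 1:2, onset_s = onsets, word = c("a", "b"),
                       is_odor = c(TRUE, FALSE), is_living = FALSE,
                       is_food = FALSE, presentation = 1L)
  class(trials) <- c("trial_table", "data.frame")
  # trial 1: 2 baseline spikes (10 Hz), 3 spikes in [0.5, 1.0) (6 Hz)
  # trial 2: 0 baseline spikes,         2 spikes in [0.5, 1.0) (4 Hz)
  spikes <- list(u1 = sort(c(9.85, 9.95, 10.6, 10.7, 10.8, 20.6, 20.8)))
  counts <- bin_spike_counts(spikes, trials)
  rt <- suppressMessages(rate_tensor(counts))
  expect_equal(rt$mu_b[[1]], 5)
  expect_equal(rt$sigma_b[[1]], sqrt(50))
  w2 <- 3L  # [0.5, 1.0)
  expect_equal(unname(rt$rate[1, , w2]), c(6, 4))
  expect_equal(unname(rt$z[1, , w2]), c(1, -1) / sqrt(50))
  expect_equal((5 - rt$mu_b[[1]]) / rt$sigma_b[[1]], 0)

  # normalization identity on a simulated session
  rt2 <- small_tensor(seed = 6)
  z <- zscore_rates(rt2)
  bz <- z[, , 1]
  expect_equal(unname(rowMeans(bz)), rep(0, nrow(bz)), tolerance = 1e-10)
  expect_equal(unname(apply(bz, 1L, sd)), rep(1, nrow(bz)),
               tolerance = 1e-10)
})

test_that("units with constant baseline are excluded from z analyses", {
  ses <- relative_spike_session(c(-0.1, 0.7), n_trials = 5L)
  expect_message(rt <- rate_tensor(bin_spike_counts(ses$spikes, ses$trials)),
                 "zero baseline SD")
  expect_false(rt$units$zscore_ok[1])
  expect_equal(dim(zscore_rates(rt))[1], 0L)
})

test_that("truncated windows at the recording end raise a warning", {
  ses <- relative_spike_session(0.1, n_trials = 2L)
  expect_warning(bin_spike_counts(ses$spikes, ses$trials,
                                  session_end_s = 21),
                 "truncated")
})

test_that("long-format export round-trips counts and rates", {
  rt <- small_tensor(seed = 9)
  long <- rate_tensor_long(rt)
  expect_equal(nrow(long), prod(dim(rt$counts)))
  expect_equal(sum(long$count), sum(rt$counts))
  i <- which(long$unit_id == rt$units$unit_id[3] &
               long$window == "post_0000_0500")
  expect_equal(long$rate_hz[i], unname(rt$rate[3, , 2]))
})
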