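# Window firing rates: spike binning, rate conversion, inclusion filter,
# baseline z-scoring.

#' Analysis windows relative to stimulus onset
#'
#' The default window set is a 200 ms baseline `[-0.2, 0)` s plus four
#' non-overlapping 500 ms post-stimulus windows covering `[0, 2)` s. With
#' `post_bin_ms = 100` the post-stimulus period is instead divided into
#' twenty 100 ms windows (higher temporal resolution); the baseline is
#' unchanged. All windows are half-open `[start, end)`.
#'
#' @param post_bin_ms width of the post-stimulus windows, 500 or 100.
#' @return a `window_set` data frame with columns `window`, `start_s`,
#'   `end_s`, `duration_s`, `is_baseline`.
#' @export
window_set <- function(post_bin_ms = 500) {
  stopifnot(post_bin_ms %in% c(500, 100))
  n <- 2000L %/% post_bin_ms
  # one shared edge vector so starts and ends are bitwise identical where
  # windows abut (required by the tiling check in bin_spike_counts)
  edges <- c(-0.2, (0:n) * post_bin_ms / 1000)
  starts <- edges[seq_len(n + 1L)]
  ends <- edges[seq_len(n + 1L) + 1L]
  out <- data.frame(
    window = c("baseline", sprintf("post_%04.0f_%04.0f",
                                   starts[-1L] * 1000, ends[-1L] * 1000)),
    start_s = starts,
    end_s = ends,
    is_baseline = c(TRUE, rep(FALSE, n)),
    stringsAsFactors = FALSE
  )
  out$duration_s <- out$end_s - out$start_s
  class(out) <- c("window_set", "data.frame")
  out
}

#' Bin spike counts into onset-locked windows
#'
#' Counts spikes of every unit in each half-open window `[start, end)`
#' relative to each trial onset. By default only first-presentation trials
#' enter the analysis. Windows must not overlap across consecutive trials
#' (guaranteed by the paradigm's minimum 2.2 s inter-onset interval).
#'
#' @param spikes a `spike_session`, or a list of sorted spike-time vectors
#'   (one per unit, named), or a data frame with columns `unit_id`,
#'   `spike_time_s` (optionally `region`).
#' @param trials a `trial_table`.
#' @param windows a [window_set()].
#' @param first_presentation_only restrict to `presentation == 1` trials.
#' @param session_end_s optional recording end time; trials whose last
#'   window extends beyond it are counted as-is with a truncation warning.
#' @return integer array `[unit, trial, window]` with dimnames; attribute
#'   `units` carries the unit/region table when available.
#' @export
bin_spike_counts <- function(spikes, trials, windows = window_set(),
                             first_presentation_only = TRUE,
                             session_end_s = NULL) {
  units_df <- NULL
  if (inherits(spikes, "spike_session")) {
    if (is.null(session_end_s)) session_end_s <- spikes$session_end_s
    units_df <- spikes$units
    spikes <- spikes$spikes
  } else if (is.data.frame(spikes)) {
    units_df <- unique(spikes[intersect(c("unit_id", "region"),
                                        names(spikes))])
    spikes <- split(spikes$spike_time_s, spikes$unit_id)[
      unique(units_df$unit_id)]
  }
  stopifnot(is.list(spikes), inherits(trials, "data.frame"))
  if (first_presentation_only) {
    trials <- trials[trials$presentation == 1L, , drop = FALSE]
  }
  onsets <- trials$onset_s
  stopifnot(!is.unsorted(onsets))
  n_w <- nrow(windows)
  rel_edges <- sort(unique(c(windows$start_s, windows$end_s)))
  n_cell <- length(rel_edges) - 1L
  # map each elementary interval between consecutive edges to its window
  cell_win <- rep(NA_integer_, n_cell)
  for (w in seq_len(n_w)) {
    inside <- rel_edges[-length(rel_edges)] >= windows$start_s[w] &
      rel_edges[-1L] <= windows$end_s[w]
    cell_win[inside] <- w
  }
  if (anyNA(cell_win)) stop("windows do not tile their span", call. = FALSE)
  edges <- as.vector(outer(rel_edges, onsets, `+`))
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("trial windows overlap: inter-onset intervals are too short",
         call. = FALSE)
  }
  if (!is.null(session_end_s) &&
      max(onsets) + max(windows$end_s) > session_end_s) {
    warning("analysis windows of late trials extend beyond the recording; ",
            "counts are truncated at the recording end")
  }
  n_u <- length(spikes)
  n_t <- length(onsets)
  counts <- array(0L, dim = c(n_u, n_t, n_w),
                  dimnames = list(names(spikes), trials$trial_index,
                                  windows$window))
  n_edge_cells <- length(rel_edges)  # cells per trial incl. trailing gap
  for (u in seq_len(n_u)) {
    idx <- findInterval(spikes[[u]], edges)
    idx <- idx[idx >= 1L & idx <= n_t * n_edge_cells]
    cell <- (idx - 1L) %% n_edge_cells + 1L
    keep <- cell <= n_cell
    idx <- idx[keep]
    cell <- cell[keep]
    tr <- (idx - 1L) %/% n_edge_cells + 1L
    w <- cell_win[cell]
    tab <- table(factor(tr, levels = seq_len(n_t)),
                 factor(w, levels = seq_len(n_w)))
    counts[u, , ] <- counts[u, , ] + as.integer(tab)
  }
  attr(counts, "trials") <- trials
  attr(counts, "windows") <- windows
  attr(counts, "units") <- units_df
  counts
}

#' Across-trial mean firing rate of one window
#'
#' Total spikes across trials divided by the number of trials and by the
#' window duration, i.e. the count-to-Hz conversion (x2 for a 500 ms bin,
#' x5 for the 200 ms baseline).
#'
#' @param total_count summed spike count across trials.
#' @param n_trials number of trials.
#' @param window_duration_s window duration in seconds.
#' @return mean rate in Hz.
#' @export
mean_rate_per_window <- function(total_count, n_trials, window_duration_s) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  stop_if_not_scalar(window_duration_s, "window_duration_s", lower = 1e-12)
  total_count / n_trials / window_duration_s
}

#' Build the per-unit window rate tensor
#'
#' Converts binned counts to rates in Hz (count / window duration), computes
#' each unit's baseline mean and SD across trials, z-scores every window
#' against those baseline statistics, and applies the minimum-rate inclusion
#' filter. Units whose baseline SD is zero cannot be z-scored and are marked
#' `zscore_ok = FALSE` (with a logged reason); units whose maximum
#' across-trial mean rate over all windows is below `threshold_hz` are
#' marked `retained = FALSE`.
#'
#' @param counts output of [bin_spike_counts()].
#' @param threshold_hz minimum-rate inclusion threshold (default 2 Hz).
#' @param baseline_conversion `"duration"` converts the baseline count with
#'   its true 200 ms duration (x5); `"half_second"` applies the x2
#'   conversion of the 500 ms bins uniformly to all windows.
#' @return a `rate_tensor` list: arrays `counts`, `rate`, `z`
#'   `[unit, trial, window]`; `mu_b`, `sigma_b` per unit; `mean_rate`
#'   `[unit, window]`; data frames `units` (with `retained`, `zscore_ok`),
#'   `trials`, `windows`.
#' @export
rate_tensor <- function(counts, threshold_hz = 2.0,
                        baseline_conversion = c("duration", "half_second")) {
  baseline_conversion <- match.arg(baseline_conversion)
  windows <- attr(counts, "windows")
  trials <- attr(counts, "trials")
  units_df <- attr(counts, "units")
  stopifnot(!is.null(windows), !is.null(trials))
  dur <- windows$duration_s
  if (baseline_conversion == "half_second") {
    dur <- rep(0.5, nrow(windows))
  }
  rate <- sweep(counts * 1.0, 3L, dur, `/`)
  b <- which(windows$is_baseline)
  stopifnot(length(b) == 1L)
  mu_b <- apply(rate[, , b, drop = FALSE], 1L, mean)
  sigma_b <- apply(rate[, , b, drop = FALSE], 1L, stats::sd)
  z <- sweep(sweep(rate, 1L, mu_b, `-`), 1L, sigma_b, `/`)
  mean_rate <- apply(rate, c(1L, 3L), mean)
  retained <- apply(mean_rate, 1L, max) >= threshold_hz
  zscore_ok <- sigma_b > 0
  if (any(!zscore_ok)) {
    message(sum(!zscore_ok), " unit(s) excluded from z-based analyses: ",
            "zero baseline SD (silent or constant in the baseline window)")
  }
  if (is.null(units_df)) {
    units_df <- data.frame(unit_id = rownames(counts),
                           region = NA_character_,
                           stringsAsFactors = FALSE)
  }
  units_df <- units_df[match(rownames(counts), units_df$unit_id), ,
                       drop = FALSE]
  units_df$retained <- retained
  units_df$zscore_ok <- zscore_ok
  structure(list(counts = counts, rate = rate, z = z, mu_b = mu_b,
                 sigma_b = sigma_b, mean_rate = mean_rate,
                 units = units_df, trials = trials, windows = windows,
                 threshold_hz = threshold_hz,
                 baseline_conversion = baseline_conversion),
            class = "rate_tensor")
}

#' Units passing the minimum-rate filter
#'
#' A unit is retained iff its across-trial mean rate reaches `threshold_hz`
#' in at least one analysis window (baseline included).
#'
#' @param rt a [rate_tensor()].
#' @param threshold_hz threshold in Hz; defaults to the tensor's.
#' @return character vector of retained unit ids.
#' @export
apply_rate_filter <- function(rt, threshold_hz = rt$threshold_hz) {
  stopifnot(inherits(rt, "rate_tensor"))
  rownames(rt$counts)[apply(rt$mean_rate, 1L, max) >= threshold_hz]
}

#' Baseline-normalized rates of the analyzable units
#'
#' Returns the z-score array restricted to units that pass both the
#' minimum-rate filter and the nonzero-baseline-SD requirement. For every
#' such unit the z-scored baseline window has mean 0 and SD 1 across trials
#' by construction.
#'
#' @param rt a [rate_tensor()].
#' @return numeric array `[unit, trial, window]` of z-scores.
#' @export
zscore_rates <- function(rt) {
  stopifnot(inherits(rt, "rate_tensor"))
  keep <- rt$units$retained & rt$units$zscore_ok
  rt$z[keep, , , drop = FALSE]
}

#' @export
print.rate_tensor <- function(x, ...) {
  cat(sprintf(paste0("rate_tensor: %d units x %d trials x %d windows; ",
                     "%d retained (>= %.3g Hz), %d z-scorable\n"),
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$units$retained), x$threshold_hz,
              sum(x$units$zscore_ok)))
  invisible(x)
}

#' Export a rate tensor as a long-format data frame
#'
#' @param rt a [rate_tensor()].
#' @return data frame with columns `unit_id, region, trial_index, window,
#'   count, rate_hz, z`.
#' @export
rate_tensor_long <- function(rt) {
  stopifnot(inherits(rt, "rate_tensor"))
  d <- dim(rt$counts)
  grid <- expand.grid(unit = seq_len(d[1]), trial = seq_len(d[2]),
                      window = seq_len(d[3]))
  data.frame(unit_id = rownames(rt$counts)[grid$unit],
             region = rt$units$region[grid$unit],
             trial_index = rt$trials$trial_index[grid$trial],
             window = rt$windows$window[grid$window],
             count = as.vector(rt$counts),
             rate_hz = as.vector(rt$rate),
             z = as.vector(rt$z),
             stringsAsFactors = FALSE)
}
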