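# Seeded synthetic recording sessions: inhomogeneous Poisson spike trains
# with known ground-truth response structure.

#' Sample an inhomogeneous Poisson spike train
#'
#' Emits spikes from a piecewise-constant rate function. Counts in any
#' subinterval are Poisson with mean equal to the integral of the rate, and
#' disjoint intervals are independent: each constant segment draws a Poisson
#' count and scatters the spikes uniformly within the segment.
#'
#' @param breaks_s increasing vector of segment boundaries (seconds),
#'   length m + 1 for m segments.
#' @param rates_hz non-negative rate (Hz) of each of the m segments.
#' @param seed optional integer seed.
#' @return sorted numeric vector of spike times.
#' @export
poisson_spike_train <- function(breaks_s, rates_hz, seed = NULL) {
  stopifnot(length(breaks_s) == length(rates_hz) + 1L)
  if (any(diff(breaks_s) <= 0)) {
    stop("segment boundaries must be strictly increasing", call. = FALSE)
  }
  if (any(rates_hz < 0)) stop("rates must be non-negative", call. = FALSE)
  with_seed(seed, {
    durs <- diff(breaks_s)
    counts <- stats::rpois(length(rates_hz), rates_hz * durs)
    total <- sum(counts)
    if (total == 0L) return(numeric(0))
    starts <- rep(breaks_s[-length(breaks_s)], counts)
    sort(starts + stats::runif(total) * rep(durs, counts))
  })
}

#' Configuration for a synthetic recording session
#'
#' Defaults encode the study conditions: 195 units split 57/54/22/29/33
#' across amygdala, hippocampus, entorhinal, parahippocampal and piriform
#' cortex; a 300-trial continuous-recognition run (100 words shown once, 100
#' twice, 0.5 s display, 1.7-2.3 s jittered post-stimulus interval);
#' log-normal baseline rates with median 4 Hz so that most units clear the
#' 2 Hz inclusion filter; per-region fractions of stimulus-responsive and
#' odor-associated units mirroring the observed prevalence (19/17/27/10/12%
#' responsive, 12/2/5/3/3% odor-associated); multiplicative response gains of
#' 2 (increases) or 0.5 (decreases) applied inside a [0.3, 1.0] s response
#' window, which concentrates the strongest modulation in the 500-1000 ms
#' analysis bin.
#'
#' @param units_per_region named integer vector of unit counts, names from
#'   [mtl_regions()].
#' @param fraction_responsive,fraction_odor_associated per-region fractions
#'   (recycled if scalar) of units with post-stimulus resp. odor-dependent
#'   rate modulation.
#' @param response_gain,decrease_gain multiplicative rate factor during the
#'   response window for increasing resp. decreasing responsive units.
#' @param prop_response_decrease fraction of responsive units that decrease.
#' @param odor_gain,odor_decrease_gain extra factor on odor-word trials for
#'   odor-associated units (increase resp. decrease variants).
#' @param prop_odor_decrease fraction of odor-associated units that decrease.
#' @param response_window_s response window relative to onset, within [0, 2].
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline rate distribution (default median 4 Hz).
#' @param n_once,n_twice trial-sequence composition.
#' @param display_s,isi_range_s paradigm timing.
#' @param seed integer seed controlling every random draw.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(units_per_region = c(amygdala = 57L,
                                                  hippocampus = 54L,
                                                  entorhinal = 22L,
                                                  parahippocampal = 29L,
                                                  piriform = 33L),
                             fraction_responsive = c(amygdala = 0.19,
                                                     hippocampus = 0.17,
                                                     entorhinal = 0.27,
                                                     parahippocampal = 0.10,
                                                     piriform = 0.12),
                             fraction_odor_associated = c(amygdala = 0.12,
                                                          hippocampus = 0.02,
                                                          entorhinal = 0.05,
                                                          parahippocampal = 0.03,
                                                          piriform = 0.03),
                             response_gain = 2.0,
                             decrease_gain = 0.5,
                             prop_response_decrease = 0.3,
                             odor_gain = 2.0,
                             odor_decrease_gain = 0.5,
                             prop_odor_decrease = 0.2,
                             response_window_s = c(0.3, 1.0),
                             baseline_meanlog = log(4),
                             baseline_sdlog = 0.5,
                             n_once = 100L,
                             n_twice = 100L,
                             display_s = 0.5,
                             isi_range_s = c(1.7, 2.3),
                             seed = 1L) {
  regions <- names(units_per_region)
  if (is.null(regions) || !all(regions %in% mtl_regions())) {
    stop("units_per_region must be named with regions from mtl_regions()",
         call. = FALSE)
  }
  expand <- function(x) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, length(regions)), regions)
    if (is.null(names(x))) names(x) <- regions
    x[regions]
  }
  fraction_responsive <- expand(fraction_responsive)
  fraction_odor_associated <- expand(fraction_odor_associated)
  stopifnot(all(units_per_region >= 0L),
            all(fraction_responsive >= 0, fraction_responsive <= 1),
            all(fraction_odor_associated >= 0,
                fraction_odor_associated <= 1),
            response_gain > 0, decrease_gain > 0, odor_gain > 0,
            odor_decrease_gain > 0,
            length(response_window_s) == 2L,
            response_window_s[1] >= 0, response_window_s[2] <= 2.0,
            response_window_s[1] < response_window_s[2])
  structure(list(units_per_region = units_per_region,
                 fraction_responsive = fraction_responsive,
                 fraction_odor_associated = fraction_odor_associated,
                 response_gain = response_gain,
                 decrease_gain = decrease_gain,
                 prop_response_decrease = prop_response_decrease,
                 odor_gain = odor_gain,
                 odor_decrease_gain = odor_decrease_gain,
                 prop_odor_decrease = prop_odor_decrease,
                 response_window_s = response_window_s,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 n_once = as.integer(n_once),
                 n_twice = as.integer(n_twice),
                 display_s = display_s,
                 isi_range_s = isi_range_s,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a full recording session with known ground truth
#'
#' Builds a randomized trial sequence, assigns each unit a baseline rate and
#' (per the configured fractions) response and odor gains, then emits an
#' inhomogeneous Poisson spike train across the whole session, including
#' inter-trial intervals. A unit's rate on a trial is
#' `baseline * response_gain` inside its response window, further multiplied
#' by `odor_gain` when the unit is odor-associated and the trial's word is
#' odor-related. Odor-associated units modulate inside the same response
#' window whether or not they are also stimulus-responsive.
#'
#' @param config a [synthetic_config()].
#' @param words a `word_list`; defaults to the packaged synthetic 200-word
#'   fixture.
#' @return a `spike_session` list with elements `spikes` (list of sorted
#'   spike-time vectors, one per unit), `units` (data frame: unit_id, region,
#'   baseline_rate_hz, response_gain, odor_gain, is_responsive,
#'   is_odor_associated), `trials` (a `trial_table`), and `config`.
#' @export
simulate_session <- function(config = synthetic_config(),
                             words = synthetic_word_list()) {
  stopifnot(inherits(config, "synthetic_config"))
  trials <- make_trial_sequence(words, config$n_once, config$n_twice,
                                seed = config$seed,
                                display_s = config$display_s,
                                isi_range_s = config$isi_range_s)
  n_trials <- nrow(trials)
  session_end <- trials$onset_s[n_trials] + config$display_s +
    config$isi_range_s[2] + 1.0
  regions <- names(config$units_per_region)
  n_units <- sum(config$units_per_region)
  with_seed(config$seed + 1L, {
    region <- rep(regions, config$units_per_region)
    unit_id <- sprintf("u%03d_%s", seq_len(n_units), region)
    baseline <- stats::rlnorm(n_units, config$baseline_meanlog,
                              config$baseline_sdlog)
    is_responsive <- logical(n_units)
    is_odor_associated <- logical(n_units)
    for (r in regions) {
      in_r <- which(region == r)
      n_resp <- round(config$fraction_responsive[[r]] * length(in_r))
      n_odor <- round(config$fraction_odor_associated[[r]] * length(in_r))
      if (n_resp > 0) is_responsive[sample(in_r, n_resp)] <- TRUE
      if (n_odor > 0) is_odor_associated[sample(in_r, n_odor)] <- TRUE
    }
    resp_gain <- ifelse(is_responsive,
                        ifelse(stats::runif(n_units) <
                                 config$prop_response_decrease,
                               config$decrease_gain, config$response_gain),
                        1.0)
    odor_gain <- ifelse(is_odor_associated,
                        ifelse(stats::runif(n_units) <
                                 config$prop_odor_decrease,
                               config$odor_decrease_gain, config$odor_gain),
                        1.0)
    # Shared segmentation: [gap][response window] per trial, then tail.
    win <- config$response_window_s
    starts <- trials$onset_s + win[1]
    ends <- trials$onset_s + win[2]
    breaks <- c(0, as.vector(rbind(starts, ends)), session_end)
    idx_win <- seq(2L, 2L * n_trials, by = 2L)  # response-window segments
    spikes <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      seg_gain <- rep(1.0, 2L * n_trials + 1L)
      seg_gain[idx_win] <- resp_gain[u] *
        ifelse(is_odor_associated[u] & trials$is_odor, odor_gain[u], 1.0)
      spikes[[u]] <- poisson_spike_train(breaks, baseline[u] * seg_gain)
    }
    units <- data.frame(unit_id = unit_id, region = region,
                        baseline_rate_hz = baseline,
                        response_gain = resp_gain, odor_gain = odor_gain,
                        is_responsive = is_responsive,
                        is_odor_associated = is_odor_associated,
                        stringsAsFactors = FALSE)
    structure(list(spikes = stats::setNames(spikes, unit_id), units = units,
                   trials = trials, config = config,
                   session_end_s = session_end),
              class = "spike_session")
  })
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf(paste0("spike_session: %d units, %d trials, %.0f s; ",
                     "%d responsive, %d odor-associated (ground truth)\n"),
              nrow(x$units), nrow(x$trials), x$session_end_s,
              sum(x$units$is_responsive), sum(x$units$is_odor_associated)))
  invisible(x)
}
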