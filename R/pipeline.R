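# Pipeline orchestration and delimited-text round-tripping. Times are
# seconds as decimal fractions with the session clock origin at recording
# start; all interchange formats are plain CSV.

#' Write / read spike trains as CSV
#'
#' Long format with columns `unit_id, region, spike_time_s`.
#'
#' @param session a `spike_session`, or a data frame in the long format.
#' @param path output CSV path.
#' @return `read_spike_trains` returns a data frame sorted by unit and time.
#' @export
write_spike_trains <- function(session, path) {
  df <- if (inherits(session, "spike_session")) {
    n <- lengths(session$spikes)
    data.frame(unit_id = rep(session$units$unit_id, n),
               region = rep(session$units$region, n),
               spike_time_s = unlist(session$spikes, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else session
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(df)))
  df[order(df$unit_id, df$spike_time_s), , drop = FALSE]
}

#' Write / read a trial-event table as CSV
#' @param trials a `trial_table`.
#' @param path CSV path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "onset_s", "word", "is_odor", "presentation")
  stopifnot(all(need %in% names(df)))
  if (is.unsorted(df$onset_s, strictly = TRUE)) {
    stop("trial onsets must be strictly increasing", call. = FALSE)
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Pipeline configuration
#'
#' Collects every analysis parameter: input paths (NULL for a simulated
#' session), output directory, the minimum-rate threshold, family alpha and
#' correction method, category schemes for the ensemble ANOVAs, temporal
#' resolution, cluster-permutation settings, and the mandatory seed that
#' drives every stochastic stage.
#'
#' @param spikes_path,events_path,words_path input CSVs; when
#'   `spikes_path` is NULL a synthetic session is simulated.
#' @param out_dir output directory for the report bundle.
#' @param threshold_hz minimum-rate inclusion threshold.
#' @param alpha_family family-wise alpha of the four-window screening.
#' @param correction `"bonferroni"` or `"BH"`.
#' @param schemes category schemes for the ensemble ANOVAs.
#' @param time_resolution_ms post-window width (500 or 100).
#' @param n_perm cluster-permutation count.
#' @param cluster_region region for the ensemble cluster test.
#' @param seed integer seed.
#' @param synthetic a [synthetic_config()] used when simulating (its seed
#'   is overridden by `seed`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(spikes_path = NULL, events_path = NULL,
                            words_path = NULL, out_dir = tempfile("odorrun"),
                            threshold_hz = 2.0, alpha_family = 0.05,
                            correction = "bonferroni",
                            schemes = c("odor", "living", "food"),
                            time_resolution_ms = 500, n_perm = 1000L,
                            cluster_region = "amygdala", seed = 1L,
                            synthetic = synthetic_config()) {
  stopifnot(alpha_family > 0, alpha_family < 1, threshold_hz >= 0)
  synthetic$seed <- as.integer(seed)
  structure(list(spikes_path = spikes_path, events_path = events_path,
                 words_path = words_path, out_dir = out_dir,
                 threshold_hz = threshold_hz, alpha_family = alpha_family,
                 correction = correction, schemes = schemes,
                 time_resolution_ms = time_resolution_ms,
                 n_perm = as.integer(n_perm),
                 cluster_region = cluster_region, seed = as.integer(seed),
                 synthetic = synthetic),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (synthetic-generator keys under `synthetic:`).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn_args <- y$synthetic
  y$synthetic <- NULL
  syn <- if (is.null(syn_args)) synthetic_config() else
    do.call(synthetic_config, syn_args)
  do.call(pipeline_config, c(y, list(synthetic = syn)))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: obtain a session (read the spike/event
#' CSVs, or simulate one with the configured generator), bin and normalize
#' window rates, screen units for stimulus responsiveness and odor
#' association, build the per-region prevalence tables, run the ensemble
#' mixed ANOVAs with LSD post-hocs for every configured category scheme
#' plus the food-within-odor control, and run the ensemble cluster
#' permutation test in the configured region. Every table is written as CSV
#' into `out_dir` together with a plain-text report; re-running with the
#' same config and seed reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the session, rate tensor, screening
#'   results, summaries, ANOVA tables, post-hocs and cluster result.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  words <- if (is.null(config$words_path)) synthetic_word_list() else
    load_word_list(config$words_path)
  if (is.null(config$spikes_path)) {
    stage_log("simulate", "synthetic session, seed %d", config$seed)
    session <- simulate_session(config$synthetic, words = words)
    write_spike_trains(session, out("spikes.csv"))
    write_trial_table(session$trials, out("trials.csv"))
    utils::write.csv(session$units, out("ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    stage_log("load", "reading %s", config$spikes_path)
    sp <- read_spike_trains(config$spikes_path)
    trials <- read_trial_table(config$events_path)
    units <- unique(sp[intersect(c("unit_id", "region"), names(sp))])
    session <- structure(list(spikes = split(sp$spike_time_s, sp$unit_id)[
                                units$unit_id],
                              units = units, trials = trials,
                              session_end_s = max(sp$spike_time_s) + 1),
                         class = "spike_session")
  }

  stage_log("rates", "binning %d units x %d first-presentation trials",
            nrow(session$units), sum(session$trials$presentation == 1L))
  windows <- window_set(post_bin_ms = config$time_resolution_ms)
  counts <- bin_spike_counts(session, session$trials, windows,
                             session_end_s = session$session_end_s)
  rt <- rate_tensor(counts, threshold_hz = config$threshold_hz)
  utils::write.csv(rate_tensor_long(rt), out("rate_tensor.csv"),
                   row.names = FALSE, quote = FALSE)

  screening <- summaries <- list()
  if (config$time_resolution_ms == 500) {
    for (type in c("stimulus", "odor")) {
      stage_log("screen", "%s screening (%s)", type, config$correction)
      res <- screen_units(rt, type = type,
                          alpha_family = config$alpha_family,
                          correction = config$correction)
      screening[[type]] <- res
      summaries[[type]] <- summarize_screening(res)
      utils::write.csv(res, out(sprintf("screening_%s.csv", type)),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(summaries[[type]],
                       out(sprintf("summary_%s.csv", type)),
                       row.names = FALSE, quote = FALSE)
    }
  }

  anovas <- posthocs <- list()
  for (scheme in config$schemes) {
    stage_log("ensemble", "mixed ANOVA, scheme %s", scheme)
    cells <- build_cell_means(rt, scheme = scheme)
    anovas[[scheme]] <- mixed_anova(cells)
    posthocs[[scheme]] <- lsd_posthoc(cells)
    utils::write.csv(anovas[[scheme]], out(sprintf("anova_%s.csv", scheme)),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(posthocs[[scheme]],
                     out(sprintf("posthoc_%s.csv", scheme)),
                     row.names = FALSE, quote = FALSE)
  }
  food_ctrl <- tryCatch(food_within_odor_anova(rt), error = function(e) {
    stage_log("ensemble", "food-within-odor control skipped: %s",
              conditionMessage(e))
    NULL
  })
  if (!is.null(food_ctrl)) {
    utils::write.csv(food_ctrl, out("anova_food_within_odor.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  cluster <- NULL
  if (!is.null(config$cluster_region)) {
    stage_log("clusters", "ensemble cluster test, %s, %d permutations",
              config$cluster_region, config$n_perm)
    ds <- ensemble_difference_series(session, rt,
                                     region = config$cluster_region)
    cluster <- cluster_permutation_test(ds, paired = TRUE,
                                        n_perm = config$n_perm,
                                        seed = config$seed)
    utils::write.csv(cluster$clusters, out("clusters_ensemble.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  report <- c(
    sprintf("odorunits pipeline report (seed %d)", config$seed),
    sprintf("units: %d total, %d retained (>= %.3g Hz), %d z-scorable",
            nrow(rt$units), sum(rt$units$retained), config$threshold_hz,
            sum(rt$units$retained & rt$units$zscore_ok)),
    "",
    unlist(lapply(names(summaries), function(type) {
      s <- summaries[[type]]
      c(sprintf("%s screening:", type),
        utils::capture.output(print(s)), "")
    })),
    unlist(lapply(names(anovas), function(s) {
      c(sprintf("ANOVA (%s):", s),
        utils::capture.output(print(anovas[[s]], row.names = FALSE)), "")
    })),
    if (!is.null(cluster)) c("Ensemble cluster test:",
                             utils::capture.output(print(cluster)))
  )
  writeLines(report, out("report.txt"))
  stage_log("report", "written to %s", config$out_dir)
  invisible(list(session = session, rate_tensor = rt,
                 screening = screening, summaries = summaries,
                 anovas = anovas, posthocs = posthocs,
                 food_within_odor = food_ctrl, cluster = cluster,
                 out_dir = config$out_dir))
}
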