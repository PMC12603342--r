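# Cluster-based permutation tests on time-resolved firing rates: per-bin
# t statistics thresholded at a sample-level alpha, contiguous
# supra-threshold clusters scored by their summed t, and a max-statistic
# permutation null controlling family-wise error over time.

#' Time-resolved (instantaneous) firing-rate estimate
#'
#' Bins each trial's spikes at `bin_ms` resolution on an onset-locked time
#' axis and convolves the counts with a truncated Gaussian kernel
#' (normalized to unit mass over its support), scaled to Hz. Kernel mass
#' conservation means the rate integrates to approximately the spike count
#' for spikes away from the span edges.
#'
#' @param spikes sorted spike times (seconds, session clock) of one unit.
#' @param trials a `trial_table` (first presentations are used when a
#'   `presentation` column exists).
#' @param bin_ms bin width in ms.
#' @param kernel_sd_ms Gaussian kernel SD in ms (0 disables smoothing).
#' @param span_s analysis span relative to onset; must cover at least
#'   `[-0.2, 2.0]` s.
#' @param first_presentation_only restrict to `presentation == 1` trials.
#' @return a `rate_series` list: `rate` (trials x bins matrix, Hz), `time_s`
#'   (bin centers), `bin_s`, `kernel_sd_s`.
#' @export
instantaneous_rate <- function(spikes, trials, bin_ms = 10,
                               kernel_sd_ms = 50, span_s = c(-0.5, 2.5),
                               first_presentation_only = TRUE) {
  stopifnot(bin_ms > 0, kernel_sd_ms >= 0,
            span_s[1] <= -0.2, span_s[2] >= 2.0)
  if (first_presentation_only && "presentation" %in% names(trials)) {
    trials <- trials[trials$presentation == 1L, , drop = FALSE]
  }
  bin_s <- bin_ms / 1000
  sd_s <- kernel_sd_ms / 1000
  if (6 * sd_s >= diff(span_s)) {
    stop("smoothing kernel is wider than the analysis span", call. = FALSE)
  }
  edges <- seq(span_s[1], span_s[2], by = bin_s)
  n_bins <- length(edges) - 1L
  centers <- edges[-1L] - bin_s / 2
  n_t <- nrow(trials)
  counts <- matrix(0, n_t, n_bins)
  for (i in seq_len(n_t)) {
    rel <- spikes - trials$onset_s[i]
    rel <- rel[rel >= span_s[1] & rel < span_s[2]]
    if (length(rel) > 0L) {
      counts[i, ] <- tabulate(floor((rel - span_s[1]) / bin_s) + 1L,
                              nbins = n_bins)
    }
  }
  if (sd_s > 0) {
    half <- ceiling(3 * sd_s / bin_s)
    kern <- stats::dnorm(seq(-half, half) * bin_s, sd = sd_s)
    kern <- kern / sum(kern)
    pad <- matrix(0, n_t, half)
    padded <- cbind(pad, counts, pad)
    sm <- t(apply(padded, 1L, function(row)
      stats::filter(row, kern, sides = 2L)))
    counts <- sm[, half + seq_len(n_bins), drop = FALSE]
  }
  structure(list(rate = counts / bin_s, time_s = centers, bin_s = bin_s,
                 kernel_sd_s = sd_s),
            class = "rate_series")
}

max_cluster_mass <- function(t_vec, above) {
  # largest |sum of t| over maximal runs of supra-threshold bins of one sign
  if (!any(above)) return(0)
  sgn <- sign(t_vec) * above
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep)) return(0)
  max(abs(vapply(which(keep), function(i)
    sum(t_vec[starts[i]:ends[i]]), numeric(1))))
}

find_clusters <- function(t_vec, above, time_s) {
  sgn <- sign(t_vec) * above
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0)
  data.frame(start_s = time_s[starts[keep]], end_s = time_s[ends[keep]],
             start_bin = starts[keep], end_bin = ends[keep],
             mass = vapply(keep, function(i) sum(t_vec[starts[i]:ends[i]]),
                           numeric(1)))
}

#' Cluster-based permutation test between two rate time series
#'
#' Computes a two-sided t statistic per time bin (paired across
#' observations, or pooled-variance unpaired between the two groups), forms
#' maximal contiguous runs of same-sign bins whose per-bin p falls below
#' `alpha_sample`, and scores each run by its summed t (cluster mass). The
#' null distribution of the maximum absolute cluster mass is built from
#' `n_perm` random sign flips of the paired differences (paired mode) or
#' random reassignments of observations to groups (unpaired mode); each
#' cluster's p-value is `(1 + #{null >= |mass|}) / (n_perm + 1)`, so p has
#' resolution `1/(n_perm + 1)`. Zero-variance bins get t = 0 and can never
#' be supra-threshold.
#'
#' @param a,b observations x bins matrices (trials or units), or
#'   `rate_series` objects; `b = NULL` with `paired = TRUE` treats `a` as
#'   difference series tested against zero.
#' @param paired paired (sign-flip null) or unpaired (label-shuffle null).
#' @param alpha_sample per-bin threshold forming clusters.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draws.
#' @param time_s bin centers; taken from `a` when it is a `rate_series`.
#' @return a `cluster_result` list: `clusters` data frame (start_s, end_s,
#'   mass, p, significant at 0.05), `t` per bin, `supra_threshold_mask`,
#'   `alpha_sample`, `n_perm`, `time_s`.
#' @export
cluster_permutation_test <- function(a, b = NULL, paired = TRUE,
                                     alpha_sample = 0.05, n_perm = 10000L,
                                     seed = 1L, time_s = NULL) {
  if (inherits(a, "rate_series")) {
    if (is.null(time_s)) time_s <- a$time_s
    a <- a$rate
  }
  if (inherits(b, "rate_series")) b <- b$rate
  a <- as.matrix(a)
  if (!is.null(b)) b <- as.matrix(b)
  if (is.null(time_s)) time_s <- seq_len(ncol(a))
  n_bins <- ncol(a)
  if (paired) {
    D <- if (is.null(b)) a else {
      stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b))
      a - b
    }
    n <- nrow(D)
    stopifnot(n >= 2L)
    css <- colSums(D^2)
    t_from_means <- function(M) {
      # M: draws x bins matrix of means under sign flips; column sums of
      # squares are sign-invariant, so the sd comes from css.
      v <- sweep(-(n * M^2), 2L, css, `+`) / (n - 1L)
      v[v < 1e-300] <- Inf  # zero-variance bins -> t = 0
      M / sqrt(v / n)
    }
    t_obs <- drop(t_from_means(matrix(colMeans(D), 1L)))
    df <- n - 1L
    null_max <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      n_perm, n)
      Mp <- (signs %*% D) / n
      Tp <- t_from_means(Mp)
      tcrit <- stats::qt(1 - alpha_sample / 2, df)
      apply(Tp, 1L, function(tv) max_cluster_mass(tv, abs(tv) > tcrit))
    })
  } else {
    stopifnot(!is.null(b), nrow(a) >= 2L, nrow(b) >= 2L)
    X <- rbind(a, b)
    n1 <- nrow(a)
    n2 <- nrow(b)
    N <- n1 + n2
    df <- N - 2L
    sx <- colSums(X)
    sxx <- colSums(X^2)
    t_from_groupsum <- function(S1) {
      # S1: draws x bins sums of the group-1 rows under a label shuffle
      M1 <- S1 / n1
      M2 <- sweep(-S1, 2L, sx, `+`) / n2
      # pooled variance from total SS minus both group mean corrections
      ss_within <- sweep(-(n1 * M1^2 + n2 * M2^2), 2L, sxx, `+`)
      sp2 <- ss_within / df
      sp2[sp2 < 1e-300] <- Inf
      (M1 - M2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
    t_obs <- drop(t_from_groupsum(matrix(colSums(a), 1L)))
    null_max <- with_seed(seed, {
      tcrit <- stats::qt(1 - alpha_sample / 2, df)
      P <- matrix(0, n_perm, N)
      for (i in seq_len(n_perm)) P[i, sample(N, n1)] <- 1
      Tp <- t_from_groupsum(P %*% X)
      apply(Tp, 1L, function(tv) max_cluster_mass(tv, abs(tv) > tcrit))
    })
  }
  tcrit <- stats::qt(1 - alpha_sample / 2, df)
  above <- abs(t_obs) > tcrit
  clusters <- find_clusters(t_obs, above, time_s)
  clusters$p <- vapply(clusters$mass, function(m)
    (1 + sum(null_max >= abs(m))) / (n_perm + 1), numeric(1))
  clusters$significant <- clusters$p < 0.05
  structure(list(clusters = clusters, t = t_obs,
                 supra_threshold_mask = above, df = df,
                 alpha_sample = alpha_sample, n_perm = n_perm,
                 time_s = time_s),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters) > 0L) {
    print(x$clusters[c("start_s", "end_s", "mass", "p", "significant")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Ensemble odor-vs-control difference series across units
#'
#' Builds, for each analyzable unit of a region, the difference between its
#' trial-averaged z-scored instantaneous rate on odor-word trials and on
#' control-word trials, yielding the units x bins matrix used by the paired
#' ensemble cluster test.
#'
#' @param session a `spike_session`.
#' @param rt the session's [rate_tensor()] (provides baseline statistics
#'   and unit inclusion).
#' @param region region to include.
#' @param bin_ms,kernel_sd_ms,span_s passed to [instantaneous_rate()].
#' @return a `rate_series` whose rows are unit-wise odor-minus-control
#'   z-scored rate differences.
#' @export
ensemble_difference_series <- function(session, rt, region = "amygdala",
                                       bin_ms = 10, kernel_sd_ms = 50,
                                       span_s = c(-0.5, 2.5)) {
  stopifnot(inherits(session, "spike_session"))
  keep <- which(rt$units$retained & rt$units$zscore_ok &
                  rt$units$region == region)
  first <- session$trials[session$trials$presentation == 1L, , drop = FALSE]
  odor <- first$is_odor
  out <- NULL
  time_s <- NULL
  for (i in seq_along(keep)) {
    u <- keep[i]
    rs <- instantaneous_rate(session$spikes[[rt$units$unit_id[u]]], first,
                             bin_ms = bin_ms, kernel_sd_ms = kernel_sd_ms,
                             span_s = span_s,
                             first_presentation_only = FALSE)
    zrate <- (rs$rate - rt$mu_b[u]) / rt$sigma_b[u]
    if (is.null(out)) {
      out <- matrix(0, length(keep), ncol(zrate))
      time_s <- rs$time_s
    }
    out[i, ] <- colMeans(zrate[odor, , drop = FALSE]) -
      colMeans(zrate[!odor, , drop = FALSE])
  }
  structure(list(rate = out, time_s = time_s, bin_s = bin_ms / 1000,
                 kernel_sd_s = kernel_sd_ms / 1000),
            class = "rate_series")
}
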