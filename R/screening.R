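# Per-unit screening: stimulus responsiveness (paired baseline-vs-post
# t-tests) and odor association (unpaired odor-vs-control t-tests), with
# Bonferroni or Benjamini-Hochberg control over the four-window family.

two_sided_p <- function(t, df) 2 * stats::pt(-abs(t), df)

paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  s <- stats::sd(d)
  if (n < 2L || !is.finite(s)) return(c(t = NA_real_, p = NA_real_))
  if (s == 0) return(c(t = 0, p = 1))
  t <- mean(d) / (s / sqrt(n))
  c(t = t, p = two_sided_p(t, n - 1))
}

unpaired_t <- function(x, y, welch = FALSE) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) {
    stop("both conditions need at least 2 trials", call. = FALSE)
  }
  s1 <- stats::sd(x)
  s2 <- stats::sd(y)
  if (s1 == 0 && s2 == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1))
  }
  tt <- summary_stat_ttest(mean(x), s1, n1, mean(y), s2, n2, welch = welch)
  c(t = tt$t, p = tt$p)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard false-discovery-rate step-up rule: sort the m p-values, find the
#' largest k with `p_(k) <= k/m * q`, and reject hypotheses 1..k. The
#' rejection set always contains the Bonferroni rejections at level q.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q family FDR level.
#' @return logical rejection flags in the original order.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  stopifnot(all(p >= 0 & p <= 1))
  ord <- order(p)
  below <- which(p[ord] <= seq_len(m) / m * q)
  flags <- logical(m)
  if (length(below) > 0L) flags[ord[seq_len(max(below))]] <- TRUE
  flags
}

window_family_flags <- function(p, alpha_family, correction) {
  if (correction == "bonferroni") {
    p < alpha_family / length(p)
  } else {
    benjamini_hochberg(p, q = alpha_family)
  }
}

unit_test_result <- function(unit_id, region, t, p, contrast_mean,
                             alpha_family, correction, windows) {
  rej <- window_family_flags(p, alpha_family, correction)
  flagged <- any(rej)
  best <- which.min(p)
  data.frame(unit_id = unit_id, region = region,
             t1 = t[1], t2 = t[2], t3 = t[3], t4 = t[4],
             p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
             flagged = flagged,
             best_window = if (flagged) windows[best] else NA_character_,
             direction = if (flagged) {
               if (contrast_mean[best] >= 0) "increase" else "decrease"
             } else NA_character_,
             correction = correction,
             stringsAsFactors = FALSE)
}

#' Test one unit for stimulus responsiveness
#'
#' Four two-sided paired t-tests compare the unit's z-scored rate in each
#' post-stimulus window against its z-scored baseline rate, paired across
#' first-presentation trials. The unit is flagged when at least one test
#' survives the four-window family correction (Bonferroni: p < alpha/4 =
#' 0.0125 at the default family level). A window with zero variance of the
#' paired differences gets p = 1 with a warning. The response direction
#' (increase/decrease) is the sign of the mean post-minus-baseline contrast
#' in the most significant window.
#'
#' @param z trials x windows matrix of z-scores (column 1 = baseline, then
#'   the four post windows), or trials x 5 rate matrix (the paired t is
#'   invariant to the unit-wise linear z-transform).
#' @param alpha_family family-wise alpha over the four windows.
#' @param correction `"bonferroni"` or `"BH"`.
#' @param unit_id,region identifiers carried into the result.
#' @return one-row data frame (`UnitTestResult`): per-window t and p,
#'   `flagged`, `best_window`, `direction`.
#' @export
test_stimulus_responsiveness <- function(z, alpha_family = 0.05,
                                         correction = c("bonferroni", "BH"),
                                         unit_id = "unit", region = NA) {
  correction <- match.arg(correction)
  z <- as.matrix(z)
  stopifnot(ncol(z) == 5L, nrow(z) >= 2L)
  res <- vapply(2:5, function(w) paired_t(z[, w], z[, 1L]), numeric(2))
  if (any(res["p", ] == 1 & res["t", ] == 0)) {
    zero_var <- res["p", ] == 1 & res["t", ] == 0
    if (any(apply(z[, which(zero_var) + 1L, drop = FALSE] - z[, 1L], 2L,
                  function(d) stats::sd(d) == 0 && mean(d) != 0))) {
      warning("zero variance of paired differences; p set to 1")
    }
  }
  cm <- colMeans(z[, 2:5, drop = FALSE] - z[, 1L])
  unit_test_result(unit_id, region, res["t", ], res["p", ], cm,
                   alpha_family, correction, colnames(z)[2:5])
}

#' Test one unit for odor association
#'
#' Four two-sided unpaired t-tests compare z-scored rates on odor-word
#' trials against control-word trials within each post-stimulus window. The
#' unit is flagged when at least one test survives the four-window family
#' correction; direction is the sign of (mean odor - mean control) in the
#' most significant window.
#'
#' @param z trials x windows matrix (column 1 = baseline, then four post
#'   windows); only the post windows are tested.
#' @param is_odor logical per-trial condition labels.
#' @param alpha_family family-wise alpha over the four windows.
#' @param correction `"bonferroni"` or `"BH"`.
#' @param welch use Welch instead of pooled-variance t-tests.
#' @param unit_id,region identifiers carried into the result.
#' @return one-row `UnitTestResult` data frame.
#' @export
test_odor_association <- function(z, is_odor, alpha_family = 0.05,
                                  correction = c("bonferroni", "BH"),
                                  welch = FALSE, unit_id = "unit",
                                  region = NA) {
  correction <- match.arg(correction)
  z <- as.matrix(z)
  is_odor <- as.logical(is_odor)
  stopifnot(ncol(z) == 5L, nrow(z) == length(is_odor))
  if (sum(is_odor) < 2L || sum(!is_odor) < 2L) {
    stop("both odor and control conditions need at least 2 trials",
         call. = FALSE)
  }
  res <- vapply(2:5, function(w) {
    unpaired_t(z[is_odor, w], z[!is_odor, w], welch = welch)
  }, numeric(2))
  cm <- colMeans(z[is_odor, 2:5, drop = FALSE]) -
    colMeans(z[!is_odor, 2:5, drop = FALSE])
  unit_test_result(unit_id, region, res["t", ], res["p", ], cm,
                   alpha_family, correction, colnames(z)[2:5])
}

#' Screen every analyzable unit of a session
#'
#' Applies [test_stimulus_responsiveness()] or [test_odor_association()] to
#' each unit that passes the minimum-rate filter and has a z-scorable
#' baseline.
#'
#' @param rt a [rate_tensor()] built on the standard five-window set.
#' @param type `"stimulus"` (baseline vs post, paired) or `"odor"`
#'   (odor vs control words, unpaired).
#' @param alpha_family family-wise alpha over the four windows.
#' @param correction `"bonferroni"` or `"BH"`.
#' @param use_zscores test z-scored rates (default) or raw rates; the
#'   paired contrast is invariant to this choice, and raw-rate screening is
#'   provided as the robustness companion.
#' @param welch Welch correction for the unpaired odor tests.
#' @return data frame of `UnitTestResult` rows, one per analyzable unit.
#' @export
screen_units <- function(rt, type = c("stimulus", "odor"),
                         alpha_family = 0.05,
                         correction = c("bonferroni", "BH"),
                         use_zscores = TRUE, welch = FALSE) {
  type <- match.arg(type)
  correction <- match.arg(correction)
  stopifnot(inherits(rt, "rate_tensor"))
  keep <- which(rt$units$retained & rt$units$zscore_ok)
  arr <- if (use_zscores) rt$z else rt$rate
  is_odor <- rt$trials$is_odor
  rows <- lapply(keep, function(u) {
    m <- arr[u, , ]
    if (type == "stimulus") {
      test_stimulus_responsiveness(m, alpha_family, correction,
                                   unit_id = rt$units$unit_id[u],
                                   region = rt$units$region[u])
    } else {
      test_odor_association(m, is_odor, alpha_family, correction,
                            welch = welch,
                            unit_id = rt$units$unit_id[u],
                            region = rt$units$region[u])
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "type") <- type
  out
}
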