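# Region-level prevalence: are there more flagged units than the 5% of
# units expected to be flagged by chance?

#' Exact one-sided binomial prevalence test
#'
#' Upper-tail exact test of whether `k` flagged units out of `n` exceed the
#' count expected if each unit were flagged independently with probability
#' `p0` (the per-unit alpha level, 0.05 by default):
#' `p = P(X >= k)` for `X ~ Binomial(n, p0)`, computed by exact summation of
#' the binomial mass.
#'
#' @param k number of flagged units.
#' @param n total units in the region.
#' @param p0 chance flag probability.
#' @return list with `k`, `n`, `p0`, `proportion` and upper-tail `p_value`.
#' @export
binomial_prevalence_test <- function(k, n, p0 = 0.05) {
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, n >= 0, k == round(k),
            n == round(n), p0 > 0, p0 < 1)
  if (k > n) stop("k cannot exceed n", call. = FALSE)
  p_value <- if (n == 0L) 1.0 else sum(stats::dbinom(k:n, n, p0))
  list(k = as.integer(k), n = as.integer(n), p0 = p0,
       proportion = if (n > 0) k / n else NA_real_,
       p_value = min(p_value, 1.0))
}

#' Summarize unit screening per region
#'
#' Builds the region-by-region prevalence table: total units, flagged units
#' (split into increases and decreases), the percentage of flagged units
#' (rounded to integer percent for display), and the exact upper-tail
#' binomial p-value against a chance flag probability `p0`. A grand-total
#' row pools all regions.
#'
#' @param unit_results data frame from [screen_units()].
#' @param totals optional named vector of unit counts per region; defaults
#'   to the units present in `unit_results`.
#' @param p0 chance flag probability for the binomial test.
#' @param regions region display order.
#' @return `screening_summary` data frame with columns `region, n_total,
#'   n_flagged, percent, n_increase, n_decrease, binomial_p`.
#' @export
summarize_screening <- function(unit_results, totals = NULL, p0 = 0.05,
                                regions = mtl_regions()) {
  stopifnot(is.data.frame(unit_results))
  if (is.null(totals)) {
    totals <- table(factor(unit_results$region, levels = regions))
    totals <- stats::setNames(as.integer(totals), regions)
  }
  rows <- lapply(regions, function(r) {
    in_r <- unit_results$region == r
    n <- as.integer(totals[[r]])
    k <- sum(unit_results$flagged[in_r])
    data.frame(region = r, n_total = n, n_flagged = k,
               percent = if (n > 0) round(100 * k / n) else NA_real_,
               n_increase = sum(in_r & unit_results$flagged &
                                  unit_results$direction == "increase",
                                na.rm = TRUE),
               n_decrease = sum(in_r & unit_results$flagged &
                                  unit_results$direction == "decrease",
                                na.rm = TRUE),
               binomial_p = binomial_prevalence_test(k, n, p0)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(region = "all", n_total = sum(out$n_total),
                      n_flagged = sum(out$n_flagged),
                      percent = round(100 * sum(out$n_flagged) /
                                        max(sum(out$n_total), 1L)),
                      n_increase = sum(out$n_increase),
                      n_decrease = sum(out$n_decrease),
                      binomial_p = binomial_prevalence_test(
                        sum(out$n_flagged), sum(out$n_total), p0)$p_value,
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  class(out) <- c("screening_summary", "data.frame")
  attr(out, "type") <- attr(unit_results, "type")
  out
}

#' Format a p-value the way prevalence tables print them
#'
#' Values below 0.01 are shown to one significant figure at four decimals;
#' larger values to two or three significant decimals.
#'
#' @param p numeric p-values.
#' @return character vector.
#' @export
format_prevalence_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    if (x < 0.01) sprintf("%.4f", signif(x, 1)) else
      formatC(signif(x, 2), format = "fg")
  }, character(1))
}

#' @export
print.screening_summary <- function(x, ...) {
  type <- attr(x, "type")
  cat(sprintf("Prevalence of %s units per region\n",
              if (identical(type, "odor")) "odor-associated"
              else "stimulus-responsive"))
  disp <- data.frame(region = x$region,
                     total = x$n_total,
                     flagged = sprintf("%d (%s%%)", x$n_flagged, x$percent),
                     increase = x$n_increase, decrease = x$n_decrease,
                     binomial_p = format_prevalence_p(x$binomial_p))
  print(disp, row.names = FALSE)
  invisible(x)
}
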