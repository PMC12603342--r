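# Ensemble statistics: split-plot (mixed) ANOVA of z-scored window rates
# with within-unit factors CATEGORY x TIME and between-unit factor REGION,
# plus LSD post-hoc comparisons.

onorm_contrasts <- function(L) {
  C <- stats::contr.helmert(L)
  sweep(C, 2L, sqrt(colSums(C^2)), `/`)
}

#' Per-unit condition-by-window cell means
#'
#' Averages each unit's z-scored (or raw) rates over trials within each
#' CATEGORY level x post-stimulus TIME window cell. The category scheme
#' splits trials by the odor, living, or food flag of the presented word.
#' Units lacking trials in some cell are excluded with a message; if a whole
#' category level has no trials the table cannot be built.
#'
#' @param rt a [rate_tensor()]; its post windows define TIME (4 cells at
#'   500 ms resolution, 20 at 100 ms).
#' @param scheme `"odor"`, `"living"` or `"food"`.
#' @param use_zscores use z-scored rates (default) or raw rates.
#' @param trial_subset optional logical vector over the tensor's trials
#'   restricting which trials enter (e.g. odor-word trials only).
#' @param region_subset optional character vector of regions to keep.
#' @return a `cell_means` list: `Y` (units x 2T matrix, level-major), unit
#'   ids, `region` factor, `scheme`, level labels and `T`.
#' @export
build_cell_means <- function(rt, scheme = c("odor", "living", "food"),
                             use_zscores = TRUE, trial_subset = NULL,
                             region_subset = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(rt, "rate_tensor"))
  flag <- rt$trials[[paste0("is_", scheme)]]
  if (is.null(flag)) stop("trials lack an is_", scheme, " column")
  keep_trials <- if (is.null(trial_subset)) rep(TRUE, nrow(rt$trials)) else
    trial_subset
  keep_units <- rt$units$retained & rt$units$zscore_ok
  if (!is.null(region_subset)) {
    keep_units <- keep_units & rt$units$region %in% region_subset
  }
  arr <- if (use_zscores) rt$z else rt$rate
  post <- which(!rt$windows$is_baseline)
  T_ <- length(post)
  lev_trials <- list(which(keep_trials & flag), which(keep_trials & !flag))
  if (any(vapply(lev_trials, length, integer(1)) == 0L)) {
    stop("a ", scheme, " category level has no trials; cannot build cells",
         call. = FALSE)
  }
  uidx <- which(keep_units)
  Y <- matrix(NA_real_, length(uidx), 2L * T_)
  for (l in 1:2) {
    Y[, (l - 1L) * T_ + seq_len(T_)] <-
      apply(arr[uidx, lev_trials[[l]], post, drop = FALSE], c(1L, 3L), mean)
  }
  complete <- stats::complete.cases(Y)
  if (any(!complete)) {
    message(sum(!complete), " unit(s) excluded from the ANOVA: empty cell")
  }
  structure(list(Y = Y[complete, , drop = FALSE],
                 unit_id = rt$units$unit_id[uidx][complete],
                 region = factor(rt$units$region[uidx][complete]),
                 scheme = scheme,
                 levels = c(scheme, paste0("non-", scheme)),
                 T_ = T_),
            class = "cell_means")
}

stratum_ss <- function(S, group) {
  S <- as.matrix(S)
  k <- ncol(S)
  N <- nrow(S)
  r <- nlevels(group)
  n_g <- as.vector(table(group))
  m_g <- apply(S, 2L, function(col) tapply(col, group, mean))
  m_g <- matrix(m_g, nrow = r)
  fitted <- m_g[as.integer(group), , drop = FALSE]
  ss_err <- sum((S - fitted)^2)
  wmean <- colSums(S) / N
  umean <- colMeans(m_g)
  ss_effect <- sum(umean^2) * r^2 / sum(1 / n_g)
  ss_inter <- sum(sweep(sweep(m_g, 2L, wmean, `-`)^2, 1L, n_g, `*`))
  list(ss_effect = ss_effect, df_effect = k,
       ss_inter = ss_inter, df_inter = k * (r - 1L),
       ss_err = ss_err, df_err = k * (N - r))
}

anova_row <- function(effect, ss, df1, ss_err, df2, eps = 1) {
  # degenerate stratum (no variation at all): report F = 0, not 0/0
  F <- if (ss == 0) 0 else (ss / df1) / (ss_err / df2)
  data.frame(effect = effect, F = F, df_num = df1 * eps, df_den = df2 * eps,
             p = stats::pf(F, df1 * eps, df2 * eps, lower.tail = FALSE),
             partial_eta_sq = ss / (ss + ss_err),
             stringsAsFactors = FALSE)
}

#' Split-plot mixed ANOVA of condition-by-window cell means
#'
#' Univariate mixed (split-plot) ANOVA with within-unit factors CATEGORY
#' (2 levels) and TIME (T windows) and between-unit factor REGION. Each
#' within-unit effect is carried by an orthonormal contrast of the 2T cell
#' means and tested against its own effect-by-units-within-region error
#' stratum; REGION is tested against units within region. Unequal region
#' sizes are handled by Type III (unweighted-means) sums of squares for the
#' within-effect main terms, matching the conventional general-linear-model
#' treatment of unbalanced split-plot designs. No sphericity correction is
#' applied by default (`gg = TRUE` applies Greenhouse-Geisser-adjusted
#' degrees of freedom to the TIME-bearing effects).
#'
#' With a single region (or when `cells` was built for one region only) the
#' between factor is dropped and the within effects are tested against
#' their effect-by-units strata, e.g. a FOOD main effect on N units has
#' df = (1, N - 1).
#'
#' @param cells a [build_cell_means()] table.
#' @param gg apply Greenhouse-Geisser epsilon correction to effects
#'   involving TIME.
#' @return data frame of `AnovaResult` rows: `effect, F, df_num, df_den, p,
#'   partial_eta_sq`.
#' @export
mixed_anova <- function(cells, gg = FALSE) {
  stopifnot(inherits(cells, "cell_means"))
  Y <- cells$Y
  group <- droplevels(cells$region)
  N <- nrow(Y)
  r <- nlevels(group)
  if (N < 2L) stop("need at least 2 units", call. = FALSE)
  if (r > 1L && any(table(group) < 2L)) {
    empty <- names(which(table(group) < 2L))
    stop("region(s) with fewer than 2 units: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  T_ <- cells$T_
  cat_name <- toupper(cells$scheme)
  u2 <- rep(1 / sqrt(2), 2)
  uT <- rep(1 / sqrt(T_), T_)
  Q2 <- onorm_contrasts(2L)
  QT <- onorm_contrasts(T_)
  contrasts <- list()
  contrasts[[cat_name]] <- kronecker(Q2, matrix(uT, ncol = 1))
  contrasts[["TIME"]] <- kronecker(matrix(u2, ncol = 1), QT)
  contrasts[[paste0(cat_name, ":TIME")]] <- kronecker(Q2, QT)
  out <- list()
  if (r > 1L) {
    s0 <- Y %*% matrix(kronecker(u2, uT), ncol = 1)
    st <- stratum_ss(s0, group)
    out[["REGION"]] <- anova_row("REGION", st$ss_inter, r - 1L,
                                 st$ss_err, N - r)
  }
  for (nm in names(contrasts)) {
    S <- Y %*% contrasts[[nm]]
    st <- stratum_ss(S, group)
    eps <- 1
    if (gg && grepl("TIME", nm)) {
      eps <- gg_epsilon(Y, contrasts[["TIME"]], group)
    }
    out[[nm]] <- anova_row(nm, st$ss_effect, st$df_effect,
                           st$ss_err, st$df_err, eps)
    if (r > 1L) {
      out[[paste0(nm, ":REGION")]] <-
        anova_row(paste0(nm, ":REGION"), st$ss_inter, st$df_inter,
                  st$ss_err, st$df_err, eps)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

gg_epsilon <- function(Y, M, group) {
  # Greenhouse-Geisser epsilon from the pooled within-group covariance of
  # the orthonormalized TIME contrast scores.
  S <- Y %*% M
  resid <- S - apply(S, 2L, function(col)
    stats::ave(col, group, FUN = mean))
  V <- crossprod(resid) / (nrow(S) - nlevels(group))
  k <- ncol(V)
  sum(diag(V))^2 / (k * sum(V^2))
}

#' LSD post-hoc category comparison within each region
#'
#' Fisher's least-significant-difference comparison of the two CATEGORY
#' levels within a region, on unit-level category marginal means (averaged
#' over TIME). The default computes an uncorrected paired t-test per region;
#' `error = "pooled"` uses the classic LSD pooled error, i.e. the SD of the
#' unit-level difference scores pooled across all regions with df = N - r.
#' Cohen's d is the mean difference divided by the SD of the unit-level
#' differences.
#'
#' @param cells a [build_cell_means()] table.
#' @param regions regions to report (default: all present).
#' @param error `"within_region"` (per-region paired t) or `"pooled"`.
#' @return data frame of `PosthocResult` rows: per-region n, mean and SEM of
#'   each category level, mean difference, `t`, `df`, `p`, `cohen_d`.
#' @export
lsd_posthoc <- function(cells, regions = levels(cells$region),
                        error = c("within_region", "pooled")) {
  error <- match.arg(error)
  stopifnot(inherits(cells, "cell_means"))
  T_ <- cells$T_
  m1 <- rowMeans(cells$Y[, seq_len(T_), drop = FALSE])
  m2 <- rowMeans(cells$Y[, T_ + seq_len(T_), drop = FALSE])
  d <- m1 - m2
  grp <- cells$region
  if (error == "pooled") {
    resid <- d - stats::ave(d, grp, FUN = mean)
    df_pool <- length(d) - nlevels(droplevels(grp))
    sd_pool <- sqrt(sum(resid^2) / df_pool)
  }
  rows <- lapply(regions, function(r) {
    in_r <- grp == r
    n <- sum(in_r)
    if (n < 2L) stop("region '", r, "' has fewer than 2 units",
                     call. = FALSE)
    dr <- d[in_r]
    sd_d <- stats::sd(dr)
    if (error == "pooled") {
      se <- sd_pool / sqrt(n)
      df <- df_pool
    } else {
      se <- sd_d / sqrt(n)
      df <- n - 1L
    }
    if (se == 0) {
      t <- 0
      p <- 1
    } else {
      t <- mean(dr) / se
      p <- two_sided_p(t, df)
    }
    data.frame(region = r, n = n,
               mean_1 = mean(m1[in_r]),
               sem_1 = stats::sd(m1[in_r]) / sqrt(n),
               mean_2 = mean(m2[in_r]),
               sem_2 = stats::sd(m2[in_r]) / sqrt(n),
               diff = mean(dr), t = t, df = df, p = p,
               cohen_d = if (sd_d == 0) 0 else mean(dr) / sd_d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "levels") <- cells$levels
  out
}

#' Food-vs-nonfood ANOVA within odor-word trials of one region
#'
#' Control analysis asking whether the odor effect in a region could be a
#' food effect: restricted to odor-word trials of that region's units, a
#' two-within-factor repeated-measures ANOVA with factors FOOD (food vs
#' nonfood odor words) and TIME. The FOOD main effect has df = (1, N - 1)
#' for N units.
#'
#' @param rt a [rate_tensor()].
#' @param region region to analyze (default amygdala).
#' @param use_zscores use z-scored rates.
#' @return data frame of `AnovaResult` rows (FOOD, TIME, FOOD:TIME).
#' @export
food_within_odor_anova <- function(rt, region = "amygdala",
                                   use_zscores = TRUE) {
  cells <- build_cell_means(rt, scheme = "food", use_zscores = use_zscores,
                            trial_subset = rt$trials$is_odor,
                            region_subset = region)
  mixed_anova(cells)
}
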