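test_that("cell means have the 2 x T structure per unit", {
  rt <- small_tensor(seed = 8)
  cells <- build_cell_means(rt, "odor")
  expect_equal(ncol(cells$Y), 8L)
  expect_equal(cells$T_, 4L)
  expect_equal(nrow(cells$Y),
               sum(rt$units$retained & rt$units$zscore_ok))
  # direct check of one cell: unit 1, odor trials, first post window
  u <- which(rt$units$unit_id == cells$unit_id[1])
  expect_equal(cells$Y[1, 1],
               mean(rt$z[u, rt$trials$is_odor, 2]))

  # a scheme with all trials in one level cannot be built
  rt_bad <- rt
  rt_bad$trials$is_food <- FALSE
  expect_error(build_cell_means(rt_bad, "food"), "no trials")
})

test_that("the split-plot decomposition matches the aov oracle", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    region <- rep(c("amygdala", "hippocampus", "piriform"), each = 4)
    Y <- matrix(rnorm(length(region) * 8), length(region), 8)
    # inject additive effects: category shift in one region, a time trend
    Y[region == "amygdala", 1:4] <- Y[region == "amygdala", 1:4] + 0.8
    Y <- Y + rep(seq(0, 0.6, length.out = 4), 2)[col(Y)] * 0
    expect_anova_matches_oracle(Y, region)
  }
})

test_that("the category-by-region interaction has df (4, 190) at full scale", {
  counts <- c(amygdala = 57L, hippocampus = 54L, entorhinal = 22L,
              parahippocampal = 29L, piriform = 33L)
  region <- rep(names(counts), counts)
  set.seed(3)
  Y <- matrix(rnorm(195 * 8), 195, 8)
  res <- mixed_anova(cells_from_matrix(Y, region))
  cr <- res[res$effect == "ODOR:REGION", ]
  expect_equal(cr$df_num, 4)
  expect_equal(cr$df_den, 190)
  expect_equal(res$df_den[res$effect == "REGION"], 190)
  expect_equal(res$df_den[res$effect == "TIME:REGION"], 570)
})

test_that("degenerate and invariance properties of the mixed ANOVA hold", {
  region <- rep(c("amygdala", "piriform"), each = 5)
  # all cell means equal -> every F = 0
  res0 <- mixed_anova(cells_from_matrix(matrix(1.0, 10, 8), region))
  expect_true(all(res0$F == 0))

  set.seed(9)
  Y <- matrix(rnorm(10 * 8), 10, 8)
  a <- mixed_anova(cells_from_matrix(Y, region))
  b <- mixed_anova(cells_from_matrix(Y + 3.7, region))
  expect_equal(a$F, b$F, tolerance = 1e-10)

  # partial eta squared identity for every effect
  expect_equal(a$partial_eta_sq,
               a$F * a$df_num / (a$F * a$df_num + a$df_den),
               tolerance = 1e-10)

  # an empty / singleton region is a singular design
  expect_error(mixed_anova(cells_from_matrix(Y, c(rep("amygdala", 9),
                                                  "piriform"))),
               "piriform")
})

test_that("category F statistics are identical at 500 ms and 100 ms resolution", {
  s <- small_session(seed = 13)
  rt500 <- suppressMessages(rate_tensor(bin_spike_counts(
    s, s$trials, window_set(500))))
  rt100 <- suppressMessages(rate_tensor(bin_spike_counts(
    s, s$trials, window_set(100))))
  a500 <- mixed_anova(build_cell_means(rt500, "odor"))
  a100 <- mixed_anova(build_cell_means(rt100, "odor"))
  expect_equal(a100$df_num[a100$effect == "ODOR:REGION"], 4)
  for (eff in c("ODOR", "ODOR:REGION", "REGION")) {
    expect_equal(a100$F[a100$effect == eff], a500$F[a500$effect == eff],
                 tolerance = 1e-8)
  }
  # TIME strata differ by construction
  expect_equal(a100$df_num[a100$effect == "TIME"], 19)
})

test_that("LSD post-hocs detect an injected category difference", {
  # unit-level category differences ~ N(0.019, 0.05) over 57 units
  set.seed(17)
  d <- rnorm(57, mean = 0.019, sd = 0.05)
  base <- rnorm(57, 0, 0.1)
  Y <- cbind(matrix(base + d / 2, 57, 4), matrix(base - d / 2, 57, 4))
  cells <- cells_from_matrix(Y, rep("amygdala", 57))
  ph <- lsd_posthoc(cells)
  expect_lt(ph$p, 0.05)
  expect_equal(ph$cohen_d, 0.38, tolerance = 0.35)
  expect_equal(ph$diff, mean(d), tolerance = 1e-12)

  # sign flip of category labels negates d, keeps p
  Yf <- Y[, c(5:8, 1:4)]
  phf <- lsd_posthoc(cells_from_matrix(Yf, rep("amygdala", 57)))
  expect_equal(phf$p, ph$p, tolerance = 1e-12)
  expect_equal(phf$cohen_d, -ph$cohen_d, tolerance = 1e-12)

  # identical category marginals -> guard p = 1, d = 0
  Y0 <- cbind(matrix(base, 57, 4), matrix(base, 57, 4))
  ph0 <- lsd_posthoc(cells_from_matrix(Y0, rep("amygdala", 57)))
  expect_equal(ph0$p, 1)
  expect_equal(ph0$cohen_d, 0)

  # pooled-error variant has pooled degrees of freedom
  region2 <- rep(c("amygdala", "piriform"), c(30, 27))
  php <- lsd_posthoc(cells_from_matrix(Y, region2), error = "pooled")
  expect_true(all(php$df == 57 - 2))
})

test_that("the food-within-odor control ANOVA has the repeated-measures df", {
  s <- small_session(seed = 19, units_per_region = c(amygdala = 12L))
  rt <- suppressMessages(rate_tensor(bin_spike_counts(s, s$trials)))
  res <- food_within_odor_anova(rt)
  n <- sum(rt$units$retained & rt$units$zscore_ok)
  food <- res[res$effect == "FOOD", ]
  expect_equal(food$df_num, 1)
  expect_equal(food$df_den, n - 1)
  expect_true(all(c("FOOD", "TIME", "FOOD:TIME") %in% res$effect))
  expect_false("REGION" %in% res$effect)

  # identical food/nonfood cell means per unit -> F = 0 for FOOD
  T_ <- 4L
  base <- matrix(rnorm(12 * T_), 12, T_)
  res0 <- mixed_anova(cells_from_matrix(cbind(base, base),
                                        rep("amygdala", 12),
                                        scheme = "food"))
  expect_equal(res0$F[res0$effect == "FOOD"], 0)
})

test_that("null repeated-measures p-values are uniformly distributed", {
  set.seed(23)
  ps <- replicate(300, {
    Y <- matrix(rnorm(20 * 8), 20, 8)
    res <- mixed_anova(cells_from_matrix(Y, rep("amygdala", 20),
                                         scheme = "food"))
    res$p[res$effect == "FOOD"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
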