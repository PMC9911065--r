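test_that("the univariate mixed model recovers a generating background effect", {
  set.seed(101)
  tab <- simulate_ma_experiment()
  fit <- fit_univariate_lmm(tab, "ln_SF", include_interaction = FALSE)
  cf <- fit$coefficients
  bg <- cf[grep("^genotype", cf$term), ]
  # generated with delta_PB306 = 0.44 on SF
  expect_lt(abs(bg$estimate - 0.44), 3 * bg$se)
  expect_true(all(fit$varcomp >= 0))

  # REML variant runs and reports the method
  fitr <- fit_univariate_lmm(tab, "ln_SF", include_interaction = FALSE,
                             method = "REML")
  expect_equal(fitr$method, "REML")

  # missing design cell is named
  sub <- tab[!(tab$genotype == "PB306" & tab$ma_status == "MA"), ]
  expect_error(fit_univariate_lmm(sub, "ln_SF"), "design cell absent")
})

test_that("likelihood-ratio tests obey nesting and reject REML fits", {
  set.seed(102)
  tab <- simulate_ma_experiment()
  full <- fit_univariate_lmm(tab, "ln_SB")
  reduced <- fit_univariate_lmm(tab, "ln_SB", include_interaction = FALSE)
  out <- lrt(full, reduced)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
  expect_true(out$p_value >= 0 && out$p_value <= 1)

  # identical models: statistic 0, p = 1
  same <- lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  remlfit <- fit_univariate_lmm(tab, "ln_SB", method = "REML")
  expect_error(lrt(remlfit, reduced), "requires ML")
})

test_that("REML variance components match closed-form ANOVA on a balanced design", {
  # balanced one-way random-effects layout; block variance generated as zero
  set.seed(103)
  n_lines <- 30; n_rep <- 4
  des <- simulation_design(n_lines = n_lines, n_blocks = 2,
                           plates_per_line = 2,
                           true_block_cov = matrix(0, 6, 6))
  # build the balanced table directly: line effects + residual only
  le <- rnorm(n_lines, 0, sqrt(0.3))
  tab <- data.frame(line_id = rep(paste0("L", seq_len(n_lines)), each = n_rep),
                    block_id = rep(c("B1", "B2"), length.out = n_lines * n_rep))
  tab$y <- le[rep(seq_len(n_lines), each = n_rep)] + rnorm(nrow(tab), 0, 0.5)

  fit <- lme4::lmer(y ~ 1 + (1 | line_id), data = tab, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_line <- vc$vcov[vc$grp == "line_id"]
  v_res <- vc$vcov[vc$grp == "Residual"]

  # closed-form ANOVA estimators for the balanced one-way layout
  a <- anova(lm(y ~ line_id, data = tab))
  ms_line <- a$`Mean Sq`[1]; ms_err <- a$`Mean Sq`[2]
  expect_equal(v_res, ms_err, tolerance = 1e-6)
  expect_equal(v_line, (ms_line - ms_err) / n_rep, tolerance = 1e-6)
})

test_that("Levene's test detects unequal spread and matches the reference implementation", {
  # two groups with identical spread, shifted by a constant: statistic 0
  x <- c(1, 2, 3, 4, 11, 12, 13, 14)
  g <- rep(c("a", "b"), each = 4)
  out <- levene_test(x, g)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  expect_error(levene_test(x, rep("a", 8)), "at least 2 groups")

  # agreement with car's mean-centered Levene test
  set.seed(104)
  y <- c(rnorm(30, 0, 1), rnorm(30, 0, 2.5), rnorm(30, 1, 1))
  gy <- rep(c("a", "b", "c"), each = 30)
  mine <- levene_test(y, gy)
  ref <- car::leveneTest(y ~ factor(gy), center = mean)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # power at a 4x variance ratio with n = 50 per group
  set.seed(105)
  rej <- vapply(seq_len(200), function(i) {
    z <- c(rnorm(50, 0, 1), rnorm(50, 0, 2))
    levene_test(z, rep(c("a", "b"), each = 50))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("the bias analysis drops a null interaction and recovers generated effects", {
  set.seed(106)
  tab <- simulate_ma_experiment()   # generated with eta = 0
  rep_tab <- mutational_bias_analysis(tab)
  expect_equal(nrow(rep_tab), 6)
  expect_equal(rep_tab$trait, paste0("ln_", c("SF","SB","FS","FB","BS","BF")))
  # eta = 0 in the generator: the interaction should be dropped for most traits
  expect_gte(sum(rep_tab$interaction_dropped), 5)
  # strong generated background effects on SF/SB/FS/BF are detected
  strong <- rep_tab$trait %in% c("ln_SF", "ln_SB", "ln_FS", "ln_BF")
  expect_true(all(rep_tab$background_p[strong] < 0.01))
  # the FS mutational bias (0.188) is covered by a 3 SE band
  fs <- rep_tab[rep_tab$trait == "ln_FS", ]
  expect_lt(abs(fs$bias_effect - 0.188), 3 * fs$bias_se)
  expect_true(all(rep_tab$levene_p >= 0 & rep_tab$levene_p <= 1))
})

test_that("heteroskedasticity between groups is picked up by the Levene step", {
  set.seed(107)
  designs <- ma_experiment_designs(residual_scale = list(PB306_MA = 4))
  tab <- simulate_ma_experiment(designs)
  rep_tab <- mutational_bias_analysis(tab)
  # a 4x residual variance in one group should trip Levene for most traits
  expect_gte(sum(rep_tab$levene_p < 0.05), 4)
})

test_that("phenotypic standardization meets its exact post-conditions", {
  set.seed(108)
  tab <- simulate_phenotypes(quick_design())
  traits <- paste0("ln_", c("SF","SB","FS","FB","BS","BF"))
  std <- standardize_traits(tab)
  Z <- as.matrix(std[, traits])
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(mean(apply(Z, 2, sd)), 1, tolerance = 1e-12)
  # each trait's sd stays proportional to its original value
  expect_equal(apply(Z, 2, sd) * attr(std, "sigma_bar"),
               apply(as.matrix(tab[, traits]), 2, sd), tolerance = 1e-10)

  # idempotence up to re-centering: standardizing again changes nothing
  std2 <- standardize_traits(std)
  expect_equal(as.matrix(std2[, traits]), Z, tolerance = 1e-10)
  expect_equal(attr(std2, "sigma_bar"), 1, tolerance = 1e-12)

  # uniform per-trait sds of 2 reduce to division by 2
  tab2 <- tab
  for (k in seq_along(traits))
    tab2[[traits[k]]] <- scale(tab[[traits[k]]])[, 1] * 2
  std3 <- standardize_traits(tab2)
  expect_equal(attr(std3, "sigma_bar"), 2, tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(std3[, traits]), 2, sd)), rep(1, 6),
               tolerance = 1e-12)

  const <- tab; const[, traits] <- 1
  expect_error(standardize_traits(const), "mean standard deviation is zero")
})
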