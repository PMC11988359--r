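test_that("unpaired t test matches the hand-computed formula", {
  a <- c(1.0, 2.0, 3.0); b <- c(2.5, 3.5, 5.5)
  ## Welch by hand
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  r <- unpaired_t(a, b, "welch")
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-12)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  ## Student by hand
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_s <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  rs <- unpaired_t(a, b, "student")
  expect_equal(rs$t, t_s, tolerance = 1e-12)
  expect_equal(rs$df, 4)
  ## identical groups: t = 0, p = 1
  r0 <- unpaired_t(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
})

test_that("the v_in group separation is detected at its theoretical power", {
  ## 27 vs 18 lesions at the published group means/sds. The empirical
  ## detection rate at p < 0.001 must match the noncentral-t power
  ## computation (the independent oracle) for these exact group sizes.
  v1 <- 0.10^2 / 27; v2 <- 0.10^2 / 18
  ncp <- (0.38 - 0.24) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 26 + v2^2 / 17)
  tcrit <- qt(1 - 0.001 / 2, df)
  power <- 1 - pt(tcrit, df, ncp) + pt(-tcrit, df, ncp)
  set.seed(2024)
  hits <- replicate(1000, {
    mal <- rnorm(27, 0.38, 0.10)
    ben <- rnorm(18, 0.24, 0.10)
    unpaired_t(mal, ben)$p < 0.001
  })
  expect_lt(abs(mean(hits) - power), 0.04)
  ## and the separation is detected at p < 0.05 essentially always
  set.seed(2025)
  hits05 <- replicate(500, {
    unpaired_t(rnorm(27, 0.38, 0.10), rnorm(18, 0.24, 0.10))$p < 0.05
  })
  expect_gte(mean(hits05), 0.95)
})

test_that("t-test p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(2000, unpaired_t(rnorm(27), rnorm(18))$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("empirical AUC equals exhaustive pair counting", {
  set.seed(13)
  for (i in 1:20) {
    labels <- rep(c("benign", "malignant"), c(9, 11))
    scores <- rnorm(20) + (labels == "malignant") * runif(1, 0, 2)
    scores[sample(20, 2)] <- scores[1]   # inject ties
    r <- roc_analysis(scores, labels, positive = "malignant")
    oracle <- auc_pair_count(scores, labels, "malignant")
    expect_equal(r$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
  }
})

test_that("ROC handles separation, null, and monotone transforms", {
  labels <- rep(c("benign", "malignant"), each = 10)
  perfect <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  r <- roc_analysis(perfect, labels, positive = "malignant")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  ## shuffled labels: AUC near 0.5
  set.seed(8)
  big <- rnorm(2000)
  lab2 <- sample(rep(c("a", "b"), 1000))
  expect_equal(roc_analysis(big, lab2)$auc, 0.5, tolerance = 0.05)
  ## strictly monotone transform leaves the AUC unchanged
  sc <- rnorm(40); lb <- rep(c("a", "b"), 20)
  expect_equal(roc_analysis(exp(2 * sc) + 1, lb)$auc,
               roc_analysis(sc, lb)$auc)
})

test_that("DeLong comparison behaves at the null, under power, and vs bootstrap", {
  ## identical scores: p = 1
  sc <- rnorm(30); lb <- rep(c("a", "b"), 15)
  expect_equal(delong_compare(sc, sc, lb), 1)
  ## informative vs pure noise score, n = 200: detected in >= 90% of reps
  set.seed(55)
  hits <- replicate(60, {
    lab <- rep(c("neg", "pos"), each = 100)
    good <- rnorm(200) + (lab == "pos") * 1.2
    noise <- rnorm(200)
    delong_compare(good, noise, lab) < 0.05
  })
  expect_gte(mean(hits), 0.9)
  ## DeLong variance of the AUC difference tracks the bootstrap variance
  set.seed(66)
  lab <- rep(c("neg", "pos"), each = 60)
  s1 <- rnorm(120) + (lab == "pos") * 1.0
  s2 <- 0.6 * s1 + rnorm(120)
  d_obs <- roc_analysis(s1, lab, "pos")$auc - roc_analysis(s2, lab, "pos")$auc
  z <- qnorm(1 - delong_compare(s1, s2, lab) / 2)
  var_delong <- (d_obs / z)^2
  boots <- replicate(400, {
    i <- c(sample(which(lab == "neg"), replace = TRUE),
           sample(which(lab == "pos"), replace = TRUE))
    auc_pair_count(s1[i], lab[i], "pos") - auc_pair_count(s2[i], lab[i], "pos")
  })
  expect_lt(abs(var_delong - var(boots)), 0.15 * var(boots))
})

test_that("DeLong CI coverage is near nominal over binormal cohorts of n = 45", {
  set.seed(77)
  true_auc <- pnorm(1 / sqrt(2))   # binormal AUC for unit mean shift
  cover <- replicate(1000, {
    sc <- c(rnorm(18), rnorm(27, 1))
    lb <- rep(c("benign", "malignant"), c(18, 27))
    r <- roc_analysis(sc, lb, positive = "malignant")
    r$ci_low <= true_auc && true_auc <= r$ci_high
  })
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("combined logistic models behave like the single-score ROC limits", {
  set.seed(88)
  n <- 45
  recs <- data.frame(
    group = rep(c("benign", "malignant"), c(18, 27)))
  recs$cellularity <- rnorm(n, ifelse(recs$group == "malignant", 2.48, 1.13),
                            0.6)
  recs$d <- rnorm(n, ifelse(recs$group == "malignant", 17.26, 24.13), 3.5)
  recs$noise <- rnorm(n)
  ## single predictor: AUC identical to the raw-score ROC
  m1 <- combined_model(recs, "cellularity")
  expect_equal(m1$roc$auc,
               roc_analysis(recs$cellularity, recs$group, "malignant")$auc,
               tolerance = 1e-10)
  ## adding a pure-noise predictor never worsens the in-sample fit
  ## (deviance is monotone under nesting; the AUC can wiggle slightly
  ## because maximum likelihood does not maximise AUC)
  dev1 <- -2 * sum(ifelse(recs$group == "malignant",
                          log(m1$probabilities),
                          log(1 - m1$probabilities)))
  m2 <- combined_model(recs, c("cellularity", "noise"))
  dev2 <- -2 * sum(ifelse(recs$group == "malignant",
                          log(m2$probabilities),
                          log(1 - m2$probabilities)))
  expect_lte(dev2, dev1 + 1e-8)
  expect_gte(m2$roc$auc, m1$roc$auc - 0.02)
  ## combining informative predictors is at least as good as the best single
  m3 <- combined_model(recs, c("cellularity", "d"))
  best_single <- max(m1$roc$auc,
                     roc_analysis(recs$d, recs$group, "malignant")$auc)
  expect_gte(m3$roc$auc, best_single - 0.02)
  expect_true(all(m3$probabilities > 0 & m3$probabilities < 1))
  expect_error(combined_model(transform(recs, d = NA), c("d")), "missing")
})

test_that("IHC subgroup comparison has the right shape, null and power", {
  ## shape: one row per (marker, parameter)
  cfg <- default_cohort_config()
  cfg$benign$n_lesions <- 2L
  tr <- summarize_truth(draw_cohort(cfg, seed = 12))
  out <- ihc_subgroup_compare(tr)
  expect_equal(nrow(out), 4 * 4)
  expect_setequal(unique(out$marker), c("er", "pr", "her2", "ki67"))
  ## null: markers independent of parameters -> p roughly uniform
  set.seed(14)
  ps <- unlist(lapply(1:40, function(i) {
    tr_i <- summarize_truth(draw_cohort(cfg, seed = 1000 + i))
    ihc_subgroup_compare(tr_i, markers = "pr", parameters = "d")$p
  }))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  ## power: the PR-negative v_in shift is detected with adequate n
  cfg2 <- default_cohort_config()
  cfg2$malignant$n_lesions <- 200L
  cfg2$benign$n_lesions <- 2L
  eff <- list(marker = "pr", level = "negative", param = "v_in",
              shift = 0.08)
  tr2 <- summarize_truth(draw_cohort(cfg2, seed = 15, ihc_effect = eff))
  out2 <- ihc_subgroup_compare(tr2, markers = "pr", parameters = "v_in")
  expect_lt(out2$p, 0.05)
  expect_lt(out2$mean_positive, out2$mean_negative)
  ## Holm correction is exposed behind a flag
  outh <- ihc_subgroup_compare(tr, p_adjust = "holm")
  expect_true(all(outh$p_adjusted >= outh$p - 1e-15))
})
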