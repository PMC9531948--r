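test_that("km_curve reproduces hand product-limit values", {
  all_cens <- km_curve(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))

  k <- km_curve(c(5, 10, 15), c(1, 1, 0))
  expect_equal(km_at(k, 5), 2 / 3, tolerance = 1e-12)
  expect_equal(km_at(k, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(km_at(k, 14.9), 1 / 3, tolerance = 1e-12)
  expect_equal(km_at(k, 2), 1)

  both <- km_curve(c(4, 7), c(1, 1))
  expect_equal(km_at(both, 8), 0)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("km_curve matches the closed-form oracle on random fixtures", {
  for (k in 1:30) {
    set.seed(300 + k)
    n <- sample(3:25, 1)
    t <- sample(1:12, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6)
    curve <- km_curve(t, e)
    for (at in c(0, 3, 6, 9, 12))
      expect_equal(km_at(curve, at), oracle_km(t, e, at),
                   tolerance = 1e-12)
    expect_true(all(diff(curve$survival) <= 1e-12))
    expect_true(all(curve$survival >= 0 & curve$survival <= 1))
  }
})

test_that("logrank matches the observed-minus-expected tabulation", {
  same <- logrank(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  t1 <- c(2, 4, 6, 8); e1 <- c(1, 1, 0, 1)
  t2 <- c(3, 5, 7, 9); e2 <- c(1, 0, 1, 0)
  got <- logrank(t1, e1, t2, e2)
  expect_equal(got$statistic, oracle_logrank(t1, e1, t2, e2),
               tolerance = 1e-9)
  swapped <- logrank(t2, e2, t1, e1)
  expect_equal(swapped$statistic, got$statistic, tolerance = 1e-12)
  expect_error(logrank(numeric(0), numeric(0), t2, e2), "non-empty")
})

test_that("risk stratification thresholds on training nodes only", {
  rg <- risk_stratify(c(1, 2, 3, 4, 0, 5),
                      c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(rg$threshold, 2.5)
  expect_equal(rg$labels[5:6], c("low", "high"))

  tied <- risk_stratify(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(tied$labels == "low"))

  # a test patient's risk cannot move the threshold
  r <- c(1, 2, 3, 4, 100)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(risk_stratify(r, mask)$threshold,
               risk_stratify(replace(r, 5, -100), mask)$threshold)
})

test_that("horizon AUC equals the pairwise concordance count", {
  perfect <- auc_ci(c(9, 8, 1, 2), c(10, 20, 90, 95), c(1, 1, 0, 0),
                    horizon = 60, n_boot = 50)
  expect_equal(perfect$auc, 1)
  flat <- auc_ci(rep(2, 6), c(10, 20, 30, 70, 80, 90),
                 c(1, 1, 1, 0, 0, 0), horizon = 60, n_boot = 50)
  expect_equal(flat$auc, 0.5)

  set.seed(77)
  r <- rnorm(10); t <- c(seq(10, 50, 10), seq(70, 110, 10)); e <- rep(1, 10)
  got <- auc_ci(r, t, e, horizon = 60, n_boot = 50)
  expect_equal(got$auc, oracle_auc(r, as.integer(t <= 60)),
               tolerance = 1e-12)
  # monotone transforms leave the point estimate unchanged
  got2 <- auc_ci(exp(2 * r), t, e, horizon = 60, n_boot = 50)
  expect_equal(got2$auc, got$auc, tolerance = 1e-12)
  # censored before the horizon are excluded
  e2 <- e; e2[1] <- 0
  expect_equal(auc_ci(r, t, e2, horizon = 60, n_boot = 10)$n_excluded, 1L)
})

test_that("AUC point estimate agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  r <- rnorm(30); lab <- rbinom(30, 1, 0.4)
  ours <- sagesurv:::auc_mw(r, lab)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, r, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("NRI matches direct counting and is antisymmetric", {
  r_old <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  r_new <- c(0.3, 0.1, 0.5, 0.2, 0.4, 0.9, 0.6, 0.8)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  got <- nri(r_old, r_new, lab, n_boot = 50)
  expect_equal(got$nri, oracle_nri(r_old, r_new, lab), tolerance = 1e-12)

  expect_equal(nri(r_old, r_old, lab, n_boot = 10)$nri, 0)
  up <- ifelse(lab == 1, r_old + 1, r_old - 1)
  expect_equal(nri(r_old, up, lab, n_boot = 10)$nri, 2)
  rev <- nri(r_new, r_old, lab, n_boot = 50)
  expect_equal(rev$nri, -got$nri, tolerance = 1e-12)
  expect_error(nri(r_old, r_new, rep(1, 8), n_boot = 10), "both")
})

test_that("IDI matches the hand mean-difference computation", {
  p_old <- c(0.2, 0.4, 0.3, 0.6, 0.5, 0.1, 0.7, 0.3)
  p_new <- c(0.5, 0.6, 0.4, 0.8, 0.3, 0.2, 0.5, 0.1)
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  got <- idi(p_old, p_new, lab, n_boot = 50)
  expect_equal(got$idi, oracle_idi(p_old, p_new, lab), tolerance = 1e-12)

  expect_equal(idi(p_old, p_old, lab, n_boot = 10)$idi, 0)
  expect_equal(idi(rep(0.5, 8), as.numeric(lab == 1), lab,
                   n_boot = 10)$idi, 1)
  expect_equal(idi(p_new, p_old, lab, n_boot = 50)$idi, -got$idi,
               tolerance = 1e-12)
  expect_error(idi(p_old * 10, p_new, lab, n_boot = 10), "probabilities")
})

test_that("decision curves match hand confusion-matrix tabulation", {
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  lab <- c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0)
  d <- dca(p, lab, thresholds = c(0.25, 0.5))
  expect_equal(d$net_benefit[d$threshold == 0.25],
               oracle_net_benefit(p, lab, 0.25), tolerance = 1e-12)
  expect_true(all(d$treat_none == 0))
  # tiny threshold: everyone treated, NB tends to the prevalence
  d0 <- dca(p, lab, thresholds = 0.001)
  expect_equal(d0$net_benefit, mean(lab) - (1 - mean(lab)) * 0.001 / 0.999,
               tolerance = 1e-12)
  # permutation of subjects leaves the curve unchanged
  set.seed(1); perm <- sample(10)
  expect_equal(dca(p[perm], lab[perm], thresholds = c(0.25, 0.5)), d)
  expect_error(dca(p, lab, thresholds = c(0, 0.5)), "strictly inside")
})

test_that("rank-to-probability mapping is monotone and bounded", {
  r <- c(-3, 0.5, 0.5, 10, -7)
  p <- rank_to_probability(r)
  expect_true(all(p > 0 & p < 1))
  expect_equal(order(p), order(r))
  expect_equal(p[2], p[3])
})

test_that("self-comparison yields null improvement metrics", {
  coh <- generate_cohort(cohort_spec(n_patients = 200, seed = 31))
  rec <- assign_splits(coh$records, seed = 31)
  risks <- coh$latent_risk
  rep1 <- evaluate_models(risks, risks, rec$os_time, rec$os_event,
                          rec$split == "train", rec$split == "test",
                          n_boot = 30)
  expect_equal(rep1$nri, 0)
  expect_equal(rep1$idi, 0)
  expect_equal(rep1$dca, rep1$dca_baseline)
  expect_equal(rep1$auc, rep1$auc_baseline)
})

test_that("the stage-ordinal baseline discriminates when stage drives risk", {
  coh <- generate_cohort(cohort_spec(n_patients = 600, seed = 37,
                                     effect_stage = 1.0))
  rec <- assign_splits(coh$records, seed = 37)
  base <- stage_baseline_risk(rec)
  res <- auc_ci(base[rec$split == "test"], rec$os_time[rec$split == "test"],
                rec$os_event[rec$split == "test"], n_boot = 50)
  expect_gt(res$auc, 0.5)
})

test_that("evaluation reports are reproducible under a fixed seed", {
  coh <- generate_cohort(cohort_spec(n_patients = 150, seed = 41))
  rec <- assign_splits(coh$records, seed = 41)
  new <- coh$latent_risk + rnorm(150, sd = 0.3)
  old <- stage_baseline_risk(rec)
  args <- list(new, old, rec$os_time, rec$os_event,
               rec$split == "train", rec$split == "test",
               n_boot = 100, seed = 77)
  r1 <- do.call(evaluate_models, args)
  r2 <- do.call(evaluate_models, args)
  expect_identical(r1, r2)
  expect_true(r1$auc >= r1$auc_ci[1] && r1$auc <= r1$auc_ci[2])
})
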