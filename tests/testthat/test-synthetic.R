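test_that("the same seed and config reproduce byte-identical cohorts", {
  cfg <- cohort_config(n_patients = 50, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_patients = 50, seed = 124)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
  fu_cfg <- followup_config(seed = 5)
  expect_identical(generate_followup(fu_cfg), generate_followup(fu_cfg))
})

test_that("vein-level ERC prevalence lands in the exact binomial interval", {
  cfg <- cohort_config(n_patients = 200, seed = 17)
  veins <- generate_cohort(cfg)
  n <- nrow(veins)
  bounds <- qbinom(c(0.025, 0.975), n, cfg$erc_prevalence)
  expect_gte(sum(veins$erc_true), bounds[1])
  expect_lte(sum(veins$erc_true), bounds[2])
})

test_that("calibrated covariate medians match the configured targets", {
  cfg <- cohort_config(n_patients = 3000, p_untested = 0,
                       missing_prob = c(tti = 0, n_unsuccessful = 0, nadir = 0),
                       seed = 29)
  veins <- generate_cohort(cfg)
  non <- veins[!veins$erc_true, ]
  erc <- veins[veins$erc_true, ]
  expect_equal(median(non$tti_s), 40, tolerance = 0.05)        # relative
  expect_equal(median(non$nadir_temp_c), -47, tolerance = 0.01)
  expect_equal(median(erc$nadir_temp_c), -41, tolerance = 0.05)
  expect_equal(unname(quantile(non$tti_s, 0.25)), 27, tolerance = 0.05)
  expect_equal(unname(quantile(non$tti_s, 0.75)), 60, tolerance = 0.05)
  expect_equal(mean(non$n_unsuccessful >= 1), 0.212, tolerance = 0.1)
  expect_equal(mean(erc$n_unsuccessful >= 1), 0.366, tolerance = 0.2)
})

test_that("a zero-slope outcome model destroys score discrimination", {
  cfg <- cohort_config(n_patients = 500, p_untested = 0,
                       missing_prob = c(tti = 0, n_unsuccessful = 0, nadir = 0),
                       outcome_model = list(slope = 0), seed = 37)
  veins <- generate_cohort(cfg)
  s <- erc_score(veins$tti_s, veins$n_unsuccessful, veins$nadir_temp_c)
  expect_equal(roc_curve(s, veins$erc_true)$auc, 0.5, tolerance = 0.16)
})

test_that("a steeper outcome slope strictly increases the score AUC", {
  aucs <- vapply(c(0, 0.75, 2), function(slope) {
    cfg <- cohort_config(n_patients = 1500, p_untested = 0,
                         missing_prob = c(tti = 0, n_unsuccessful = 0, nadir = 0),
                         outcome_model = list(slope = slope), seed = 43)
    veins <- generate_cohort(cfg)
    s <- erc_score(veins$tti_s, veins$n_unsuccessful, veins$nadir_temp_c)
    roc_curve(s, veins$erc_true)$auc
  }, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("group-conditional laws give the score realistic discrimination", {
  cfg <- cohort_config(n_patients = 2000, p_untested = 0,
                       missing_prob = c(tti = 0, n_unsuccessful = 0, nadir = 0),
                       seed = 47)
  veins <- generate_cohort(cfg)
  s <- erc_score(veins$tti_s, veins$n_unsuccessful, veins$nadir_temp_c)
  auc <- roc_curve(s, veins$erc_true)$auc
  expect_gt(auc, 0.65)
  expect_lt(auc, 0.9)
})

test_that("patient random effect induces within-patient clustering of ERC", {
  cfg <- cohort_config(n_patients = 4000, patient_re_sd = 2.5, seed = 53)
  veins <- generate_cohort(cfg)
  # prevalence calibration still holds under the random effect
  expect_equal(mean(veins$erc_true), cfg$erc_prevalence, tolerance = 0.15)
  by_pat <- dplyr::count(veins[veins$erc_true, ], patient_id)
  frac_multi <- mean(by_pat$n >= 2)
  cfg0 <- cohort_config(n_patients = 4000, patient_re_sd = 0, seed = 53)
  by_pat0 <- dplyr::count(generate_cohort(cfg0)[generate_cohort(cfg0)$erc_true, ],
                          patient_id)
  expect_gt(frac_multi, mean(by_pat0$n >= 2))
})

test_that("extracted trace features match the generator's closed forms", {
  withr::with_seed(59, {
    for (i in 1:60) {
      tti <- runif(1, 20, 90)
      nadir <- runif(1, -55, -35)
      trunc <- runif(1) < 0.3
      tr <- generate_trace(tti_s = tti, nadir_temp_c = nadir,
                           deflation_truncated = trunc, noise_sd = 0)
      truth <- attr(tr, "truth")
      f <- extract_features(tr, tti_s = tti, deflation_truncated = trunc)
      expect_equal(f$nadir_temp_c, truth$nadir_temp_c, tolerance = 0.05)
      expect_equal(f$freeze_auc, truth$freeze_auc, tolerance = 0.005)
      expect_equal(f$freeze_magnitude, truth$freeze_magnitude, tolerance = 0.01)
      expect_equal(f$temp_at_30s, truth$temp_at_30s, tolerance = 1e-2)
      expect_equal(f$warming_time_to_0, truth$warming_time_to_0, tolerance = 0.5)
      expect_equal(f$warming_time_to_20, truth$warming_time_to_20,
                   tolerance = 1)
      expect_equal(f$warming_truncated, truth$warming_truncated)
    }
  })
})

test_that("a requested nadir is recovered within a sampling step", {
  tr <- generate_trace(nadir_temp_c = -47)
  f <- extract_features(tr)
  expect_equal(f$nadir_temp_c, -47, tolerance = 0.01)
  # truncated export: warming time to 20 carries the truncation flag
  trc <- generate_trace(nadir_temp_c = -47, deflation_truncated = TRUE)
  w <- warming_time_to(trc, 20)
  expect_true(attr(w, "truncated"))
})

test_that("metrics on a large cohort recover the generator's operating point", {
  cfg <- cohort_config(n_patients = 6000, p_untested = 0,
                       missing_prob = c(tti = 0, n_unsuccessful = 0, nadir = 0),
                       seed = 67)
  veins <- generate_cohort(cfg)
  s <- erc_score(veins$tti_s, veins$n_unsuccessful, veins$nadir_temp_c)
  cutoff <- -7.2
  m <- metrics_from_confusion(confusion_at_cutoff(s, veins$erc_true, cutoff))
  ref <- generator_operating_point(cfg, cutoff)
  expect_equal(m$sensitivity, ref$sensitivity, tolerance = 0.05)
  expect_equal(m$specificity, ref$specificity, tolerance = 0.02)
})

test_that("followup generator hits its category counts exactly", {
  cfg <- followup_config(n_patients = 80, n_missing_followup = 10,
                         n_aad_only = 10, n_recur_on_aad_excluded = 10,
                         n_recur_on_aad_censored = 10, seed = 71)
  fu <- generate_followup(cfg)
  expect_equal(nrow(fu$followup), 80)
  expect_equal(sum(is.na(fu$followup$last_followup_day)), 10)
  e <- build_survival_entries(fu$followup, fu$aad_intervals, quiet = TRUE)
  tab <- table(survival_exclusions(e)$reason)
  expect_equal(unname(tab[["missing_followup"]]), 10)
  expect_equal(unname(tab[["no_aad_free_followup"]]), 10)
  expect_equal(unname(tab[["recurrence_on_aad_without_aad_free_followup"]]), 10)
  expect_equal(nrow(e), 80 - 30)
})

test_that("a zero-event configuration yields a flat KM curve", {
  cfg <- followup_config(n_patients = 40, p_erc_patient = 0,
                         n_missing_followup = 0, n_aad_only = 0,
                         n_recur_on_aad_excluded = 0,
                         n_recur_on_aad_censored = 0,
                         event_rate = 1e-9, p_early_exit = 0, seed = 73)
  fu <- generate_followup(cfg)
  e <- build_survival_entries(fu$followup, fu$aad_intervals, quiet = TRUE)
  expect_false(any(e$event))
  expect_true(all(km_estimate(e)$estimate == 1))
})

test_that("infeasible calibrations are rejected", {
  expect_error(cohort_config(tti = list(non_erc = c(median = 40, q25 = 60, q75 = 27),
                                        erc = c(median = 50, q25 = 38, q75 = 75))),
               "infeasible")
  expect_error(followup_config(n_patients = 10, n_missing_followup = 20),
               "exceed")
})
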