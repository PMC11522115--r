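test_that("blanking and AAD rules map follow-up to entries", {
  fu <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    erc = c(FALSE, FALSE, TRUE, TRUE),
    recurrence_day = c(200, 200, 50, NA),
    last_followup_day = c(455, 455, 455, 455),
    last_aad_free_day = c(NA, 150, NA, NA),
    recurrence_on_aad = c(FALSE, TRUE, FALSE, NA))
  e <- build_survival_entries(fu, quiet = TRUE)
  expect_equal(nrow(e), 4)
  a <- e[e$patient_id == "A", ]
  expect_equal(a$time, 110)            # 200 - 90, event off AAD
  expect_true(a$event)
  b <- e[e$patient_id == "B", ]
  expect_equal(b$time, 60)             # censored at last AAD-free day 150
  expect_false(b$event)
  cc <- e[e$patient_id == "C", ]       # blanking recurrence ignored
  expect_false(cc$event)
  expect_equal(cc$time, 365)           # administrative horizon
  expect_equal(levels(e$group), c("non-ERC", "ERC"))
})

test_that("AAD intervals pause the survival clock", {
  fu <- tibble::tibble(patient_id = "A", recurrence_day = 300,
                       last_followup_day = 455)
  aad <- tibble::tibble(patient_id = "A", start_day = 150, end_day = 250)
  e <- build_survival_entries(fu, aad, quiet = TRUE)
  expect_equal(e$time, (300 - 90) - 100)   # 100 AAD days do not accrue
  expect_true(e$event)
  # reset mode restarts the clock after the AAD spell
  e2 <- build_survival_entries(fu, aad, aad_gap = "reset", quiet = TRUE)
  expect_equal(e2$time, 300 - 250)
})

test_that("patients without AAD-free follow-up are excluded with reasons", {
  fu <- tibble::tibble(
    patient_id = c("X", "Y", "Z"),
    recurrence_day = c(NA, 200, NA),
    last_followup_day = c(400, 400, NA),
    recurrence_on_aad = c(NA, TRUE, NA))
  aad <- tibble::tibble(patient_id = c("X", "Y"), start_day = c(0, 0),
                        end_day = c(400, 400))
  e <- build_survival_entries(fu, aad, quiet = TRUE)
  expect_equal(nrow(e), 0)
  excl <- survival_exclusions(e)
  expect_setequal(excl$reason[excl$patient_id == "X"], "no_aad_free_followup")
  expect_setequal(excl$reason[excl$patient_id == "Y"],
                  "recurrence_on_aad_without_aad_free_followup")
  expect_setequal(excl$reason[excl$patient_id == "Z"], "missing_followup")
  # inconsistent dates are rejected, not silently fixed
  bad <- tibble::tibble(patient_id = "W", recurrence_day = 500,
                        last_followup_day = 400)
  eb <- build_survival_entries(bad, quiet = TRUE)
  expect_equal(survival_exclusions(eb)$reason, "inconsistent_dates")
})

test_that("entry plus exclusion counts always equal the input patient count", {
  fu <- generate_followup(followup_config(seed = 9))
  e <- build_survival_entries(fu$followup, fu$aad_intervals, quiet = TRUE)
  excl <- survival_exclusions(e)
  expect_equal(nrow(e) + nrow(excl), nrow(fu$followup))
  # exclusion tallies equal the generator's bookkeeping
  tab <- table(excl$reason)
  expect_equal(unname(tab[["missing_followup"]]), fu$truth$missing)
  expect_equal(unname(tab[["no_aad_free_followup"]]), fu$truth$aad_only)
  expect_equal(unname(tab[["recurrence_on_aad_without_aad_free_followup"]]),
               fu$truth$recur_aad_excl)
  expect_equal(nrow(e), fu$truth$n_entrants)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  e <- tibble::tibble(time = c(1, 1.5, 2, 3),
                      event = c(TRUE, FALSE, TRUE, FALSE))
  km <- km_estimate(e)
  # S(2) = (3/4) * (1/2): the censor at 1.5 leaves 2 at risk at time 2
  expect_equal(km_survival_at(km, 2), 0.375)
  expect_equal(km_survival_at(km, 1), 0.75)
  expect_equal(km_survival_at(km, 0.5), 1)
})

test_that("KM with no events is flat at one; without censoring it counts", {
  flat <- km_estimate(tibble::tibble(time = c(10, 20, 30),
                                     event = c(FALSE, FALSE, FALSE)))
  expect_true(all(flat$estimate == 1))
  # no censoring: S(t) = proportion with time > t
  withr::with_seed(3, {
    times <- sample(1:50, 30, replace = TRUE)
    km <- km_estimate(tibble::tibble(time = times, event = TRUE))
    for (t in c(0, 5, 17, 33, 49)) {
      expect_equal(km_survival_at(km, t), mean(times > t))
    }
  })
})

test_that("KM is a non-increasing step function within [0, 1]", {
  withr::with_seed(13, {
    e <- tibble::tibble(time = rexp(80, 1 / 100),
                        event = runif(80) < 0.7,
                        group = factor(rep(c("A", "B"), 40)))
    km <- km_estimate(e)
    for (g in levels(km$group)) {
      est <- km$estimate[km$group == g]
      expect_false(is.unsorted(rev(est)))
      expect_true(all(est >= 0 & est <= 1))
    }
  })
})

test_that("log-rank on identical groups is exactly null", {
  base <- tibble::tibble(time = c(5, 8, 12, 20), event = c(TRUE, TRUE, FALSE, TRUE))
  e <- dplyr::bind_rows(dplyr::mutate(base, group = "A"),
                        dplyr::mutate(base, group = "B"))
  lr <- log_rank(e)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(log_rank(base), "group")
  expect_error(log_rank(dplyr::mutate(base, group = "A")), "two non-empty groups")
})

test_that("log-rank statistic equals the observed-minus-expected oracle", {
  withr::with_seed(23, {
    for (i in 1:10) {
      n <- 40
      e <- tibble::tibble(time = round(rexp(n, 1 / 50) + 1),
                          event = runif(n) < 0.8,
                          group = factor(sample(c("A", "B"), n, replace = TRUE)))
      expect_equal(log_rank(e)$chi_square,
                   logrank_oracle(e$time, e$event, e$group),
                   tolerance = 1e-8)
    }
  })
})

test_that("doubling every subject leaves KM unchanged and doubles O and E", {
  e <- tibble::tibble(time = c(3, 5, 7, 9, 11, 13),
                      event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                      group = factor(rep(c("A", "B"), 3)))
  e2 <- dplyr::bind_rows(e, e)
  for (t in c(2, 5, 8, 12)) {
    expect_equal(km_survival_at(km_estimate(e), t, group = "A"),
                 km_survival_at(km_estimate(e2), t, group = "A"))
  }
  oe1 <- attr(log_rank(e), "obs_exp")
  oe2 <- attr(log_rank(e2), "obs_exp")
  expect_equal(oe2$observed, 2 * oe1$observed)
  expect_equal(oe2$expected, 2 * oe1$expected)
})

test_that("log-rank holds its nominal type-I error under equal hazards", {
  n_rep <- 400
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- followup_config(n_patients = 60, p_erc_patient = 0.5,
                           n_missing_followup = 0, n_aad_only = 0,
                           n_recur_on_aad_excluded = 0,
                           n_recur_on_aad_censored = 0,
                           event_rate = 0.5, hazard_ratio_erc = 1,
                           seed = 10000 + r)
    fu <- generate_followup(cfg)
    e <- build_survival_entries(fu$followup, fu$aad_intervals, quiet = TRUE)
    pvals[r] <- log_rank(e)$p_value
  }
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})
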