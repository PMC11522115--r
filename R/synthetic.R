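#' Synthetic cohorts, traces, and follow-up
#'
#' Generators that emulate the statistical structure the validation analysis
#' assumes -- right-skewed times to isolation, group-shifted nadir
#' temperatures, a low vein-level ERC prevalence with optional within-patient
#' clustering, exponential-cooling freeze traces, and follow-up timelines
#' exercising every blanking/AAD censoring rule -- so that every stage of the
#' pipeline is testable without patient data. The same seed and configuration
#' always reproduce byte-identical output.
#'
#' @name synthetic-data
NULL

# log-normal parameters from a median and IQR
.lnorm_from_median_iqr <- function(median, q25, q75) {
  if (!(q25 > 0 && q75 > q25 && median > q25 && median < q75)) {
    abort("infeasible log-normal calibration: need 0 < q25 < median < q75")
  }
  list(meanlog = log(median), sdlog = log(q75 / q25) / (2 * qnorm(0.75)))
}

# normal parameters from a median and IQR
.norm_from_median_iqr <- function(median, q25, q75) {
  if (!(q75 > q25)) abort("infeasible normal calibration: need q75 > q25")
  list(mean = median, sd = (q75 - q25) / (2 * qnorm(0.75)))
}

# intercept a such that E[plogis(a + offset + b)] = target, b ~ N(0, re_sd);
# `offsets` is a sample of fixed linear-predictor contributions (0 for none)
.calibrate_logit_intercept <- function(target, offsets = 0, re_sd = 0) {
  f <- function(a) {
    if (re_sd == 0) {
      mean(plogis(a + offsets)) - target
    } else {
      mean(vapply(offsets, function(o) {
        integrate(function(b) plogis(a + o + b) * dnorm(b, 0, re_sd),
                  -8 * re_sd, 8 * re_sd)$value
      }, 0)) - target
    }
  }
  uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Cohort generator configuration
#'
#' Defaults reproduce the study conditions: 200 patients with four veins
#' each, a vein-level ERC prevalence of 5.3%, TTI log-normal with median
#' 40 s (IQR 27-60) in non-ERC veins and 50 s (IQR 38-75) in ERC veins,
#' nadir temperature normal with median -47 deg C (IQR -51..-43) versus
#' -41 deg C (IQR -45..-38), and unsuccessful applications zero-inflated
#' geometric with 21.2% versus 36.6% of veins having at least one. Roughly
#' 12% of veins are never adenosine-tested and each predictor is missing in
#' about 5.6% of veins, so that complete-case filtering has something to do.
#'
#' @param n_patients Number of patients.
#' @param veins_per_patient Veins per patient (at most 4).
#' @param erc_prevalence Target vein-level ERC prevalence.
#' @param tti Per-group TTI law, `list(non_erc = c(median, q25, q75), erc = ...)`
#'   in seconds.
#' @param nadir Per-group nadir-temperature law, same shape, deg C.
#' @param p_unsuccessful Per-group probability of at least one unsuccessful
#'   application, `c(non_erc = , erc = )`.
#' @param unsuccessful_geom_prob Geometric success probability for counts
#'   beyond the first unsuccessful application.
#' @param patient_re_sd SD (logit scale) of the patient-level random effect
#'   on ERC risk; 0 (independence between a patient's veins) by default,
#'   reflecting that the score itself ignores clustering.
#' @param outcome_model Optional `list(slope =, intercept = NULL)`: when
#'   supplied, ERC labels are reassigned by a logistic model on the true
#'   risk score (plus the patient effect); the intercept is calibrated to
#'   the target prevalence when `NULL`. `slope = 0` yields labels
#'   independent of the score (AUC 0.5).
#' @param p_untested Probability that a (non-ERC) vein was never
#'   adenosine-tested.
#' @param missing_prob Per-field missingness probabilities,
#'   `c(tti =, n_unsuccessful =, nadir =)`.
#' @param seed Integer seed; same seed and config give byte-identical
#'   cohorts.
#' @return A list of class `erc_cohort_config`.
#' @export
cohort_config <- function(n_patients = 200, veins_per_patient = 4,
                          erc_prevalence = 0.053,
                          tti = list(non_erc = c(median = 40, q25 = 27, q75 = 60),
                                     erc = c(median = 50, q25 = 38, q75 = 75)),
                          nadir = list(non_erc = c(median = -47, q25 = -51, q75 = -43),
                                       erc = c(median = -41, q25 = -45, q75 = -38)),
                          p_unsuccessful = c(non_erc = 0.212, erc = 0.366),
                          unsuccessful_geom_prob = 0.6,
                          patient_re_sd = 0,
                          outcome_model = NULL,
                          p_untested = 92 / 774,
                          missing_prob = c(tti = 0.056, n_unsuccessful = 0.056,
                                           nadir = 0.056),
                          seed = 1L) {
  stopifnot(n_patients >= 1, veins_per_patient >= 1, veins_per_patient <= 4,
            erc_prevalence > 0, erc_prevalence < 1,
            all(p_unsuccessful >= 0), all(p_unsuccessful <= 1),
            unsuccessful_geom_prob > 0, unsuccessful_geom_prob <= 1,
            patient_re_sd >= 0, p_untested >= 0, p_untested < 1,
            all(missing_prob >= 0), all(missing_prob < 1))
  for (g in c("non_erc", "erc")) {
    .lnorm_from_median_iqr(tti[[g]][["median"]], tti[[g]][["q25"]], tti[[g]][["q75"]])
    .norm_from_median_iqr(nadir[[g]][["median"]], nadir[[g]][["q25"]], nadir[[g]][["q75"]])
  }
  structure(list(n_patients = n_patients, veins_per_patient = veins_per_patient,
                 erc_prevalence = erc_prevalence, tti = tti, nadir = nadir,
                 p_unsuccessful = p_unsuccessful,
                 unsuccessful_geom_prob = unsuccessful_geom_prob,
                 patient_re_sd = patient_re_sd, outcome_model = outcome_model,
                 p_untested = p_untested, missing_prob = missing_prob,
                 seed = as.integer(seed)),
            class = "erc_cohort_config")
}

# draw group-conditional covariates for `n` veins of group `g`
.draw_covariates <- function(n, g, config) {
  tt <- .lnorm_from_median_iqr(config$tti[[g]][["median"]],
                               config$tti[[g]][["q25"]],
                               config$tti[[g]][["q75"]])
  nd <- .norm_from_median_iqr(config$nadir[[g]][["median"]],
                              config$nadir[[g]][["q25"]],
                              config$nadir[[g]][["q75"]])
  any_u <- runif(n) < config$p_unsuccessful[[g]]
  tibble(tti_s = rlnorm(n, tt$meanlog, tt$sdlog),
         nadir_temp_c = rnorm(n, nd$mean, nd$sd),
         n_unsuccessful = ifelse(any_u,
                                 1 + rgeom(n, config$unsuccessful_geom_prob), 0))
}

#' Generate a synthetic vein-level cohort
#'
#' Veins are assigned a latent ERC group (Bernoulli at the target
#' prevalence, shifted by the patient random effect when
#' `patient_re_sd > 0`), covariates are drawn from the group-conditional
#' calibrated laws, and -- when an `outcome_model` is supplied -- the ERC
#' label is reassigned by a logistic model on the true risk score. The
#' ground-truth label is kept in column `erc_true` alongside the observed
#' `erc_status` (which may be `"untested"`) and the possibly-missing
#' predictors.
#'
#' @param config An [cohort_config()] object.
#' @param params Score parameters used for the `outcome_model` score.
#' @return A vein table (tibble) with the standard columns plus `erc_true`;
#'   the configuration is attached as attribute `"config"`.
#' @export
generate_cohort <- function(config = cohort_config(), params = score_params()) {
  stopifnot(inherits(config, "erc_cohort_config"))
  with_seed(config$seed, {
    n_p <- config$n_patients
    n_v <- n_p * config$veins_per_patient
    patient_id <- sprintf("P%04d", seq_len(n_p))
    b <- rnorm(n_p, 0, config$patient_re_sd)
    veins <- expand_grid(patient_id = patient_id,
                         vein = pv_labels[seq_len(config$veins_per_patient)])
    b_vein <- rep(b, each = config$veins_per_patient)
    alpha <- .calibrate_logit_intercept(config$erc_prevalence,
                                        re_sd = config$patient_re_sd)
    erc_true <- runif(n_v) < plogis(alpha + b_vein)
    cov <- tibble(tti_s = numeric(n_v), nadir_temp_c = numeric(n_v),
                  n_unsuccessful = numeric(n_v))
    for (g in c("non_erc", "erc")) {
      idx <- if (g == "erc") which(erc_true) else which(!erc_true)
      if (length(idx)) cov[idx, ] <- .draw_covariates(length(idx), g, config)
    }
    if (!is.null(config$outcome_model)) {
      slope <- config$outcome_model$slope
      score <- erc_score(cov$tti_s, cov$n_unsuccessful, cov$nadir_temp_c, params)
      intercept <- config$outcome_model$intercept %||%
        .calibrate_logit_intercept(config$erc_prevalence,
                                   offsets = slope * score,
                                   re_sd = config$patient_re_sd)
      erc_true <- runif(n_v) < plogis(intercept + slope * score + b_vein)
    }
    status <- rep("none", n_v)
    status[erc_true] <- ifelse(runif(sum(erc_true)) < 19 / 42,
                               "reconnection_pre_adenosine",
                               "dormant_with_adenosine")
    status[!erc_true & runif(n_v) < config$p_untested] <- "untested"
    mp <- config$missing_prob
    cov$tti_s[runif(n_v) < mp[["tti"]]] <- NA_real_
    cov$n_unsuccessful[runif(n_v) < mp[["n_unsuccessful"]]] <- NA_real_
    cov$nadir_temp_c[runif(n_v) < mp[["nadir"]]] <- NA_real_
    out <- bind_cols(veins, cov) |>
      mutate(erc_status = status,
             n_bonus = rbinom(n_v, 1, 0.05),
             erc_true = erc_true)
    attr(out, "config") <- config
    out
  })
}

#' Group-conditional operating point of the generator
#'
#' Sensitivity and specificity of the risk score at a cutoff under the
#' generator's own covariate laws, obtained by drawing a large fresh sample
#' directly from the group-conditional distributions (independent of any
#' generated cohort). Serves as the parameter-recovery reference for
#' metrics measured on finite cohorts.
#'
#' @param config An [cohort_config()] object.
#' @param cutoff Score cutoff.
#' @param params Score parameters.
#' @param n Monte-Carlo draws per group.
#' @param seed Seed for the reference draw.
#' @return One-row tibble with `cutoff`, `sensitivity`, `specificity`.
#' @export
generator_operating_point <- function(config, cutoff, params = score_params(),
                                      n = 2e5, seed = 999L) {
  with_seed(seed, {
    pos <- .draw_covariates(n, "erc", config)
    neg <- .draw_covariates(n, "non_erc", config)
    s_pos <- erc_score(pos$tti_s, pos$n_unsuccessful, pos$nadir_temp_c, params)
    s_neg <- erc_score(neg$tti_s, neg$n_unsuccessful, neg$nadir_temp_c, params)
    tibble(cutoff = cutoff,
           sensitivity = mean(s_pos >= cutoff),
           specificity = mean(s_neg < cutoff))
  })
}

#' Generate a synthetic freeze trace
#'
#' Exponential-approach cooling from `start_temp_c` toward the requested
#' nadir over the application, then a linear rewarm to 0 deg C followed by
#' an exponential approach to 37 deg C, sampled at `sample_hz`. When
#' `deflation_truncated` the recording stops once the rewarm reaches
#' `deflate_temp_c` (before 20 deg C), emulating automatic balloon
#' deflation cutting the console export short. The generating curve's exact
#' feature values (freeze AUC, magnitude, warming times, spot temperatures)
#' are attached as attribute `"truth"` for oracle testing.
#'
#' @param tti_s Time to isolation (s); the freeze lasts `tti_s +
#'   freeze_extra_s`.
#' @param nadir_temp_c Asymptotic nadir (deg C, negative).
#' @param start_temp_c Temperature at application start.
#' @param tau_cool Cooling time constant (s).
#' @param rewarm_rate Initial linear rewarm rate (deg C per s).
#' @param tau_warm Exponential rewarm time constant (s).
#' @param freeze_extra_s Ablation continues this long past isolation.
#' @param deflation_truncated Whether the export ends at balloon deflation.
#' @param deflate_temp_c Rewarm temperature at which a truncated export
#'   ends; must be below 20.
#' @param record_until_c Rewarm temperature at which a full export ends;
#'   above 20 so warming time to 20 deg C is observable.
#' @param noise_sd SD of Gaussian measurement noise added to the samples.
#' @param sample_hz Sampling rate (Hz).
#' @param seed Optional seed for the noise.
#' @return Trace tibble (`time_s`, `temp_c`) with attributes `"truth"`,
#'   `"tti_s"` and `"deflation_truncated"`.
#' @export
generate_trace <- function(tti_s = 40, nadir_temp_c = -47, start_temp_c = 20,
                           tau_cool = 20, rewarm_rate = 7, tau_warm = 40,
                           freeze_extra_s = 150,
                           deflation_truncated = FALSE, deflate_temp_c = 10,
                           record_until_c = 25, noise_sd = 0,
                           sample_hz = 1, seed = NULL) {
  stopifnot(nadir_temp_c < 0, start_temp_c > 0, tau_cool > 0,
            rewarm_rate > 0, tau_warm > 0, deflate_temp_c < 20,
            deflate_temp_c > 0, record_until_c > 20, record_until_c < 37)
  tf <- tti_s + freeze_extra_s
  amp <- start_temp_c - nadir_temp_c
  cool <- function(t) nadir_temp_c + amp * exp(-t / tau_cool)
  t_nadir <- tf                       # strictly decreasing => minimum at tf
  nadir_actual <- cool(tf)
  s1 <- -nadir_actual / rewarm_rate   # linear rewarm reaches 0 deg C
  warm <- function(s) {               # s = time since tf
    ifelse(s <= s1, nadir_actual + rewarm_rate * s,
           37 * (1 - exp(-(s - s1) / tau_warm)))
  }
  warm_time_to <- function(th) {      # exact crossing of the warming curve
    if (th <= 0) (th - nadir_actual) / rewarm_rate
    else s1 + tau_warm * log(37 / (37 - th))
  }
  end_temp <- if (deflation_truncated) deflate_temp_c else record_until_c
  s_end <- warm_time_to(end_temp)
  # analytic sub-zero pieces of the generating curve
  t_zero <- tau_cool * log(amp / (-nadir_temp_c))
  cool_area <- -(nadir_temp_c * (tf - t_zero) +
                   amp * tau_cool * (exp(-t_zero / tau_cool) - exp(-tf / tau_cool)))
  warm_area <- -nadir_actual * s1 / 2
  time_below <- (tf - t_zero) + s1
  truth <- tibble(
    nadir_temp_c = nadir_actual,
    nadir_time_s = t_nadir,
    freeze_auc = cool_area + warm_area,
    time_below_zero_s = time_below,
    freeze_magnitude = (cool_area + warm_area) / time_below,
    temp_at_30s = if (tf >= 30) cool(30) else NA_real_,
    temp_at_60s = if (tf >= 60) cool(60) else NA_real_,
    temp_at_tti = cool(tti_s),
    warming_time_to_0 = min(warm_time_to(0), s_end),
    warming_time_to_15 = min(warm_time_to(15), s_end),
    warming_time_to_20 = min(warm_time_to(20), s_end),
    warming_truncated = deflation_truncated &&
      (warm_time_to(20) > s_end || warm_time_to(15) > s_end)
  )
  times <- seq(0, tf + s_end, by = 1 / sample_hz)
  temps <- ifelse(times <= tf, cool(times), warm(times - tf))
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) rnorm(length(times), 0, noise_sd)
    else with_seed(as.integer(seed), rnorm(length(times), 0, noise_sd))
    temps <- temps + noise
  }
  out <- tibble(time_s = times, temp_c = temps)
  attr(out, "truth") <- truth
  attr(out, "tti_s") <- tti_s
  attr(out, "deflation_truncated") <- deflation_truncated
  out
}

#' Follow-up generator configuration
#'
#' Category counts default to the study's accounting on 201 patients: 13
#' with missing follow-up, 7 whose entire post-blanking follow-up was on an
#' antiarrhythmic drug, 23 with a recurrence on an AAD before ever stopping
#' it (all excluded from the curve), plus a configurable number of entrants
#' censored at a late AAD restart. Event times among entrants are
#' exponential, with a group hazard ratio for ERC patients.
#'
#' @param n_patients Number of patients.
#' @param p_erc_patient Patient-level ERC prevalence.
#' @param n_missing_followup Patients with no usable follow-up.
#' @param n_aad_only Patients with AAD-covered follow-up and no recurrence.
#' @param n_recur_on_aad_excluded Patients recurring on an AAD with no
#'   prior AAD-free follow-up.
#' @param n_recur_on_aad_censored Entrants recurring after an AAD restart
#'   (censored at the restart).
#' @param event_rate Yearly AF-recurrence hazard among non-ERC entrants.
#' @param hazard_ratio_erc Hazard ratio of ERC versus non-ERC patients.
#' @param p_early_exit Probability an entrant's last follow-up falls short
#'   of the full horizon.
#' @param max_followup_day Last scheduled follow-up day (calendar, from
#'   ablation).
#' @param blanking_days Blanking period (days).
#' @param seed Integer seed.
#' @return A list of class `erc_followup_config`.
#' @export
followup_config <- function(n_patients = 201, p_erc_patient = 35 / 201,
                            n_missing_followup = 13, n_aad_only = 7,
                            n_recur_on_aad_excluded = 23,
                            n_recur_on_aad_censored = 5,
                            event_rate = 0.28, hazard_ratio_erc = 1,
                            p_early_exit = 0.15,
                            max_followup_day = 455, blanking_days = 90,
                            seed = 1L) {
  n_special <- n_missing_followup + n_aad_only + n_recur_on_aad_excluded +
    n_recur_on_aad_censored
  if (n_special > n_patients) abort("category counts exceed n_patients")
  stopifnot(event_rate > 0, hazard_ratio_erc >= 0,
            p_erc_patient >= 0, p_erc_patient <= 1,
            max_followup_day > blanking_days)
  structure(list(n_patients = n_patients, p_erc_patient = p_erc_patient,
                 n_missing_followup = n_missing_followup,
                 n_aad_only = n_aad_only,
                 n_recur_on_aad_excluded = n_recur_on_aad_excluded,
                 n_recur_on_aad_censored = n_recur_on_aad_censored,
                 event_rate = event_rate, hazard_ratio_erc = hazard_ratio_erc,
                 p_early_exit = p_early_exit,
                 max_followup_day = max_followup_day,
                 blanking_days = blanking_days, seed = as.integer(seed)),
            class = "erc_followup_config")
}

#' Generate synthetic follow-up records
#'
#' Emits one patient per row with the exclusion/censoring category counts
#' fixed exactly as configured, so that the survival module's bookkeeping
#' can be checked against known ground truth.
#'
#' @param config An [followup_config()] object.
#' @return List with `followup` (tibble: `patient_id`, `erc`,
#'   `recurrence_day`, `last_followup_day`, `last_aad_free_day`,
#'   `recurrence_on_aad`), `aad_intervals` (tibble: `patient_id`,
#'   `start_day`, `end_day`) and `truth` (the per-category counts,
#'   including the expected number of entrants).
#' @export
generate_followup <- function(config = followup_config()) {
  stopifnot(inherits(config, "erc_followup_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    bl <- config$blanking_days
    maxd <- config$max_followup_day
    id <- sprintf("F%04d", seq_len(n))
    erc <- runif(n) < config$p_erc_patient
    cat_counts <- c(missing = config$n_missing_followup,
                    aad_only = config$n_aad_only,
                    recur_aad_excl = config$n_recur_on_aad_excluded,
                    recur_aad_cens = config$n_recur_on_aad_censored)
    category <- rep("entrant", n)
    special <- sample.int(n, sum(cat_counts))
    category[special] <- rep(names(cat_counts), cat_counts)
    rec <- rep(NA_real_, n)
    lastf <- rep(maxd, n)
    last_free <- rep(NA_real_, n)
    on_aad <- rep(NA, n)
    aad <- list()
    rate_day <- config$event_rate / 365 *
      ifelse(erc, config$hazard_ratio_erc, 1)
    for (i in seq_len(n)) {
      switch(category[i],
        missing = {
          lastf[i] <- NA_real_
        },
        aad_only = {
          aad[[length(aad) + 1]] <- tibble(patient_id = id[i],
                                           start_day = 0, end_day = lastf[i])
        },
        recur_aad_excl = {
          rec[i] <- runif(1, bl + 1, maxd)
          on_aad[i] <- TRUE
          aad[[length(aad) + 1]] <- tibble(patient_id = id[i],
                                           start_day = 0, end_day = lastf[i])
        },
        recur_aad_cens = {
          # AAD stopped at blanking, restarted later; recurrence on the restart
          restart <- runif(1, bl + 60, maxd - 30)
          rec[i] <- runif(1, restart + 1, maxd)
          on_aad[i] <- TRUE
          last_free[i] <- restart
          aad[[length(aad) + 1]] <- bind_rows(
            tibble(patient_id = id[i], start_day = 0, end_day = bl),
            tibble(patient_id = id[i], start_day = restart, end_day = maxd))
        },
        entrant = {
          aad[[length(aad) + 1]] <- tibble(patient_id = id[i],
                                           start_day = 0, end_day = bl)
          if (runif(1) < config$p_early_exit) {
            lastf[i] <- runif(1, bl + 30, maxd)
          }
          ev <- rexp(1, rate_day[i])
          if (bl + ev <= lastf[i]) {
            rec[i] <- bl + ev
            on_aad[i] <- FALSE
          }
        })
    }
    followup <- tibble(patient_id = id, erc = erc,
                       recurrence_day = rec, last_followup_day = lastf,
                       last_aad_free_day = last_free,
                       recurrence_on_aad = on_aad)
    truth <- as.list(cat_counts)
    truth$n_entrants <- n - sum(cat_counts) + config$n_recur_on_aad_censored
    truth$category <- category
    list(followup = followup,
         aad_intervals = list_rbind(aad),
         truth = truth)
  })
}
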