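#' ERC risk-score parameters
#'
#' The vein-level ERC risk score is the linear combination
#' `coef_tti * TTI + coef_unsuccessful * n_unsuccessful + coef_nadir * nadir`,
#' with TTI in seconds, the unsuccessful-application count, and the nadir
#' balloon temperature in deg C. The default coefficients are the published
#' ones (0.02, 0.5, 0.2); they are taken as given here, not re-derived.
#' Two cutoffs are in use: the originally derived `-6.7` and the common
#' cutoff `-7.2` chosen to perform well in both the derivation and the
#' validation cohort. A score equal to or above the cutoff flags the vein
#' for a 30-minute wait with adenosine testing.
#'
#' @param coef_tti Score units per second of TTI.
#' @param coef_unsuccessful Score units per unsuccessful application.
#' @param coef_nadir Score units per deg C of nadir temperature.
#' @param cutoff Classification cutoff (score units); `-7.2` by default.
#' @return A list of class `erc_score_params`.
#' @export
#' @examples
#' score_params()               # common cutoff -7.2
#' score_params(cutoff = -6.7)  # originally derived cutoff
score_params <- function(coef_tti = 0.02, coef_unsuccessful = 0.5,
                         coef_nadir = 0.2, cutoff = -7.2) {
  vals <- c(coef_tti, coef_unsuccessful, coef_nadir, cutoff)
  if (length(vals) != 4 || anyNA(vals) || any(!is.finite(vals))) {
    abort("all score parameters must be single finite numbers")
  }
  structure(list(coef_tti = coef_tti, coef_unsuccessful = coef_unsuccessful,
                 coef_nadir = coef_nadir, cutoff = cutoff),
            class = "erc_score_params")
}

#' @export
print.erc_score_params <- function(x, ...) {
  cat("ERC risk score: ", x$coef_tti, " * TTI + ", x$coef_unsuccessful,
      " * n_unsuccessful + ", x$coef_nadir, " * nadir  (cutoff ",
      x$cutoff, ", score >= cutoff => test)\n", sep = "")
  invisible(x)
}

#' Compute the ERC risk score
#'
#' @param tti_s Time to isolation in seconds.
#' @param n_unsuccessful Number of unsuccessful cryo-applications.
#' @param nadir_temp_c Nadir balloon temperature in deg C.
#' @param params An [score_params()] object.
#' @return Numeric score(s); the arithmetic is exact on the given values.
#'   Missing inputs are an error -- filter with [filter_complete_veins()]
#'   first.
#' @export
#' @examples
#' erc_score(30, 1, -40)  # -6.9
erc_score <- function(tti_s, n_unsuccessful, nadir_temp_c,
                      params = score_params()) {
  if (anyNA(tti_s) || anyNA(n_unsuccessful) || anyNA(nadir_temp_c)) {
    abort("erc_score inputs must be complete; see filter_complete_veins()")
  }
  params$coef_tti * tti_s + params$coef_unsuccessful * n_unsuccessful +
    params$coef_nadir * nadir_temp_c
}

#' Classify a score against a cutoff
#'
#' A score equal to or above the cutoff requires a 30-minute waiting period
#' with adenosine testing; ties count as positive.
#'
#' @param score Numeric score(s).
#' @param cutoff Cutoff in score units.
#' @return Factor with levels `no_test`, `test_required`.
#' @export
classify_score <- function(score, cutoff = -7.2) {
  factor(ifelse(score >= cutoff, "test_required", "no_test"),
         levels = c("no_test", "test_required"))
}

#' Append score and decision columns to a vein table
#'
#' Tidy-style wrapper: computes the score where all three predictors are
#' present (`NA` elsewhere) and the test decision at the chosen cutoff.
#'
#' @param veins A vein table.
#' @param params An [score_params()] object.
#' @param cutoff Cutoff; defaults to the one in `params`.
#' @return `veins` with columns `erc_score` and `decision` appended.
#' @export
add_erc_score <- function(veins, params = score_params(), cutoff = params$cutoff) {
  veins <- validate_vein_table(veins)
  complete <- !is.na(veins$tti_s) & !is.na(veins$n_unsuccessful) &
    !is.na(veins$nadir_temp_c)
  score <- rep(NA_real_, nrow(veins))
  score[complete] <- erc_score(veins$tti_s[complete],
                               veins$n_unsuccessful[complete],
                               veins$nadir_temp_c[complete], params)
  veins$erc_score <- score
  veins$decision <- classify_score(score, cutoff)
  veins
}

#' TTI threshold that makes a vein test-positive
#'
#' Inverts the score at the cutoff: for a given nadir temperature and
#' unsuccessful-application count, the minimal time to isolation (s) at
#' which the score reaches the cutoff,
#' `TTI* = (cutoff - coef_unsuccessful * n - coef_nadir * nadir) / coef_tti`.
#' Values at or below 0 mean the vein must always be tested regardless of
#' TTI.
#'
#' @param nadir_temp_c Nadir balloon temperature(s), deg C.
#' @param n_unsuccessful Unsuccessful-application count(s).
#' @param params An [score_params()] object; `coef_tti` must be positive.
#' @return TTI threshold(s) in seconds (continuous).
#' @export
#' @examples
#' tti_threshold(-39, 0)  # 30 s
#' tti_threshold(-44, 3)  # 5 s
tti_threshold <- function(nadir_temp_c, n_unsuccessful = 0,
                          params = score_params()) {
  if (params$coef_tti <= 0) abort("coef_tti must be positive to invert the score")
  raw <- (params$cutoff - params$coef_unsuccessful * n_unsuccessful -
            params$coef_nadir * nadir_temp_c) / params$coef_tti
  # decimal coefficients are not binary-exact; snap away the representation
  # error so integral thresholds come out integral
  round(raw, 7)
}

#' Bedside decision table
#'
#' Grid of nadir balloon temperature by unsuccessful-application count, each
#' cell holding the rule for that combination: `always_test` when the TTI
#' threshold is at or below 0 s, `never_test` when it exceeds `tti_cap`
#' (observed TTIs beyond the cap are not displayed on the tool), and
#' otherwise the minimal TTI (s) at which adenosine testing is required.
#'
#' @param params An [score_params()] object.
#' @param nadir_range Integer nadir grid in deg C (rows).
#' @param u_range Unsuccessful-count grid (columns).
#' @param tti_cap Display cap in seconds (default 95); thresholds beyond it
#'   render as `never_test`.
#' @return Long tibble of class `erc_decision_table` with columns
#'   `nadir_temp_c`, `n_unsuccessful`, `tti_star`, `rule`,
#'   `tti_threshold_s` (`NA` unless `rule == "tti_threshold"`). Use
#'   [decision_table_wide()] for the bedside layout.
#' @export
decision_table <- function(params = score_params(),
                           nadir_range = seq(-30, -53),
                           u_range = 0:3, tti_cap = 95) {
  if (any(nadir_range != round(nadir_range))) {
    abort("nadir_range must be an integer grid")
  }
  if (tti_cap <= 0) abort("tti_cap must be positive")
  grid <- expand_grid(nadir_temp_c = nadir_range, n_unsuccessful = u_range)
  tti_star <- tti_threshold(grid$nadir_temp_c, grid$n_unsuccessful, params)
  rule <- dplyr::case_when(
    tti_star <= 0 ~ "always_test",
    tti_star > tti_cap ~ "never_test",
    TRUE ~ "tti_threshold"
  )
  out <- grid |>
    mutate(tti_star = tti_star,
           rule = rule,
           tti_threshold_s = ifelse(rule == "tti_threshold", tti_star, NA_real_))
  attr(out, "params") <- params
  attr(out, "tti_cap") <- tti_cap
  class(out) <- c("erc_decision_table", class(out))
  out
}

#' Decision table in bedside (wide) layout
#'
#' One row per nadir temperature, one column per unsuccessful-application
#' count, cells rendered as `"ERC test"`, `"NO ERC test"`, or
#' `">= <TTI>: ERC test"`.
#'
#' @param dt An [decision_table()] result.
#' @return Wide tibble of formatted cells.
#' @export
decision_table_wide <- function(dt) {
  cell <- dplyr::case_when(
    dt$rule == "always_test" ~ "ERC test",
    dt$rule == "never_test" ~ "NO ERC test",
    TRUE ~ paste0(">= ", round(dt$tti_threshold_s, 2), ": ERC test")
  )
  tibble(nadir_temp_c = dt$nadir_temp_c,
         u = paste0("u_", dt$n_unsuccessful),
         cell = cell) |>
    pivot_wider(names_from = "u", values_from = "cell")
}

#' @export
print.erc_decision_table <- function(x, ...) {
  p <- attr(x, "params")
  cat("ERC decision table (cutoff ", p$cutoff, ", TTI cap ",
      attr(x, "tti_cap"), " s)\n", sep = "")
  print(decision_table_wide(x), n = Inf)
  invisible(x)
}
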