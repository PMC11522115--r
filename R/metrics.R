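#' Diagnostic-accuracy metrics
#'
#' Confusion counts at a cutoff, the derived test characteristics
#' (sensitivity, specificity, likelihood ratios), prevalence-adjusted
#' predictive values via Bayes' theorem, and the expected-count projections
#' used to express model performance in whole veins.
#'
#' @name validation-metrics
NULL

# round half away from zero (base round() is half-to-even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Confusion counts at a cutoff
#'
#' Prediction is positive iff `score >= cutoff` (ties count as positive,
#' matching the classifier).
#'
#' @param scores Numeric vein scores.
#' @param labels Logical ERC outcomes (or anything coercible to logical).
#' @param cutoff Score cutoff.
#' @return One-row tibble with `cutoff`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  drop <- is.na(scores) | is.na(labels)
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " pair(s) with missing score or label"))
    scores <- scores[!drop]; labels <- labels[!drop]
  }
  pred <- scores >= cutoff
  tibble(cutoff = cutoff,
         tp = sum(pred & labels), fp = sum(pred & !labels),
         fn = sum(!pred & labels), tn = sum(!pred & !labels))
}

# PPV/NPV from rates via Bayes at an external prevalence
.bayes_pv <- function(sens, spec, prev) {
  ppv <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  npv <- spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)
  list(ppv = ppv, npv = npv)
}

#' Metrics from confusion counts
#'
#' Sensitivity and specificity come from the counts; the predictive values
#' are prevalence-adjusted via Bayes' theorem at `prevalence`, which is
#' deliberately decoupled from the sample's class balance: a validation
#' analysis typically supplies the cohort-level vein prevalence (e.g.
#' 41/774) rather than the complete-case subset prevalence. With
#' `prevalence = NULL` the sample prevalence `(tp+fn)/n` is used, in which
#' case `ppv = tp/(tp+fp)` and `npv = tn/(tn+fn)` exactly.
#'
#' @param confusion One-row data frame (or named list) with `tp`, `fp`,
#'   `fn`, `tn`, as from [confusion_at_cutoff()].
#' @param prevalence Disease prevalence used for the predictive values, in
#'   `[0, 1]`; `NULL` for the sample prevalence.
#' @param allow_degenerate If `TRUE`, a single-class sample yields `NA`
#'   rates instead of an error (used for degenerate report rows).
#' @return One-row tibble: the counts plus `sensitivity`, `specificity`,
#'   `lr_pos`, `lr_neg`, `ppv`, `npv`, `youden`, `prevalence_used`, and a
#'   `lr_undefined` flag set when a likelihood ratio is infinite or 0/0
#'   (specificity exactly 1 or 0).
#' @export
#' @examples
#' cc <- tibble::tibble(tp = 14, fp = 67, fn = 23, tn = 546)
#' metrics_from_confusion(cc, prevalence = 41 / 774)
metrics_from_confusion <- function(confusion, prevalence = NULL,
                                   allow_degenerate = FALSE) {
  cc <- as.list(confusion)
  for (f in c("tp", "fp", "fn", "tn")) {
    if (is.null(cc[[f]])) abort(paste0("confusion is missing '", f, "'"))
    if (cc[[f]] < 0) abort("confusion counts must be non-negative")
  }
  n_pos <- cc$tp + cc$fn
  n_neg <- cc$fp + cc$tn
  if (n_pos == 0 || n_neg == 0) {
    if (!allow_degenerate) {
      abort("need at least one positive and one negative for rates")
    }
    return(tibble(cutoff = cc$cutoff %||% NA_real_,
                  tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                  sensitivity = if (n_pos > 0) cc$tp / n_pos else NA_real_,
                  specificity = if (n_neg > 0) cc$tn / n_neg else NA_real_,
                  lr_pos = NA_real_, lr_neg = NA_real_, lr_undefined = TRUE,
                  ppv = NA_real_, npv = NA_real_, youden = NA_real_,
                  prevalence_used = prevalence %||% NA_real_))
  }
  sens <- cc$tp / n_pos
  spec <- cc$tn / n_neg
  if (is.null(prevalence)) prevalence <- n_pos / (n_pos + n_neg)
  if (prevalence < 0 || prevalence > 1) abort("prevalence must be in [0, 1]")
  lr_pos <- if (spec < 1) sens / (1 - spec) else Inf
  lr_neg <- if (spec > 0) (1 - sens) / spec else NaN
  pv <- .bayes_pv(sens, spec, prevalence)
  tibble(cutoff = cc$cutoff %||% NA_real_,
         tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
         sensitivity = sens, specificity = spec,
         lr_pos = lr_pos, lr_neg = lr_neg,
         lr_undefined = spec %in% c(0, 1),
         ppv = pv$ppv, npv = pv$npv,
         youden = sens + spec - 1,
         prevalence_used = prevalence)
}

#' Predictive values from published rates
#'
#' Bayes' theorem applied directly to a reported sensitivity, specificity
#' and prevalence, for cohorts where only the rates are available (e.g. a
#' derivation cohort summarised in print).
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param prevalence Prevalence in `[0, 1]`.
#' @return One-row tibble with the inputs, `lr_pos`, `lr_neg`, `ppv`,
#'   `npv`, `youden`.
#' @export
#' @examples
#' metrics_from_rates(0.7250, 0.7822, 0.0922)
metrics_from_rates <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  pv <- .bayes_pv(sensitivity, specificity, prevalence)
  tibble(sensitivity = sensitivity, specificity = specificity,
         lr_pos = if (specificity < 1) sensitivity / (1 - specificity) else Inf,
         lr_neg = if (specificity > 0) (1 - sensitivity) / specificity else NaN,
         ppv = pv$ppv, npv = pv$npv,
         youden = sensitivity + specificity - 1,
         prevalence_used = prevalence)
}

#' Metrics at one or more cutoffs
#'
#' Convenience wrapper chaining [confusion_at_cutoff()] and
#' [metrics_from_confusion()] over a vector of cutoffs.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Numeric vector of cutoffs.
#' @inheritParams metrics_from_confusion
#' @return Tibble with one metrics row per cutoff.
#' @export
metrics_at_cutoff <- function(scores, labels, cutoffs, prevalence = NULL,
                              allow_degenerate = FALSE) {
  rows <- lapply(cutoffs, function(cutoff) {
    metrics_from_confusion(confusion_at_cutoff(scores, labels, cutoff),
                           prevalence = prevalence,
                           allow_degenerate = allow_degenerate)
  })
  list_rbind(rows)
}

#' Expected counts from rates
#'
#' Expresses test performance in whole veins: the number of ERC veins
#' correctly predicted (`sensitivity * n_pos`), the number of non-ERC veins
#' incorrectly predicted (`(1 - specificity) * n_neg`), and the number of
#' ERC veins missed (`(1 - sensitivity) * n_pos`), each rounded to the
#' nearest integer (half away from zero).
#'
#' @inheritParams metrics_from_rates
#' @param n_pos Number of ERC veins.
#' @param n_neg Number of non-ERC veins.
#' @return One-row tibble with `predicted_tp`, `predicted_fp`,
#'   `predicted_missed`.
#' @export
#' @examples
#' expected_counts(0.3784, 0.8907, 37, 613)
expected_counts <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 0, n_neg >= 0)
  tibble(predicted_tp = .round_half_away(sensitivity * n_pos),
         predicted_fp = .round_half_away((1 - specificity) * n_neg),
         predicted_missed = .round_half_away((1 - sensitivity) * n_pos))
}

#' Compare candidate cutoffs across two cohorts
#'
#' Evaluates every candidate cutoff in both cohorts and reports the cutoff
#' maximising the minimum Youden index (sensitivity + specificity - 1)
#' across the two -- an explicit, reproducible criterion for a cutoff that
#' performs well in both a derivation and a validation dataset. Ties go to
#' the most negative cutoff.
#'
#' @param scores_a,labels_a Scores and logical outcomes of cohort A.
#' @param scores_b,labels_b Scores and logical outcomes of cohort B.
#' @param cutoffs Candidate cutoffs; defaults to all distinct scores of the
#'   two cohorts.
#' @param prevalence_a,prevalence_b Optional external prevalences for the
#'   predictive values of each cohort.
#' @param cohort_names Length-2 names used in the `cohort` column.
#' @return Tibble of class `erc_cutoff_comparison`: one metrics row per
#'   cohort per cutoff, with the selected cutoff in attribute
#'   `"optimal_cutoff"` (also reported by [glance()]).
#' @export
compare_cutoffs <- function(scores_a, labels_a, scores_b, labels_b,
                            cutoffs = NULL,
                            prevalence_a = NULL, prevalence_b = NULL,
                            cohort_names = c("cohort_a", "cohort_b")) {
  if (is.null(cutoffs)) cutoffs <- sort(unique(c(scores_a, scores_b)))
  cutoffs <- sort(cutoffs)
  ma <- metrics_at_cutoff(scores_a, labels_a, cutoffs, prevalence_a) |>
    mutate(cohort = cohort_names[1], .before = 1)
  mb <- metrics_at_cutoff(scores_b, labels_b, cutoffs, prevalence_b) |>
    mutate(cohort = cohort_names[2], .before = 1)
  out <- bind_rows(ma, mb)
  min_youden <- pmin(ma$youden, mb$youden)
  attr(out, "optimal_cutoff") <- cutoffs[which.max(min_youden)]
  attr(out, "min_youden") <- max(min_youden)
  class(out) <- c("erc_cutoff_comparison", class(out))
  out
}

#' @export
glance.erc_cutoff_comparison <- function(x, ...) {
  tibble(optimal_cutoff = attr(x, "optimal_cutoff"),
         min_youden = attr(x, "min_youden"))
}
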