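#' Full validation report for a vein cohort
#'
#' Runs the complete validation pipeline on a vein-level table: scores the
#' complete-data veins, evaluates the requested cutoffs (confusion counts,
#' sensitivity/specificity, likelihood ratios, prevalence-adjusted
#' predictive values), projects the expected whole-vein counts, builds the
#' ROC curve, and summarises the patient-level consequence of each cutoff
#' (how many patients would skip the 30-minute wait with adenosine testing,
#' and how many ERC patients that would miss).
#'
#' The prevalence used for the predictive values defaults to the vein-level
#' ERC prevalence of the *full* table (before complete-case filtering),
#' matching how a cohort-level prevalence is reported; untested veins count
#' as ERC-negative.
#'
#' A patient skips testing only when every one of their veins has complete
#' data and every score falls below the cutoff -- a vein with missing data
#' forces testing (conservative).
#'
#' @param veins A vein table (see [read_vein_table()]).
#' @param cutoffs Cutoffs to evaluate; defaults to the derived (-6.7) and
#'   common (-7.2) cutoffs.
#' @param params An [score_params()] object.
#' @param prevalence Prevalence for the predictive values; `NULL` for the
#'   full-table vein prevalence.
#' @param require_tested Passed to [filter_complete_veins()].
#' @param output_dir Optional directory; when given, `metrics.csv`,
#'   `expected_counts.csv`, `patient_summary.csv` and `roc_points.csv` are
#'   written there.
#' @return List of class `erc_validation_report` with elements `metrics`,
#'   `expected`, `patient_summary` (tibbles), `roc` (an `erc_roc`, or
#'   `NULL` when the filtered cohort is single-class, flagged in
#'   `roc_degenerate`), `prevalence`, `n_complete`, `n_total`, `cutoffs`,
#'   `params`.
#' @export
run_validation_report <- function(veins, cutoffs = c(-6.7, -7.2),
                                  params = score_params(), prevalence = NULL,
                                  require_tested = FALSE,
                                  output_dir = NULL) {
  veins <- validate_vein_table(veins)
  all_labels <- erc_positive(veins$erc_status) %in% TRUE
  if (is.null(prevalence)) prevalence <- mean(all_labels)
  complete <- filter_complete_veins(veins, require_tested = require_tested,
                                    quiet = TRUE)
  if (nrow(complete) == 0) {
    abort("no veins with complete model data remain after filtering")
  }
  scores <- erc_score(complete$tti_s, complete$n_unsuccessful,
                      complete$nadir_temp_c, params)
  labels <- erc_positive(complete$erc_status) %in% TRUE
  metrics <- metrics_at_cutoff(scores, labels, cutoffs, prevalence = prevalence,
                               allow_degenerate = TRUE)
  expected <- list_rbind(lapply(seq_len(nrow(metrics)), function(i) {
    ec <- if (is.na(metrics$sensitivity[i]) || is.na(metrics$specificity[i])) {
      tibble(predicted_tp = NA_real_, predicted_fp = NA_real_,
             predicted_missed = NA_real_)
    } else {
      expected_counts(metrics$sensitivity[i], metrics$specificity[i],
                      sum(labels), sum(!labels))
    }
    bind_cols(tibble(cutoff = metrics$cutoff[i]), ec)
  }))
  roc_degenerate <- !any(labels) || !any(!labels)
  roc <- if (roc_degenerate) {
    inform("single-class cohort after filtering: no ROC curve computed")
    NULL
  } else {
    roc_curve(scores, labels)
  }
  scored <- add_erc_score(veins, params)
  by_patient <- scored |>
    group_by(.data$patient_id) |>
    summarise(n_veins = n(),
              all_complete = all(!is.na(.data$erc_score)),
              max_score = suppressWarnings(max(.data$erc_score, na.rm = TRUE)),
              erc_patient = any(erc_positive(.data$erc_status) %in% TRUE),
              .groups = "drop")
  patient_summary <- list_rbind(lapply(cutoffs, function(cutoff) {
    skip <- by_patient$all_complete & by_patient$max_score < cutoff
    tibble(cutoff = cutoff,
           n_patients = nrow(by_patient),
           n_all_data = sum(by_patient$all_complete),
           n_skip_testing = sum(skip),
           n_erc_missed = sum(skip & by_patient$erc_patient))
  }))
  out <- structure(list(metrics = metrics, expected = expected,
                        patient_summary = patient_summary,
                        roc = roc, roc_degenerate = roc_degenerate,
                        prevalence = prevalence,
                        n_complete = nrow(complete), n_total = nrow(veins),
                        cutoffs = cutoffs, params = params),
                   class = "erc_validation_report")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    readr::write_csv(metrics, file.path(output_dir, "metrics.csv"))
    readr::write_csv(expected, file.path(output_dir, "expected_counts.csv"))
    readr::write_csv(patient_summary, file.path(output_dir, "patient_summary.csv"))
    if (!is.null(roc)) {
      readr::write_csv(roc$points, file.path(output_dir, "roc_points.csv"))
    }
  }
  out
}

#' @export
print.erc_validation_report <- function(x, ...) {
  cat("ERC validation report\n")
  cat(sprintf("  %d of %d veins with complete model data; prevalence used %.4f\n",
              x$n_complete, x$n_total, x$prevalence))
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC %.3f (95%% CI [%.3f, %.3f])\n",
                x$roc$auc, x$roc$auc_ci[1], x$roc$auc_ci[2]))
  } else {
    cat("  ROC: degenerate (single class)\n")
  }
  for (i in seq_len(nrow(x$metrics))) {
    m <- x$metrics[i, ]
    cat(sprintf(paste0("  cutoff %.1f: sens %.2f%%, spec %.2f%%, LR+ %.3f, ",
                       "LR- %.3f, PPV %.2f%%, NPV %.2f%%\n"),
                m$cutoff, 100 * m$sensitivity, 100 * m$specificity,
                m$lr_pos, m$lr_neg, 100 * m$ppv, 100 * m$npv))
  }
  ps <- x$patient_summary
  for (i in seq_len(nrow(ps))) {
    cat(sprintf(paste0("  cutoff %.1f: %d/%d patients with all data would skip ",
                       "testing (%d ERC patient(s) missed)\n"),
                ps$cutoff[i], ps$n_skip_testing[i], ps$n_all_data[i],
                ps$n_erc_missed[i]))
  }
  invisible(x)
}

#' @rdname decision_table
#' @param object An `erc_decision_table` object.
#' @param ... Unused.
#' @export
autoplot.erc_decision_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(label = ifelse(.data$rule == "tti_threshold",
                          paste0(">=", round(.data$tti_threshold_s)), ""),
           rule = factor(.data$rule,
                         levels = c("always_test", "tti_threshold", "never_test")))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_unsuccessful),
                                   y = factor(.data$nadir_temp_c),
                                   fill = .data$rule)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_manual(values = c(always_test = "#d95f02",
                                          tti_threshold = "#fee8c8",
                                          never_test = "#1b9e77")) +
    ggplot2::labs(x = "Unsuccessful applications",
                  y = "Nadir balloon temperature (deg C)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
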