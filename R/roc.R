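#' Empirical ROC curve with AUC confidence interval
#'
#' Sweeps the threshold over all distinct scores with the `>=` convention
#' (prediction positive iff score at or above the threshold), so the curve's
#' operating points match [confusion_at_cutoff()] exactly. The AUC is the
#' trapezoidal area, which for an empirical ROC equals the Mann-Whitney
#' pair statistic (concordant pairs plus half the ties, over
#' `n_pos * n_neg`). The 95% confidence interval uses the DeLong
#' placement-variance method by default; the Hanley-McNeil approximation is
#' available by flag.
#'
#' @param scores Numeric scores (higher = more ERC-like).
#' @param labels Logical outcomes; needs at least one positive and one
#'   negative.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `erc_roc`: a list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `auc_se`,
#'   `auc_ci`, `ci_method`, `conf_level`, `n_pos`, `n_neg`. See [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' set.seed(1)
#' s <- c(rnorm(50, 1), rnorm(50))
#' roc <- roc_curve(s, rep(c(TRUE, FALSE), each = 50))
#' glance(roc)
roc_curve <- function(scores, labels, ci_method = c("delong", "hanley"),
                      conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels must match in length")
  drop <- is.na(scores) | is.na(labels)
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " pair(s) with missing score or label"))
    scores <- scores[!drop]; labels <- labels[!drop]
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative label")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(c) sum(scores >= c & labels), 0) / n_pos
  fpr <- vapply(thr, function(c) sum(scores >= c & !labels), 0) / n_neg
  points <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  # trapezoid over FPR; ties between classes contribute half automatically
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  se <- switch(ci_method,
               delong = .delong_se(scores, labels),
               hanley = .hanley_se(auc, n_pos, n_neg))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  structure(list(points = points, auc = auc, auc_se = se, auc_ci = ci,
                 ci_method = ci_method, conf_level = conf_level,
                 n_pos = n_pos, n_neg = n_neg),
            class = "erc_roc")
}

# DeLong standard error via placements: for each positive, the fraction of
# negatives it beats (ties half); variance combines both placement sets.
.delong_se <- function(scores, labels) {
  x <- scores[labels]   # positives
  y <- scores[!labels]  # negatives
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)  # per-positive placements
  v01 <- colMeans(psi)  # per-negative placements
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

.hanley_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' @export
print.erc_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, %d operating points\n",
              x$n_pos, x$n_neg, nrow(x$points)))
  cat(sprintf("AUC %.3f (%d%% CI [%.3f, %.3f], %s)\n", x$auc,
              round(100 * x$conf_level), x$auc_ci[1], x$auc_ci[2],
              x$ci_method))
  invisible(x)
}

#' @rdname roc_curve
#' @param x An `erc_roc` object.
#' @param ... Unused.
#' @export
tidy.erc_roc <- function(x, ...) x$points

#' @rdname roc_curve
#' @export
glance.erc_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_se = x$auc_se,
         conf_low = x$auc_ci[1], conf_high = x$auc_ci[2],
         ci_method = x$ci_method, conf_level = x$conf_level,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_curve
#' @param object An `erc_roc` object.
#' @export
autoplot.erc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC %.3f (%d%% CI [%.3f, %.3f])",
                                  object$auc, round(100 * object$conf_level),
                                  object$auc_ci[1], object$auc_ci[2])) +
    ggplot2::theme_minimal()
}
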