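# tie-corrected rank-statistic AUC: P(case score > control score) + 0.5 ties
auc_rank <- function(scores_cases, scores_controls) {
  n1 <- length(scores_cases)
  n2 <- length(scores_controls)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(scores_cases, scores_controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve and AUC
#'
#' Computes the AUC both as the tie-corrected rank statistic
#' (`(concordant pairs + 0.5 * ties) / (n_cases * n_controls)`) and as the
#' trapezoidal area under the threshold-sweep ROC curve; the two must agree
#' to 1e-12. The curve starts at (0, 0), ends at (1, 1) and is monotone in
#' both coordinates.
#'
#' @param scores_cases,scores_controls classifier scores for the two groups.
#' @return list: `auc`, `points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores_cases, scores_controls) {
  a <- auc_rank(scores_cases, scores_controls)
  thr <- sort(unique(c(scores_cases, scores_controls)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_controls >= t), numeric(1))
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (points$fpr[nrow(points)] != 1 || points$tpr[nrow(points)] != 1) {
    points <- rbind(points, data.frame(fpr = 1, tpr = 1))
  }
  trap <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                    utils::tail(points$tpr, -1)) / 2)
  if (abs(trap - a) > 1e-12) {
    stop("internal check failed: rank and trapezoidal AUC disagree", call. = FALSE)
  }
  list(auc = a, points = points)
}

#' Hanley-McNeil test of an AUC against chance
#'
#' Analytic standard error of a trapezoidal AUC `A` from `n_cases` cases and
#' `n_controls` controls: with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`,
#' `SE^2 = (A(1-A) + (n_cases-1)(Q1-A^2) + (n_controls-1)(Q2-A^2)) /
#' (n_cases * n_controls)`. The z statistic compares `A` with `null_auc`
#' (0.5 = no predictive value) on the standard normal scale.
#'
#' @param auc observed AUC in \[0, 1\].
#' @param n_cases,n_controls group sizes.
#' @param null_auc null value (default 0.5).
#' @param conf_level confidence level for the normal-theory CI (default 0.95).
#' @return list: `se`, `z`, `p_two_sided`, `ci` (clipped to \[0, 1\]),
#'   `boundary` (flag: SE of exactly 0).
#' @export
hanley_mcneil_test <- function(auc, n_cases, n_controls, null_auc = 0.5,
                               conf_level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_cases >= 1, n_controls >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
                (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls))
  boundary <- se == 0
  z <- if (boundary) Inf * sign(auc - null_auc) else (auc - null_auc) / se
  if (boundary && auc == null_auc) z <- 0
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  list(se = se, z = z, p_two_sided = p, ci = ci, boundary = boundary)
}

#' Full ROC report with inference against chance
#'
#' @param scores_cases,scores_controls classifier scores for the two groups.
#' @param null_auc null AUC (default 0.5).
#' @return list of class `roc_report`: `auc`, `points`, `se`, `z`,
#'   `p_two_sided`, `ci`, `n_cases`, `n_controls`.
#' @export
roc_report <- function(scores_cases, scores_controls, null_auc = 0.5) {
  roc <- roc_auc(scores_cases, scores_controls)
  hm <- hanley_mcneil_test(roc$auc, length(scores_cases),
                           length(scores_controls), null_auc = null_auc)
  structure(c(roc, hm,
              list(n_cases = length(scores_cases),
                   n_controls = length(scores_controls))),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), z = %.2f vs chance, p = %.2g\n",
              x$auc, x$ci[1], x$ci[2], x$z, x$p_two_sided))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  stopifnot(successes >= 0, successes <= n)
  alpha <- 1 - level
  low <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes,
                                                 n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1,
                                                  n - successes)
  c(low, high)
}

#' Confusion matrix and operating characteristics at a probability cutoff
#'
#' Samples with predicted probability at or above the threshold are called
#' positive. Sensitivity and specificity carry exact Clopper-Pearson
#' intervals.
#'
#' @param probabilities predicted case probabilities.
#' @param labels binary labels (1 = case).
#' @param threshold probability cutoff (default 0.5).
#' @param ci_level confidence level (default 0.95).
#' @return list of class `confusion_report`: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `ci_sensitivity`, `ci_specificity`,
#'   `threshold`.
#' @export
confusion_at_threshold <- function(probabilities, labels, threshold = 0.5,
                                   ci_level = 0.95) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.numeric(labels)
  pos <- probabilities >= threshold
  tp <- sum(pos & labels == 1)
  fp <- sum(pos & labels == 0)
  fn <- sum(!pos & labels == 1)
  tn <- sum(!pos & labels == 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (fp + tn),
                 ci_sensitivity = binomial_ci(tp, tp + fn, ci_level),
                 ci_specificity = binomial_ci(tn, fp + tn, ci_level),
                 threshold = threshold),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d | sens %.1f%% (%.0f-%.0f%%)  spec %.1f%% (%.0f-%.0f%%) @ %.2f\n",
              x$tp, x$fp, x$fn, x$tn,
              100 * x$sensitivity, 100 * x$ci_sensitivity[1], 100 * x$ci_sensitivity[2],
              100 * x$specificity, 100 * x$ci_specificity[1], 100 * x$ci_specificity[2],
              x$threshold))
  invisible(x)
}
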