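# Confusion-matrix statistics and ROC/AUC with bootstrap confidence
# intervals - the quantitative evaluation surface of the pipeline.

#' Build a confusion matrix
#'
#' @param predicted_case,actual_case Logical vectors, or supply counts via
#'   `confusion_matrix_counts()`.
#' @return List of class `"confusion_matrix"` with fields tp, fp, tn, fn.
#' @export
confusion_matrix <- function(predicted_case, actual_case) {
  confusion_matrix_counts(
    tp = sum(predicted_case & actual_case),
    fp = sum(predicted_case & !actual_case),
    tn = sum(!predicted_case & !actual_case),
    fn = sum(!predicted_case & actual_case)
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,tn,fn Non-negative counts.
#' @export
confusion_matrix_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_tep("confusion-matrix cells must be non-negative integers",
             "tepsig_error_confusion")
  if (sum(counts) == 0)
    stop_tep("empty confusion matrix", "tepsig_error_confusion")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion-matrix statistics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, Matthews
#' correlation coefficient, and Youden index `J = sens + spec - 1`. When any
#' MCC denominator factor is zero the MCC is defined as 0 and flagged via the
#' `mcc_degenerate` field.
#'
#' @param cm A `"confusion_matrix"` (or list with tp/fp/tn/fn).
#' @return List with sensitivity, specificity, accuracy, mcc, youden,
#'   mcc_degenerate.
#' @export
confusion_stats <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0)
    stop_tep("empty confusion matrix", "tepsig_error_confusion")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- denom == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       mcc = mcc, youden = sens + spec - 1, mcc_degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' Sweeps all unique score values as thresholds in descending order, grouping
#' tied scores into a single step (so ties contribute diagonal segments), and
#' integrates by the trapezoidal rule. The resulting AUC equals the
#' Mann-Whitney U statistic divided by `n_case * n_control`, with tied
#' case/control pairs counting one half.
#'
#' @param scores Prediction scores (larger = more case-like).
#' @param y Class labels (1/"case" = positive).
#' @return Object of class `"roc_curve"`: data.frame `points` (threshold,
#'   fpr, tpr) starting at (0,0) and ending at (1,1), plus `auc`.
#' @export
roc_curve <- function(scores, y) {
  yb <- as_binary_class(y)
  n1 <- sum(yb == 1); n0 <- sum(yb == 0)
  if (n1 == 0 || n0 == 0)
    stop_tep("both classes must be present", "tepsig_error_single_class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- yb[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp_step <- tapply(lab == 1, grp, sum)
  fp_step <- tapply(lab == 0, grp, sum)
  tpr <- c(0, cumsum(tp_step) / n1)
  fpr <- c(0, cumsum(fp_step) / n0)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_case = n1, n_control = n0),
            class = "roc_curve")
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls separately with replacement `n_boot` times,
#' recomputes the AUC of each replicate, and returns the percentile interval.
#' Deterministic given `seed`.
#'
#' @param scores Prediction scores.
#' @param y Class labels.
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `ci_low`, `ci_high`, `level`, `n_boot`.
#' @export
auc_ci <- function(scores, y, n_boot = 2000, level = 0.95, seed = 1L) {
  yb <- as_binary_class(y)
  idx1 <- which(yb == 1); idx0 <- which(yb == 0)
  if (length(idx1) < 5 || length(idx0) < 5)
    stop_tep("need at least 5 samples per class for a bootstrap CI",
             "tepsig_error_degenerate")
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i1 <- sample(idx1, replace = TRUE)
    i0 <- sample(idx0, replace = TRUE)
    roc_curve(c(scores[i1], scores[i0]),
              c(rep(1L, length(i1)), rep(0L, length(i0))))$auc
  }, numeric(1)))
  alpha <- (1 - level) / 2
  q <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low = q[1], ci_high = q[2], level = level, n_boot = n_boot)
}

#' Full per-cohort evaluation report
#'
#' Combines the Youden-optimal (or supplied) cutoff, confusion matrix, the
#' five summary statistics, ROC curve, AUC and its bootstrap CI into one
#' JSON-serializable object.
#'
#' @param scores Prediction scores for one cohort.
#' @param y Class labels.
#' @param cutoff Optional fixed cutoff; defaults to the Youden-optimal one
#'   computed from `scores` and `y`.
#' @param cohort Label stored in the report.
#' @param n_boot,level,seed Passed to [auc_ci()].
#' @return Object of class `"classifier_report"`.
#' @export
classifier_report <- function(scores, y, cutoff = NULL, cohort = "training",
                              n_boot = 2000, level = 0.95, seed = 1L) {
  yb <- as_binary_class(y)
  cutoff_source <- if (is.null(cutoff)) "youden-optimal" else "supplied"
  if (is.null(cutoff)) cutoff <- choose_cutoff(scores, yb)$cutoff
  cm <- confusion_matrix(scores > cutoff, yb == 1)
  st <- confusion_stats(cm)
  roc <- roc_curve(scores, yb)
  ci <- auc_ci(scores, yb, n_boot = n_boot, level = level, seed = seed)
  structure(list(
    cohort = cohort, n_case = sum(yb == 1), n_control = sum(yb == 0),
    cutoff = cutoff, cutoff_source = cutoff_source,
    confusion = unclass(cm)[c("tp", "fp", "tn", "fn")],
    sensitivity = st$sensitivity, specificity = st$specificity,
    accuracy = st$accuracy, mcc = st$mcc, youden = st$youden,
    auc = roc$auc, auc_ci_low = ci$ci_low, auc_ci_high = ci$ci_high,
    ci_level = level,
    roc = roc$points
  ), class = "classifier_report")
}
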