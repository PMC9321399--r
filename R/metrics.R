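#' ROC curve for a binary classifier score
#'
#' Orientation: higher score implies predicted positive. Candidate thresholds
#' are the midpoints between consecutive distinct sorted scores plus the two
#' infinite endpoints, so the curve always includes (sens = 1, spec = 0) and
#' (sens = 0, spec = 1). A sample is called positive when its score is
#' strictly above the threshold.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector (1 = positive), same length.
#' @return object of class `roc_curve`: data.frame with `threshold`,
#'   `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  if (length(scores) != length(labels)) stopf("length mismatch")
  if (anyNA(scores) || any(!is.finite(scores))) stopf("scores must be finite")
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  pos <- labels == 1
  sens <- vapply(thr, function(t) mean(scores[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] <= t), numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outscores
#' a random negative, with ties counting one half.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- assert_binary_labels(labels)
  if (length(scores) != length(labels)) stopf("length mismatch")
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Best ROC operating point by the Youden index
#'
#' Maximises J = sensitivity + specificity - 1 over the curve's thresholds.
#' Ties are broken toward higher specificity, then toward the lower
#' threshold.
#'
#' @param roc a [roc_curve()].
#' @return named list: `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_best_point <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + roc$specificity - 1
  ord <- order(-j, -roc$specificity, roc$threshold)
  i <- ord[1L]
  list(threshold = roc$threshold[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], youden = j[i])
}

#' Confusion-matrix summary of binary predictions
#'
#' Matthews correlation coefficient is defined as 0 when any marginal of the
#' 2x2 table is 0.
#'
#' @param predicted,labels equal-length binary 0/1 vectors.
#' @return list of class `confusion_summary`: `tp`, `fp`, `tn`, `fn`, `n`,
#'   `accuracy`, `sensitivity`, `specificity`, `mcc`.
#' @export
confusion_metrics <- function(predicted, labels) {
  if (length(predicted) != length(labels)) stopf("length mismatch")
  predicted <- as.numeric(predicted)
  labels <- as.numeric(labels)
  if (!is_binary01(predicted) || !is_binary01(labels)) {
    stopf("'predicted' and 'labels' must be binary 0/1")
  }
  tp <- sum(predicted == 1 & labels == 1)
  fp <- sum(predicted == 1 & labels == 0)
  tn <- sum(predicted == 0 & labels == 0)
  fn <- sum(predicted == 0 & labels == 1)
  n <- tp + fp + tn + fn
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
              accuracy = (tp + tn) / n,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
              mcc = mcc)
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n = %d)\n", x$tp, x$fp, x$tn, x$fn, x$n))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  MCC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}

#' Two-group comparison of clinical variables
#'
#' Continuous variables are compared by a two-sample t-test (Welch by
#' default), binary categorical variables by a chi-square test on the 2x2
#' table (without continuity correction by default). Variables with fewer
#' than two observations in either group get an `NA` p-value.
#'
#' @param clinical a data.frame (typically a `clinical_table`).
#' @param grouping binary 0/1 (or logical) vector, one element per row of
#'   `clinical`.
#' @param variables columns to test; defaults to every column except
#'   `patient_id`.
#' @param categorical names of variables to treat as categorical; defaults to
#'   those with at most two distinct values.
#' @param welch use Welch's unequal-variance t-test (default `TRUE`).
#' @param correct apply Yates continuity correction to the chi-square test
#'   (default `FALSE`).
#' @return data.frame with one row per variable: group summaries and
#'   `p_value`.
#' @export
two_group_tests <- function(clinical, grouping, variables = NULL,
                            categorical = NULL, welch = TRUE,
                            correct = FALSE) {
  grouping <- as.numeric(grouping)
  if (!is_binary01(grouping)) stopf("'grouping' must be binary")
  if (length(grouping) != nrow(clinical)) stopf("length mismatch")
  variables <- variables %||% setdiff(names(clinical), "patient_id")
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    if (!is.numeric(x)) x <- as.numeric(as.factor(x)) - 1
    is_cat <- if (is.null(categorical)) length(unique(stats::na.omit(x))) <= 2L else v %in% categorical
    x1 <- x[grouping == 1]
    x0 <- x[grouping == 0]
    if (is_cat) {
      tab <- table(factor(grouping, c(1, 0)), factor(x, c(1, 0)))
      p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_ else
        suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
      data.frame(variable = v, type = "categorical",
                 group1 = sprintf("%d (%.1f%%)", sum(x1 == 1, na.rm = TRUE),
                                  100 * mean(x1 == 1, na.rm = TRUE)),
                 group0 = sprintf("%d (%.1f%%)", sum(x0 == 1, na.rm = TRUE),
                                  100 * mean(x0 == 1, na.rm = TRUE)),
                 p_value = p, stringsAsFactors = FALSE)
    } else {
      p <- if (sum(!is.na(x1)) < 2L || sum(!is.na(x0)) < 2L) NA_real_ else
        tryCatch(stats::t.test(x1, x0, var.equal = !welch)$p.value,
                 error = function(e) NA_real_)  # e.g. both groups constant
      data.frame(variable = v, type = "continuous",
                 group1 = sprintf("%.1f (%.1f)", mean(x1, na.rm = TRUE),
                                  stats::sd(x1, na.rm = TRUE)),
                 group0 = sprintf("%.1f (%.1f)", mean(x0, na.rm = TRUE),
                                  stats::sd(x0, na.rm = TRUE)),
                 p_value = p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
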