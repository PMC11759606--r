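#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Tied scores count one half. A cohort with a single class has no defined
#' AUC and returns `NA` with attribute `undefined = TRUE`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 outcome labels.
#' @return AUC in `[0, 1]`, or flagged `NA`.
#' @export
auc_score <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold metrics from a 2x2 contingency table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)` and accuracy `(TP+TN)/n`. An empty denominator (0/0)
#' reports 0 and is flagged in the `degenerate` attribute.
#'
#' @param tp,fp,fn,tn contingency counts.
#' @return named numeric vector `(accuracy, sensitivity, specificity, ppv,
#'   npv)` with attribute `degenerate` naming any 0/0 metrics.
#' @export
contingency_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  assert_that(n > 0, "empty contingency table")
  safe <- function(num, den) if (den == 0) 0 else num / den
  out <- c(
    accuracy = (tp + tn) / n,
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn)
  )
  degenerate <- c("sensitivity", "specificity", "ppv", "npv")[
    c(tp + fn, tn + fp, tp + fp, tn + fn) == 0]
  attr(out, "degenerate") <- degenerate
  out
}

#' Youden-optimal operating threshold
#'
#' The score threshold (predict positive at `score >= threshold`) that
#' maximizes sensitivity + specificity - 1 on the given cohort; determine it
#' on the training cohort and freeze it for test evaluation.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return the chosen threshold (lowest maximizer on ties).
#' @export
youden_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pred <- as.integer(scores >= th)
    m <- contingency_metrics(sum(pred == 1 & labels == 1),
                             sum(pred == 1 & labels == 0),
                             sum(pred == 0 & labels == 1),
                             sum(pred == 0 & labels == 0))
    m[["sensitivity"]] + m[["specificity"]] - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Full classifier metric panel
#'
#' AUC by the rank statistic with a DeLong 95% confidence interval, plus the
#' threshold metrics at the supplied operating point.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold operating threshold (predict positive at
#'   `score >= threshold`); default 0.5.
#' @param model_name,cohort bookkeeping strings copied to the output.
#' @return one-row data frame: `model_name`, `cohort`, `accuracy`, `auc`,
#'   `auc_ci_low`, `auc_ci_high`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`. A single-class cohort has flagged `NA` AUC columns.
#' @export
evaluate_classifier <- function(scores, labels, threshold = 0.5,
                                model_name = "model", cohort = "test") {
  assert_that(length(scores) > 0, "no scores supplied")
  assert_that(length(scores) == length(labels), "length mismatch")
  auc <- auc_score(scores, labels)
  if (is.na(auc) || length(unique(scores)) < 2) {
    ci <- c(NA_real_, NA_real_)
  } else {
    # a perfect AUC has a collapsed DeLong interval; pROC warns about it,
    # but the [1, 1] interval itself already carries that information
    ci <- suppressWarnings(suppressMessages(as.numeric(
      pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<"),
                   method = "delong")
    )))[c(1, 3)]
  }
  pred <- as.integer(scores >= threshold)
  m <- contingency_metrics(sum(pred == 1 & labels == 1),
                           sum(pred == 1 & labels == 0),
                           sum(pred == 0 & labels == 1),
                           sum(pred == 0 & labels == 0))
  data.frame(
    model_name = model_name, cohort = cohort,
    accuracy = m[["accuracy"]], auc = as.numeric(auc),
    auc_ci_low = ci[1], auc_ci_high = ci[2],
    sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
    ppv = m[["ppv"]], npv = m[["npv"]],
    stringsAsFactors = FALSE
  )
}
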