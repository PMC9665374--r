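# ROC / AUC statistics with DeLong confidence intervals and tests, and exact
# Clopper-Pearson intervals. pROC supplies the DeLong machinery; the
# surrounding result containers and checks are the package's interface.

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney statistic (ties counted one-half); the 95\%
#' confidence interval uses DeLong's variance estimator, truncated to [0, 1].
#'
#' @param scores numeric risk scores (higher = more likely positive)
#' @param labels binary labels (0/1, logical, or a 2-level factor whose
#'   second level is the positive class)
#' @param conf_level confidence level (default 0.95)
#' @return object of class `roc_result`: list with `auc`, `ci95` = c(lo, hi),
#'   `n_pos`, `n_neg`, and `curve` (data.frame of fpr, tpr, monotone
#'   non-decreasing)
#' @export
#' @examples
#' roc_auc(c(.9, .8, .3, .2, .6), c(1, 1, 0, 0, 1))
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- normalize_labels(labels)
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c("0", "1"), direction = "<", quiet = TRUE)
  # pROC warns that a degenerate AUC of 1 yields the interval (1, 1); that is
  # the correct truncated answer here
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  co <- pROC::coords(r, x = "all", ret = c("specificity", "sensitivity"),
                     transpose = FALSE)
  curve <- data.frame(fpr = rev(1 - co$specificity), tpr = rev(co$sensitivity))
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    ci95 = c(lo = max(0, ci[1]), hi = min(1, ci[3])),
    n_pos = sum(labels == "1"),
    n_neg = sum(labels == "0"),
    curve = curve
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC %.3f (95%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary")
  factor(labels, levels = c(0, 1))
}

#' DeLong test for two paired AUCs
#'
#' Two-sided test for a difference between the AUCs of two score vectors
#' measured on the same subjects.
#'
#' @param scores_a,scores_b paired score vectors
#' @param labels shared binary labels
#' @return list with `p_value`, `auc_a`, `auc_b`
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) stopf("paired scores differ in length")
  labels <- normalize_labels(labels)
  ra <- pROC::roc(labels, as.numeric(scores_a), levels = c("0", "1"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, as.numeric(scores_b), levels = c("0", "1"),
                  direction = "<", quiet = TRUE)
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    return(list(p_value = 1, auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb))))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(p_value = tst$p.value,
       auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile (exact) interval for a binomial proportion, as used for
#' sensitivity and specificity. The lower bound is 0 when `successes = 0`
#' and the upper bound 1 when `successes = n`.
#'
#' @param successes number of successes (0..n)
#' @param n number of trials (> 0)
#' @param level confidence level (default 0.95)
#' @return named numeric `c(lo, hi)`
#' @export
#' @examples
#' round(clopper_pearson(65, 79) * 100) # the 82% sensitivity interval
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n <= 0) stopf("n must be positive")
  if (successes < 0 || successes > n) stopf("successes must lie in 0..n")
  ci <- stats::binom.test(successes, n, conf.level = level)$conf.int
  c(lo = ci[1], hi = ci[2])
}

#' Two-by-two diagnostic table at a score threshold
#'
#' Dichotomizes the scores at `threshold` (positive when score >= threshold)
#' and reports the 2x2 counts plus sensitivity, specificity, PPV and NPV with
#' Clopper-Pearson intervals.
#'
#' @inheritParams roc_auc
#' @param threshold score threshold
#' @return list with `counts` (tp, fp, tn, fn) and `stats` (data.frame of
#'   estimate, lo, hi per statistic)
#' @export
two_by_two <- function(scores, labels, threshold) {
  labels <- normalize_labels(labels)
  pos <- scores >= threshold
  tp <- sum(pos & labels == "1"); fn <- sum(!pos & labels == "1")
  tn <- sum(!pos & labels == "0"); fp <- sum(pos & labels == "0")
  mk <- function(s, tot) {
    if (tot == 0) return(c(NA, NA, NA))
    c(s / tot, clopper_pearson(s, tot))
  }
  stats <- rbind(
    sensitivity = mk(tp, tp + fn),
    specificity = mk(tn, tn + fp),
    ppv = mk(tp, tp + fp),
    npv = mk(tn, tn + fn)
  )
  colnames(stats) <- c("estimate", "lo", "hi")
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       stats = as.data.frame(stats))
}

#' Score threshold attaining a target sensitivity
#'
#' Operating-point selection on development data: the largest threshold whose
#' sensitivity is at least `target` (so specificity is maximal subject to the
#' sensitivity floor).
#'
#' @inheritParams roc_auc
#' @param target target sensitivity (default 0.82)
#' @return numeric threshold
#' @export
threshold_for_sensitivity <- function(scores, labels, target = 0.82) {
  labels <- normalize_labels(labels)
  pos_scores <- sort(scores[labels == "1"], decreasing = TRUE)
  n1 <- length(pos_scores)
  if (!n1) stopf("no positive subjects")
  k <- ceiling(target * n1)
  unname(pos_scores[min(k, n1)])
}
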