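# Discrimination: ROC points, AUC with DeLong CI, paired AUC comparison,
# sensitivity/specificity/likelihood ratios at a cut-off, Youden-optimal
# cut-off. The event is binary (CVD death within follow-up); positives
# are classified by score >= cutoff.

#' @noRd
check_two_classes <- function(events) {
  e <- as.numeric(events) != 0
  if (all(e) || !any(e))
    stop_validation("both event and non-event subjects are required")
  e
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per distinct score threshold (ties grouped),
#' anchored at (0, 0) and (1, 1).
#'
#' @param scores numeric risk scores.
#' @param events 0/1 event indicators.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing FPR.
#' @export
roc_points <- function(scores, events) {
  e <- check_two_classes(events)
  stopifnot(length(scores) == length(e))
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(e); n0 <- sum(!e)
  tpr <- vapply(thr, function(t) sum(e & scores >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(!e & scores >= t) / n0, 0)
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' AUC (C-statistic) with DeLong confidence interval
#'
#' The AUC equals the Mann-Whitney concordance probability (ties get 1/2
#' credit); the confidence interval uses the DeLong variance estimator.
#'
#' @inheritParams roc_points
#' @param level confidence level.
#' @return list with `auc`, `lo`, `hi`, `level`.
#' @export
auc_ci <- function(scores, events, level = 0.95) {
  e <- check_two_classes(events)
  r <- pROC::roc(response = as.integer(e), predictor = scores,
                 levels = c("0", "1"), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = level, method = "delong"))
  list(auc = ci[2L], lo = ci[1L], hi = ci[3L], level = level)
}

#' Paired DeLong test comparing two AUCs on the same subjects
#'
#' @param scores_a,scores_b risk scores from two models for the same
#'   subjects.
#' @inheritParams roc_points
#' @return two-sided p-value.
#' @export
compare_auc_paired <- function(scores_a, scores_b, events) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(events))
    stop_validation("scores_a, scores_b and events must have equal length")
  e <- check_two_classes(events)
  if (isTRUE(all.equal(scores_a, scores_b))) return(1)
  ra <- pROC::roc(as.integer(e), scores_a, levels = c("0", "1"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(as.integer(e), scores_b, levels = c("0", "1"),
                  direction = "<", quiet = TRUE)
  as.numeric(pROC::roc.test(ra, rb, paired = TRUE, method = "delong")$p.value)
}

#' Sensitivity, specificity and likelihood ratios at a cut-off
#'
#' Subjects with `score >= cutoff` are classified positive. Sensitivity
#' and specificity are reported in percent with Clopper-Pearson 95%
#' intervals; `LR+ = Se/(1-Sp)` and `LR- = (1-Se)/Sp` (infinite when the
#' denominator is zero).
#'
#' @inheritParams roc_points
#' @param cutoff classification threshold (same scale as `scores`).
#' @param level confidence level for the exact binomial intervals.
#' @return list with the 2x2 counts (`tp`, `fp`, `tn`, `fn`),
#'   `sensitivity`/`specificity` (percent) with `se_ci`/`sp_ci`, and
#'   `lr_pos`/`lr_neg`.
#' @export
sens_spec_at <- function(scores, events, cutoff, level = 0.95) {
  if (!is.finite(cutoff)) stop_validation("cutoff must be finite")
  e <- as.numeric(events) != 0
  pos <- scores >= cutoff
  tp <- sum(pos & e); fn <- sum(!pos & e)
  fp <- sum(pos & !e); tn <- sum(!pos & !e)
  ci <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    100 * as.numeric(binom.test(k, n, conf.level = level)$conf.int)
  }
  se <- 100 * tp / max(tp + fn, 1L)
  sp <- 100 * tn / max(tn + fp, 1L)
  list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = se, se_ci = ci(tp, tp + fn),
       specificity = sp, sp_ci = ci(tn, tn + fp),
       lr_pos = if (sp < 100) (se / 100) / (1 - sp / 100) else Inf,
       lr_neg = if (sp > 0) (1 - se / 100) / (sp / 100) else Inf)
}

#' Youden-optimal cut-off
#'
#' Maximizes `J = Se + Sp - 1` over the observed score values; ties are
#' broken by the smallest qualifying cut-off.
#'
#' @inheritParams roc_points
#' @return the selected cut-off (an observed score value).
#' @export
optimal_cutoff <- function(scores, events) {
  e <- check_two_classes(events)
  cand <- sort(unique(scores))
  ord <- order(scores)
  s <- scores[ord]; ev <- e[ord]
  n1 <- sum(ev); n0 <- sum(!ev)
  first <- match(cand, s)
  # cases / controls with score strictly below each candidate
  cum1 <- c(0, cumsum(ev)); cum0 <- c(0, cumsum(!ev))
  cases_lt <- cum1[first]
  ctrls_lt <- cum0[first]
  se <- (n1 - cases_lt) / n1
  sp <- ctrls_lt / n0
  j <- se + sp - 1
  cand[which.max(j)]   # which.max returns the first (smallest) maximizer
}
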