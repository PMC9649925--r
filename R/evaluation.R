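## Model evaluation: AUC by the Mann-Whitney pair-counting estimator with
## DeLong variance and logit-transformed confidence intervals, the DeLong
## test for correlated AUCs, threshold metrics, and decision-curve
## analysis.

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L)
    stop("both classes must be present")
  labels
}

## Per-observation DeLong placements: V10 (positives) and V01 (negatives).
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  ## midrank formulation (ties count 1/2)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- sum(v10) / m
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC by the Mann-Whitney pair-counting estimator (ties count 1/2), with
#' a 95% confidence interval from the DeLong variance on the logit scale
#' (clamped to `[0, 1]`; degenerate at AUC 0 or 1).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary 0/1 outcome vector.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `se`, `n_pos`, `n_neg`, `method`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- check_binary_labels(labels)
  pl <- delong_placements(scores, labels)
  v10 <- if (pl$m > 1) var(pl$v10) else 0
  v01 <- if (pl$n > 1) var(pl$v01) else 0
  v <- v10 / pl$m + v01 / pl$n
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (pl$auc <= 0 || pl$auc >= 1 || se == 0) {
    ci <- c(max(0, pl$auc - z * se), min(1, pl$auc + z * se))
  } else {
    ## delta method on the logit scale keeps the interval inside (0, 1)
    lse <- se / (pl$auc * (1 - pl$auc))
    ci <- plogis(qlogis(pl$auc) + c(-1, 1) * z * lse)
  }
  structure(list(auc = pl$auc, ci_low = ci[1], ci_high = ci[2], se = se,
                 n_pos = pl$m, n_neg = pl$n, method = "delong-logit"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); %d positives / %d negatives\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects,
#' using the DeLong covariance of the paired placement values. Returns the
#' two-sided p-value for the AUC difference. If the estimated variance of
#' the difference is zero (e.g. identical scores) the p-value is defined
#' as 1 with a warning.
#'
#' @param scores_a,scores_b score vectors on identical subjects.
#' @param labels binary 0/1 outcome vector.
#' @return list with `auc_a`, `auc_b`, `difference`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  S <- s10 / pa$m + s01 / pa$n
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (vd <= .Machine$double.eps) {
    warning("zero estimated variance of the AUC difference; p-value defined as 1")
    return(list(auc_a = pa$auc, auc_b = pb$auc, difference = d, z = 0,
                p_value = 1))
  }
  z <- d / sqrt(vd)
  list(auc_a = pa$auc, auc_b = pb$auc, difference = d, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Threshold classification metrics
#'
#' Accuracy, sensitivity and specificity at a score threshold
#' (`score >= threshold` is called positive).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (both classes present).
#' @param threshold decision threshold.
#' @return named list with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- check_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Youden-optimal threshold
#'
#' The candidate score threshold maximising sensitivity + specificity - 1;
#' ties resolve to the lowest threshold. Used to fix the operating point on
#' the training cohort before reading off test-set metrics.
#'
#' @inheritParams confusion_metrics
#' @return numeric threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    cm <- confusion_metrics(scores, labels, t)
    cm$sensitivity + cm$specificity - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Decision-curve analysis
#'
#' Net benefit of a probabilistic model over a grid of threshold
#' probabilities: `NB(t) = TP/N - (FP/N) * t/(1-t)`, against the treat-all
#' strategy (classify everyone positive) and treat-none (identically 0).
#'
#' @param scores predicted probabilities.
#' @param labels binary 0/1 labels.
#' @param grid strictly increasing thresholds inside (0, 1).
#' @return object of class `net_benefit_curve`: data.frame with columns
#'   `threshold`, `nb_model`, `nb_treat_all`, `nb_treat_none`.
#' @export
decision_curve <- function(scores, labels, grid = seq(0.01, 0.60, by = 0.01)) {
  labels <- check_binary_labels(labels)
  if (any(grid <= 0 | grid >= 1)) stop("grid thresholds must lie strictly inside (0, 1)")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  N <- length(labels)
  prev <- mean(labels)
  nb_model <- vapply(grid, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    tp / N - (fp / N) * t / (1 - t)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  structure(data.frame(threshold = grid, nb_model = nb_model,
                       nb_treat_all = nb_all, nb_treat_none = 0),
            class = c("net_benefit_curve", "data.frame"))
}
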