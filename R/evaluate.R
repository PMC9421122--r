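#' Stratified k-fold plan
#'
#' Partitions the records into `k` test folds while keeping the class
#' proportion of every fold within one sample of the global proportion.
#' The plan is deterministic in `seed` and is built once per experiment,
#' then shared by every arm.
#'
#' @param manifest a tibble with columns `record_id` and `label`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return a tibble `record_id`, `label`, `fold` with attributes `k`, `seed`
#'   and `fold_hash` (a stable hash of the fold membership).
#' @export
stratified_folds <- function(manifest, k = 5L, seed = 1L) {
  counts <- table(manifest$label)
  if (any(counts < k)) {
    abort(sprintf("every class needs at least k = %d members.", k),
          class = "pcgaug_config_error")
  }
  assign_class <- function(ids, class_seed) {
    ids <- with_seed(class_seed, sample(ids))
    tibble(record_id = ids, fold = rep_len(seq_len(k), length(ids)))
  }
  plan <- bind_rows(
    lapply(sort(unique(manifest$label)), function(cl) {
      ids <- manifest$record_id[manifest$label == cl]
      assign_class(ids, derive_seed(seed, cl)) %>% mutate(label = cl)
    })
  ) %>%
    select("record_id", "label", "fold") %>%
    arrange(.data$record_id)
  attr(plan, "k") <- as.integer(k)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "fold_hash") <- fold_hash(plan)
  plan
}

#' @rdname stratified_folds
#' @param plan a fold plan.
#' @return `fold_hash()`: a hash of the test-fold membership, identical
#'   if and only if the folds are identical.
#' @export
fold_hash <- function(plan) {
  rlang::hash(lapply(seq_len(max(plan$fold)), function(j) {
    sort(plan$record_id[plan$fold == j])
  }))
}

#' ROC and precision-recall curves
#'
#' Enumerates every distinct score threshold (predict positive when
#' `score >= threshold`), builds the ROC curve and computes its AUC by the
#' trapezoid rule (equal to the pairwise concordance statistic with ties
#' counted half), and builds the precision-recall curve with area by the
#' standard step interpolation \eqn{\sum_i (R_i - R_{i-1}) P_i}.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return a list of class `pcg_roc_pr`: `roc` (tibble `threshold`, `fpr`,
#'   `tpr`), `pr` (tibble `threshold`, `recall`, `precision`), `roc_auc`,
#'   `pr_auc`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) {
    abort("both classes must be present.", class = "pcgaug_degenerate_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cum_tp <- cumsum(y == 1)
  cum_fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  thr <- s[last]
  roc <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / neg),
    tpr = c(0, tp / pos)
  )
  roc_auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  recall <- tp / pos
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  structure(
    list(
      roc = roc,
      pr = tibble(threshold = thr, recall = recall, precision = precision),
      roc_auc = roc_auc, pr_auc = pr_auc
    ),
    class = "pcg_roc_pr"
  )
}

#' Specificity at a fixed sensitivity
#'
#' Scans every distinct score threshold and returns the specificity at the
#' operating point whose sensitivity is the smallest value still at or
#' above `target` (the largest qualifying threshold; no interpolation).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @param target sensitivity target (default 0.90).
#' @return a list with `specificity`, `sensitivity` and `threshold`.
#' @export
specificity_at_sensitivity <- function(scores, labels, target = 0.90) {
  labels <- as.integer(labels)
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) {
    abort("both classes must be present.", class = "pcgaug_degenerate_error")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / neg, numeric(1))
  ok <- which(sens >= target)
  if (length(ok) == 0) {
    abort("target sensitivity unreachable.", class = "pcgaug_degenerate_error")
  }
  i <- ok[1]  # largest threshold with sensitivity >= target
  list(specificity = spec[i], sensitivity = sens[i], threshold = thr[i])
}

#' Confusion matrix, accuracy and F1
#'
#' Thresholds the scores (positive when `score >= threshold`), tabulates
#' the confusion matrix, and computes accuracy and the F1 score of the
#' abnormal (positive) class. A zero denominator in precision or recall
#' yields F1 = 0 with a warning.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return a list with `confusion` (2 x 2 matrix, rows = truth), `accuracy`,
#'   `precision`, `recall`, `sensitivity`, `specificity`, `f1`.
#' @export
confusion_f1 <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  cm <- table(
    truth = factor(labels, levels = c(0, 1)),
    predicted = factor(pred, levels = c(0, 1))
  )
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(truth = c("0", "1"), predicted = c("0", "1")))
  tp <- cm["1", "1"]; fp <- cm["0", "1"]; fn <- cm["1", "0"]; tn <- cm["0", "0"]
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    warn("no predicted positives (or degenerate precision/recall); F1 set to 0.")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(
    confusion = cm,
    accuracy = (tp + tn) / sum(cm),
    precision = precision, recall = recall,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    f1 = f1
  )
}

#' Paired mean difference with a 95% confidence interval
#'
#' For fold-matched metric vectors of an arm and the baseline, computes the
#' per-fold differences, their mean, and the paired t interval
#' \eqn{\bar d \pm t_{0.975, k-1} \, s_d / \sqrt{k}}. An arm is called
#' significantly different from baseline exactly when the interval excludes
#' zero (the CI-zero rule).
#'
#' @param arm_metric,baseline_metric equal-length numeric vectors in
#'   matched fold order (k >= 2).
#' @param conf confidence level (default 0.95).
#' @return a tibble with `estimate`, `conf.low`, `conf.high`, `significant`.
#' @export
paired_mean_difference_ci <- function(arm_metric, baseline_metric, conf = 0.95) {
  k <- length(arm_metric)
  if (length(baseline_metric) != k) {
    config_error("fold counts must match (fold-paired comparison).")
  }
  if (k < 2) config_error("at least two folds are required for a CI.")
  d <- arm_metric - baseline_metric
  m <- mean(d)
  half <- qt(1 - (1 - conf) / 2, k - 1) * sd(d) / sqrt(k)
  tibble(
    estimate = m, conf.low = m - half, conf.high = m + half,
    significant = (m - half) > 0 | (m + half) < 0
  )
}

# Mean and 95% t interval across folds, used for per-arm metric summaries.
mean_ci <- function(x, conf = 0.95) {
  k <- length(x)
  half <- if (k > 1) qt(1 - (1 - conf) / 2, k - 1) * sd(x) / sqrt(k) else 0
  c(mean = mean(x), lo = mean(x) - half, hi = mean(x) + half)
}

#' Per-fold test metrics for one arm
#'
#' @param scores,labels test-fold scores and labels.
#' @param sens_target sensitivity target for the specificity metric.
#' @param threshold decision threshold for accuracy/F1.
#' @return a one-row tibble: `accuracy`, `sensitivity`, `specificity_at_sens`,
#'   `roc_auc`, `pr_auc`, `f1`, plus confusion counts `tn`, `fp`, `fn`, `tp`.
#' @export
fold_metrics <- function(scores, labels, sens_target = 0.90, threshold = 0.5) {
  curves <- roc_pr_curves(scores, labels)
  sp <- specificity_at_sensitivity(scores, labels, sens_target)
  cf <- suppressWarnings(confusion_f1(scores, labels, threshold))
  tibble(
    accuracy = cf$accuracy,
    sensitivity = sp$sensitivity,
    specificity_at_sens = sp$specificity,
    roc_auc = curves$roc_auc,
    pr_auc = curves$pr_auc,
    f1 = cf$f1,
    tn = cf$confusion["0", "0"], fp = cf$confusion["0", "1"],
    fn = cf$confusion["1", "0"], tp = cf$confusion["1", "1"]
  )
}
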