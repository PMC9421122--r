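test_that("stratified folds partition with balanced class proportions", {
  manifest <- tibble::tibble(
    record_id = sprintf("r%02d", 1:20),
    label = c(rep(0L, 15), rep(1L, 5))
  )
  plan <- stratified_folds(manifest, k = 5, seed = 1)
  expect_setequal(plan$record_id, manifest$record_id)
  tab <- table(plan$fold, plan$label)
  expect_true(all(tab[, "0"] == 3))
  expect_true(all(tab[, "1"] == 1))
  # determinism and seed sensitivity
  expect_identical(stratified_folds(manifest, 5, 1), plan)
  expect_false(identical(stratified_folds(manifest, 5, 2)$fold, plan$fold))
  expect_identical(attr(plan, "fold_hash"),
                   attr(stratified_folds(manifest, 5, 1), "fold_hash"))
  expect_error(stratified_folds(manifest, 6, 1), class = "pcgaug_config_error")
})

test_that("ROC AUC equals the concordance statistic and printed examples", {
  r <- roc_pr_curves(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(r$roc_auc, 0.75)
  perfect <- roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$roc_auc, 1.0)
  expect_equal(perfect$pr_auc, 1.0)
  anti <- roc_pr_curves(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_equal(anti$roc_auc, 0.0)
  # oracle equivalence on random toy sets, including ties
  for (i in 1:30) {
    withr::with_seed(i, {
      n <- sample(6:25, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
    })
    expect_equal(roc_pr_curves(scores, labels)$roc_auc,
                 concordance_auc(scores, labels))
  }
  expect_error(roc_pr_curves(c(0.1, 0.9), c(1, 1)),
               class = "pcgaug_degenerate_error")
})

test_that("ROC AUC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  for (i in 1:5) {
    withr::with_seed(100 + i, {
      labels <- c(0, 1, sample(0:1, 30, replace = TRUE))
      scores <- round(runif(32), 2)
    })
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_pr_curves(scores, labels)$roc_auc, ref, tolerance = 1e-12)
  }
})

test_that("specificity at 90% sensitivity matches exhaustive enumeration", {
  perfect <- specificity_at_sensitivity(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$specificity, 1.0)
  tied <- specificity_at_sensitivity(rep(0.4, 6), c(1, 1, 0, 0, 0, 1))
  expect_equal(tied$specificity, 0.0)
  expect_equal(tied$sensitivity, 1.0)
  for (i in 1:20) {
    withr::with_seed(200 + i, {
      labels <- c(0, 1, sample(0:1, 10, replace = TRUE))
      scores <- round(runif(12), 1)
    })
    got <- specificity_at_sensitivity(scores, labels, 0.9)
    expect_equal(got$specificity, spec_at_sens_oracle(scores, labels, 0.9))
    expect_gte(got$sensitivity, 0.9)
  }
})

test_that("confusion matrix, accuracy and F1 follow their formulas", {
  all_correct <- confusion_f1(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(as.vector(all_correct$confusion), c(2L, 0L, 0L, 2L))
  expect_equal(all_correct$f1, 1)
  expect_equal(all_correct$accuracy, 1)
  # TP=8, FP=2, FN=2, TN=8
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  labels <- c(rep(1, 10), rep(0, 10))
  got <- confusion_f1(scores, labels)
  expect_equal(got$precision, 0.8)
  expect_equal(got$recall, 0.8)
  expect_equal(got$f1, 0.8)
  expect_equal(got$accuracy, 0.8)
  expect_equal(sum(got$confusion), 20)
  expect_warning(none <- confusion_f1(c(0.1, 0.2), c(1, 0)), "F1")
  expect_equal(none$f1, 0)
})

test_that("paired mean-difference CIs follow the t construction", {
  same <- paired_mean_difference_ci(c(0.8, 0.9, 0.7), c(0.8, 0.9, 0.7))
  expect_equal(same$estimate, 0)
  expect_equal(same$conf.low, 0)
  expect_equal(same$conf.high, 0)
  expect_false(same$significant)
  const <- paired_mean_difference_ci(c(0.8, 0.9, 0.7), c(0.75, 0.85, 0.65))
  expect_equal(const$estimate, 0.05)
  expect_equal(const$conf.low, 0.05)
  expect_equal(const$conf.high, 0.05)
  expect_true(const$significant)
  # hand-computed example: d = (0.01, 0.03, 0.02, 0.04, 0.05)
  d <- c(0.01, 0.03, 0.02, 0.04, 0.05)
  got <- paired_mean_difference_ci(d, rep(0, 5))
  half <- stats::qt(0.975, 4) * stats::sd(d) / sqrt(5)
  expect_equal(got$estimate, 0.03)
  expect_equal(got$conf.high - got$estimate, half)
  expect_equal(got$conf.high, 0.03 + 2.776445 * 0.0158114 / sqrt(5), tolerance = 1e-4)
  expect_error(paired_mean_difference_ci(1, 1), class = "pcgaug_config_error")
  expect_error(paired_mean_difference_ci(1:3, 1:2), class = "pcgaug_config_error")
})
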