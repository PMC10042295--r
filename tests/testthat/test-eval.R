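test_that("majority undersampling is seeded, uniform and size-checked", {
  ids <- sprintf("p%04d", 1:9457)
  s <- undersample_majority(ids, 291, seed = 3)
  expect_length(s, 291)
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s %in% ids))
  expect_identical(s, undersample_majority(ids, 291, seed = 3))
  expect_false(identical(undersample_majority(ids[1:1000], 100, seed = 1),
                         undersample_majority(ids[1:1000], 100, seed = 2)))
  expect_setequal(undersample_majority(ids[1:50], 50, seed = 1), ids[1:50])
  expect_error(undersample_majority(ids[1:10], 11, seed = 1),
               class = "ecg2img_sampling_error")
})

test_that("fold dealing is balanced and the rotation covers every patient", {
  ids <- sprintf("p%03d", 1:582)
  folds <- make_folds(ids, k = 10, seed = 5)
  sizes <- as.integer(table(folds$group_of))
  expect_equal(sort(sizes), c(rep(58L, 8), rep(59L, 2)))
  tested <- character()
  for (f in 0:9) {
    mem <- fold_members(folds, f)
    expect_length(intersect(mem$train, mem$validation), 0)
    expect_length(intersect(mem$train, mem$test), 0)
    expect_length(intersect(mem$validation, mem$test), 0)
    expect_equal(length(mem$train) + length(mem$validation) +
                   length(mem$test), 582)
    tested <- c(tested, mem$test)
  }
  expect_setequal(tested, ids)
  expect_equal(length(tested), 582)        # exactly once each
  expect_error(make_folds(ids, k = 2), class = "ecg2img_protocol_error")
  expect_error(make_folds(ids[1:5], k = 10),
               class = "ecg2img_protocol_error")
})

test_that("patient aggregation averages and thresholds with positive ties", {
  r <- aggregate_patient(c(0.2, 0.4, 0.6))
  expect_equal(r$aggregated_prob, 0.4)
  expect_equal(r$predicted_label, 0L)
  r2 <- aggregate_patient(c(1, 1, 1))
  expect_equal(r2$aggregated_prob, 1)
  expect_equal(r2$predicted_label, 1L)
  r3 <- aggregate_patient(c(0.5, 0.5, 0.5), threshold = 0.5)
  expect_equal(r3$predicted_label, 1L)     # ties classify as positive
  # order of the three per-image probabilities is irrelevant
  set.seed(13)
  for (rep in 1:10) {
    p <- stats::runif(3)
    r_a <- aggregate_patient(p)
    r_b <- aggregate_patient(sample(p))
    expect_equal(r_a$aggregated_prob, r_b$aggregated_prob)
    expect_equal(r_a$predicted_label, r_b$predicted_label)
  }
  expect_error(aggregate_patient(c(0.1, 0.2)), class = "ecg2img_shape_error")
})

test_that("confusion rates match a hand-built matrix and brute force", {
  # 44 TP, 14 FN, 46 TN, 12 FP
  truth <- c(rep(1, 58), rep(0, 58))
  pred <- c(rep(1, 44), rep(0, 14), rep(0, 46), rep(1, 12))
  rep1 <- confusion_and_rates(data.frame(predicted_label = pred,
                                         true_label = truth))
  expect_equal(rep1$tp, 44); expect_equal(rep1$fn, 14)
  expect_equal(rep1$tn, 46); expect_equal(rep1$fp, 12)
  expect_equal(rep1$sensitivity, 44 / 58 * 100, tolerance = 1e-12)
  expect_equal(rep1$specificity, 46 / 58 * 100, tolerance = 1e-12)
  expect_equal(rep1$accuracy, 90 / 116 * 100, tolerance = 1e-12)
  expect_equal(round(rep1$sensitivity, 2), 75.86)
  expect_equal(round(rep1$specificity, 2), 79.31)
  expect_equal(round(rep1$accuracy, 2), 77.59)

  perfect <- confusion_and_rates(data.frame(predicted_label = truth,
                                            true_label = truth))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(100, 100, 100))

  # random prediction sets against the counting oracle
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:60, 1)
    truth <- stats::rbinom(n, 1, 0.5)
    pred <- stats::rbinom(n, 1, 0.5)
    mine <- confusion_and_rates(data.frame(predicted_label = pred,
                                           true_label = truth))
    orc <- oracle_confusion(pred, truth)
    expect_equal(mine$tp + mine$tn + mine$fp + mine$fn, n)
    expect_equal(mine$tp, orc$tp)
    expect_equal(mine$sensitivity, orc$sens)
    expect_equal(mine$specificity, orc$spec)
    expect_equal(mine$accuracy, orc$acc)
  }
})

test_that("undefined rates are flagged, never silently zero", {
  rep0 <- confusion_and_rates(data.frame(predicted_label = c(0, 1),
                                         true_label = c(0, 0)))
  expect_true(is.na(rep0$sensitivity))
  expect_true("sensitivity" %in% rep0$undefined)
  expect_false(is.na(rep0$specificity))
})

test_that("ROC sweep equals the pairwise Mann-Whitney statistic", {
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    scores <- stats::runif(n)
    if (rep %% 3 == 0)                  # force ties in a third of the cases
      scores <- round(scores, 1)
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc_pairwise(scores, labels),
                 tolerance = 1e-12)
    expect_equal(unlist(r$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    # AUC is invariant under strictly increasing transforms
    expect_equal(roc_auc(exp(3 * scores), labels)$auc, r$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)),
               class = "ecg2img_undefined_metric_error")
})

test_that("ROC/AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- stats::runif(40)
  labels <- stats::rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  mine <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("cross-validation tests each patient once and pools correctly", {
  ds <- toy_image_dataset(10, size = 32, seed = 19)   # 20 patients
  cfg <- train_config(seed = 2, epochs = 1, freeze_backbone = FALSE)
  cv <- run_cross_validation(
    ds, cfg, k = 10, seed = 7,
    model_builder = function(c)
      build_classifier("tiny2d", c, input_shape = c(32, 32, 1)))
  expect_length(cv$per_fold, 10)
  n_tested <- sum(vapply(cv$per_fold, function(r) r$tp + r$tn + r$fp + r$fn,
                         numeric(1)))
  expect_equal(n_tested, 20)
  pooled_n <- cv$pooled$tp + cv$pooled$tn + cv$pooled$fp + cv$pooled$fn
  expect_equal(pooled_n, 20)
  accs <- vapply(cv$per_fold, `[[`, numeric(1), "accuracy")
  expect_equal(unname(cv$mean_metrics["accuracy"]), mean(accs))
})

test_that("a deliberately leaked patient aborts the protocol", {
  ds <- toy_image_dataset(6, size = 32, seed = 29)
  ids <- unique(vapply(ds$items, `[[`, character(1), "patient_id"))
  folds <- make_folds(ids, k = 3, seed = 1)
  # corrupt: first patient also appears in another group
  bad <- folds
  dup <- names(bad$group_of)[1]
  bad$group_of <- c(bad$group_of, stats::setNames(2L, dup))
  expect_error(
    run_cross_validation(ds, train_config(seed = 1, epochs = 1), k = 3,
                         folds = bad),
    class = "ecg2img_leakage_error")
  # an assignment over a different cohort is rejected too
  other <- make_folds(sprintf("zz%d", 1:12), k = 3, seed = 1)
  expect_error(
    run_cross_validation(ds, train_config(seed = 1, epochs = 1), k = 3,
                         folds = other),
    class = "ecg2img_leakage_error")
})
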