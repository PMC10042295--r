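# Patient-level aggregation, cohort balancing, the 10-fold 7/2/1
# cross-validation protocol, and confusion/ROC metrics.

#' Undersample the majority class
#'
#' Uniform random sample without replacement from the majority-class patient
#' ids, of the minority-class size, so the two outcome groups are balanced
#' before training (the imbalance-control step applied to the survivor
#' group). Deterministic per seed.
#'
#' @param ids_major Character vector of majority-class patient ids.
#' @param n_minor Number of ids to keep (the minority-class size).
#' @param seed Integer seed.
#' @return Character vector of `n_minor` distinct ids.
#' @export
undersample_majority <- function(ids_major, n_minor, seed) {
  if (n_minor > length(ids_major))
    ecg_abort(sprintf("cannot sample %d from %d majority id(s)",
                      n_minor, length(ids_major)), "sampling")
  with_seed(seed, sample(ids_major, n_minor))
}

#' Deal patients into k cross-validation groups
#'
#' Shuffles the patient ids and deals them into `k` groups whose sizes
#' differ by at most one (earlier groups take the extras). The role schedule
#' rotates: fold `f` tests on group `f`, validates on the two cyclically
#' following groups, and trains on the remaining `k - 3`; every group is the
#' test group exactly once across the `k` folds. All roles are at patient
#' level, so a patient's segment images always travel together.
#'
#' @param patient_ids Character vector of distinct patient ids.
#' @param k Number of groups (default 10; at least 3, because each fold
#'   needs disjoint train/validation/test roles).
#' @param seed Integer seed for the shuffle.
#' @return An object of class `ecg_fold_assignment` with `k`, `group_of`
#'   (named integer vector, 0-based group index) and `role_schedule`.
#' @export
make_folds <- function(patient_ids, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 3L)
    ecg_abort("k must be >= 3: each fold needs train, validation and test groups",
              "protocol")
  assert_that(!anyDuplicated(patient_ids),
              "patient ids must be distinct", "protocol")
  n <- length(patient_ids)
  assert_that(n >= k, sprintf("need at least %d patients for %d groups", k, k),
              "protocol")
  shuffled <- with_seed(seed, sample(patient_ids))
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  group_of <- rep(seq_len(k) - 1L, times = sizes)
  names(group_of) <- shuffled
  schedule <- lapply(seq_len(k) - 1L, function(f) {
    val <- c((f + 1L) %% k, (f + 2L) %% k)
    list(test = f, validation = val,
         train = setdiff(seq_len(k) - 1L, c(f, val)))
  })
  structure(list(k = k, group_of = group_of, role_schedule = schedule),
            class = "ecg_fold_assignment")
}

#' Patient ids holding each role in one fold
#'
#' @param folds An `ecg_fold_assignment`.
#' @param fold 0-based fold index.
#' @return List with character vectors `train`, `validation`, `test`.
#' @export
fold_members <- function(folds, fold) {
  sch <- folds$role_schedule[[fold + 1L]]
  ids <- names(folds$group_of)
  list(train = ids[folds$group_of %in% sch$train],
       validation = ids[folds$group_of %in% sch$validation],
       test = ids[folds$group_of == sch$test])
}

# integrity check used by the protocol driver: every cohort patient in
# exactly one group, no strays
validate_folds <- function(folds, patient_ids) {
  ids <- names(folds$group_of)
  if (anyDuplicated(ids))
    ecg_abort(paste0("patient assigned to more than one group: ",
                     ids[duplicated(ids)][1L]), "leakage")
  if (!setequal(ids, patient_ids))
    ecg_abort("fold assignment does not cover the cohort exactly", "leakage")
  invisible(TRUE)
}

#' Aggregate per-image probabilities to one patient-level prediction
#'
#' The patient-level death probability is the arithmetic mean of the
#' per-image probabilities; the predicted label is 1 (non-survivor) when the
#' mean reaches the threshold (ties classify as positive).
#'
#' @param per_image_probs Numeric vector of per-image death probabilities in
#'   `[0, 1]`; length must equal `n_segments`.
#' @param threshold Decision threshold (default 0.5).
#' @param patient_id,true_label Optional metadata carried through.
#' @param n_segments Expected number of per-image probabilities (default 3).
#' @return An `ecg_prediction_result`: list with `patient_id`,
#'   `per_image_probs`, `aggregated_prob`, `predicted_label`, `true_label`.
#' @export
aggregate_patient <- function(per_image_probs, threshold = 0.5,
                              patient_id = NA_character_, true_label = NA,
                              n_segments = 3L) {
  assert_that(length(per_image_probs) == n_segments,
              sprintf("expected %d per-image probabilities, got %d",
                      n_segments, length(per_image_probs)), "shape")
  assert_that(all(per_image_probs >= 0 & per_image_probs <= 1),
              "probabilities must lie in [0, 1]", "parse")
  agg <- mean(per_image_probs)
  structure(list(patient_id = patient_id,
                 per_image_probs = as.numeric(per_image_probs),
                 aggregated_prob = agg,
                 predicted_label = as.integer(agg >= threshold),
                 true_label = if (is.na(true_label)) NA_integer_
                              else as.integer(true_label)),
            class = "ecg_prediction_result")
}

#' Aggregate a per-image prediction table to patient level
#'
#' @param pred Data frame from [predict_dataset()] (`patient_id`, `prob`,
#'   `label`).
#' @param threshold Decision threshold.
#' @return List of `ecg_prediction_result`, one per patient.
#' @export
aggregate_predictions <- function(pred, threshold = 0.5) {
  split_idx <- split(seq_len(nrow(pred)), pred$patient_id)
  lapply(names(split_idx), function(pid) {
    rows <- split_idx[[pid]]
    aggregate_patient(pred$prob[rows], threshold = threshold,
                      patient_id = pid,
                      true_label = pred$label[rows][1L],
                      n_segments = length(rows))
  })
}

#' Confusion counts and rates
#'
#' Counts true/false positives and negatives over patient-level predictions
#' (positive class = non-survivor) and computes, in percent:
#' sensitivity = TPs/(TPs+FNs)*100, specificity = TNs/(FPs+TNs)*100,
#' accuracy = (TPs+TNs)/(TPs+TNs+FPs+FNs)*100. A rate whose denominator is
#' zero is reported as `NA` and listed in the `undefined` field, never as a
#' silent zero.
#'
#' @param results List of `ecg_prediction_result`, or a data frame with
#'   columns `predicted_label` and `true_label`.
#' @return An `ecg_metrics_report`: list with `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy` (percent) and `undefined`.
#' @export
confusion_and_rates <- function(results) {
  if (is.data.frame(results)) {
    pred <- results$predicted_label
    truth <- results$true_label
  } else {
    assert_that(length(results) >= 1L, "no predictions to score",
                "empty_input")
    pred <- vapply(results, `[[`, numeric(1), "predicted_label")
    truth <- vapply(results, `[[`, numeric(1), "true_label")
  }
  assert_that(length(pred) >= 1L, "no predictions to score", "empty_input")
  assert_that(all(pred %in% 0:1) && all(truth %in% 0:1),
              "labels must be binary 0/1", "parse")
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  undefined <- character()
  sens <- if (tp + fn > 0) tp / (tp + fn) * 100 else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (fp + tn > 0) tn / (fp + tn) * 100 else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  acc <- (tp + tn) / (tp + tn + fp + fn) * 100
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 undefined = undefined),
            class = "ecg_metrics_report")
}

#' @export
print.ecg_metrics_report <- function(x, ...) {
  cat(sprintf("<ecg_metrics_report> TP=%d TN=%d FP=%d FN=%d | sens %.2f%% spec %.2f%% acc %.2f%%%s\n",
              x$tp, x$tn, x$fp, x$fn, x$sensitivity, x$specificity,
              x$accuracy,
              if (!is.null(x$auc)) sprintf(" | AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision cutoff over all distinct scores (predict positive
#' when score >= cutoff), recording (false-positive rate, sensitivity)
#' points from (0, 0) to (1, 1); tied scores collapse into a single step.
#' The AUC is the trapezoidal area under this curve, which equals the
#' Mann-Whitney pairwise statistic P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param scores Numeric scores (higher = more non-survivor-like).
#' @param labels Binary labels (1 = non-survivor); both classes must be
#'   present, otherwise the AUC is undefined and an error is raised.
#' @return List with `roc_points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "length mismatch", "shape")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    ecg_abort("AUC undefined: both classes must be present",
              "undefined_metric")
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- vapply(cuts, function(ct) {
    pred <- scores >= ct
    c(fpr = sum(pred & labels == 0L) / n_neg,
      tpr = sum(pred & labels == 1L) / n_pos)
  }, numeric(2))
  roc <- data.frame(fpr = pts["fpr", ], tpr = pts["tpr", ])
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc_points = roc, auc = auc)
}

#' Full metrics report for patient-level predictions
#'
#' Confusion counts and rates plus the ROC curve and AUC over the
#' aggregated probabilities.
#'
#' @param results List of `ecg_prediction_result`.
#' @return An `ecg_metrics_report` including `roc_points` and `auc`.
#' @export
metrics_report <- function(results) {
  rep <- confusion_and_rates(results)
  probs <- vapply(results, `[[`, numeric(1), "aggregated_prob")
  truth <- vapply(results, `[[`, numeric(1), "true_label")
  rc <- tryCatch(roc_auc(probs, truth),
                 ecg2img_undefined_metric_error = function(e) NULL)
  if (is.null(rc)) {            # single-class result set (e.g. a tiny fold)
    rep$roc_points <- NULL
    rep$auc <- NA_real_
    rep$undefined <- c(rep$undefined, "auc")
  } else {
    rep$roc_points <- rc$roc_points
    rep$auc <- rc$auc
  }
  rep
}

#' Run the k-fold cross-validation protocol
#'
#' For each fold: a fresh model is built (parameters re-initialised per
#' fold), trained on the 7 training groups with the 2 validation groups
#' monitored, and scored on the held-out test group after patient-level
#' aggregation. Every patient is tested exactly once across the k folds.
#' Any patient appearing in two roles raises a leakage error.
#'
#' @param dataset An `ecg_image_dataset` (or lead dataset for the 1-D
#'   baseline).
#' @param config An `ecg_train_config`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the group dealing; per-fold model seeds derive from
#'   `config$seed` + fold index.
#' @param folds Optional precomputed `ecg_fold_assignment` (validated
#'   against the cohort before any training).
#' @param model_builder Function `(config) -> ecg_model` building the
#'   per-fold model; defaults to the tiny2d classifier.
#' @return List with `folds`, `per_fold` (list of `ecg_metrics_report`),
#'   `mean_metrics` (mean of per-fold sensitivity/specificity/accuracy/AUC)
#'   and `pooled` (metrics over all test predictions pooled).
#' @export
run_cross_validation <- function(dataset, config = train_config(), k = 10L,
                                 seed = 1L, folds = NULL,
                                 model_builder = NULL) {
  ids <- dataset_patients(dataset)
  if (is.null(folds)) folds <- make_folds(ids, k = k, seed = seed)
  validate_folds(folds, ids)
  if (is.null(model_builder))
    model_builder <- function(cfg) build_classifier("tiny2d", cfg)
  per_fold <- vector("list", folds$k)
  pooled_results <- list()
  for (f in seq_len(folds$k) - 1L) {
    mem <- fold_members(folds, f)
    if (length(intersect(mem$train, mem$test)) ||
        length(intersect(mem$train, mem$validation)) ||
        length(intersect(mem$validation, mem$test)))
      ecg_abort(sprintf("fold %d: overlapping roles", f), "leakage")
    cfg <- config
    cfg$seed <- config$seed + f
    model <- model_builder(cfg)
    fit <- train(model, dataset_subset(dataset, mem$train),
                 dataset_subset(dataset, mem$validation), cfg)
    pred <- predict_dataset(fit$model, dataset_subset(dataset, mem$test))
    res <- aggregate_predictions(pred, threshold = config$threshold)
    per_fold[[f + 1L]] <- metrics_report(res)
    pooled_results <- c(pooled_results, res)
  }
  mean_of <- function(field)
    mean(vapply(per_fold, function(r) r[[field]], numeric(1)), na.rm = TRUE)
  list(folds = folds, per_fold = per_fold,
       mean_metrics = c(sensitivity = mean_of("sensitivity"),
                        specificity = mean_of("specificity"),
                        accuracy = mean_of("accuracy"),
                        auc = mean_of("auc")),
       pooled = metrics_report(pooled_results))
}
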