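# End-to-end conveniences: cohort encoding and the single-split holdout
# experiment used for desk-scale validation of the whole pipeline.

#' Encode a cohort of waveform records as image panels
#'
#' Selects the four-lead panel from each record (deriving aVR where absent)
#' and encodes it into segment images.
#'
#' @param records List of `ecg_waveform_record`.
#' @param config An `ecg_render_config`.
#' @return List of `ecg_image_panel`.
#' @export
encode_cohort <- function(records, config = render_config()) {
  lapply(records, function(rec) encode_patient(select_panel(rec), config))
}

#' Single train/validation/test holdout experiment
#'
#' The ten-group dealing of [make_folds()] evaluated on its first fold only:
#' seven groups train, two validate, one is held out for testing — a
#' desk-scale single split with the same 7/2/1 role proportions as the full
#' cross-validation. The model is trained with [train()], test patients are
#' scored by per-image prediction and patient-level mean aggregation, and a
#' full metrics report (confusion rates, ROC, AUC) is returned.
#'
#' @param dataset An `ecg_image_dataset`.
#' @param config An `ecg_train_config`; `config$seed` drives the group
#'   dealing, model initialisation and training shuffles.
#' @param model_builder Function `(config) -> ecg_model`; defaults to the
#'   tiny2d classifier trained end-to-end (`freeze_backbone = FALSE`),
#'   appropriate for a backbone with no pretrained weights.
#' @return List with `model`, `history`, `split` (patient ids per role),
#'   `predictions` (patient-level results on the test set) and `report`
#'   (an `ecg_metrics_report`).
#' @export
run_holdout_experiment <- function(dataset, config = train_config(),
                                   model_builder = NULL) {
  if (is.null(model_builder)) {
    model_builder <- function(cfg) {
      cfg$freeze_backbone <- FALSE
      build_classifier("tiny2d", cfg)
    }
  }
  ids <- dataset_patients(dataset)
  folds <- make_folds(ids, k = 10L, seed = config$seed)
  mem <- fold_members(folds, 0L)
  model <- model_builder(config)
  fit <- train(model, dataset_subset(dataset, mem$train),
               dataset_subset(dataset, mem$validation), config)
  pred <- predict_dataset(fit$model, dataset_subset(dataset, mem$test))
  results <- aggregate_predictions(pred, threshold = config$threshold)
  list(model = fit$model, history = fit$history, split = mem,
       predictions = results, report = metrics_report(results))
}
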