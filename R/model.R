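# Classifier harness: transfer-learning head replacement over a pluggable
# backbone, a built-in small 2-D CNN for desk-scale work, a four-branch 1-D
# baseline, and the training loop.

#' Training configuration
#'
#' Hyperparameters of the classifier harness. The clinical-scale regime in
#' the underlying protocol is a learning rate of 1e-6 over 50 epochs with
#' batch size 8 on GPU-backed ImageNet backbones; the defaults here are the
#' desk-scale regime for the built-in backbone (Adam at 1e-3, 10 epochs),
#' with batch size kept at 8.
#'
#' @param learning_rate Positive step size (default 1e-3).
#' @param epochs Number of training epochs (default 10).
#' @param batch_size Mini-batch size (default 8).
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param freeze_backbone If `TRUE` (default), only the replaced head layers
#'   receive updates; backbone parameters stay fixed.
#' @param head_hidden_units Width of the head's hidden layer (default 256).
#' @param threshold Decision threshold on the aggregated death probability
#'   (default 0.5); ties classify as positive.
#' @return An object of class `ecg_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 10L, batch_size = 8L,
                         seed = 1L, freeze_backbone = TRUE,
                         head_hidden_units = 256L, threshold = 0.5) {
  assert_that(learning_rate > 0, "learning_rate must be positive", "config")
  assert_that(epochs >= 1L, "epochs must be >= 1", "config")
  assert_that(batch_size >= 1L, "batch_size must be >= 1", "config")
  assert_that(threshold > 0 && threshold < 1,
              "threshold must lie in (0, 1)", "config")
  structure(list(learning_rate = as.numeric(learning_rate),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 freeze_backbone = isTRUE(freeze_backbone),
                 head_hidden_units = as.integer(head_hidden_units),
                 threshold = as.numeric(threshold)),
            class = "ecg_train_config")
}

# track a (H, W, C) shape through a conv/pool stack
stack_out_shape <- function(layers) layers[[length(layers)]]$out_shape

#' Build a binary image classifier with a replaced head
#'
#' Constructs a backbone plus a fresh two-layer classification head: global
#' average pooling over the backbone's final feature maps, a hidden fully
#' connected ReLU layer of `head_hidden_units`, and a two-way output whose
#' scores are softmax-normalised. With `freeze_backbone` only the two head
#' layers are trainable — the transfer-learning scheme of replacing the
#' layers beyond the final convolution and training only the coupled layers.
#'
#' The built-in `"tiny2d"` backbone is a three-block conv/max-pool network
#' (8, 16, 32 filters of 3x3) sized for 224x224 grayscale input and CPU
#' training; no pretrained weights are required or downloaded.
#'
#' @param backbone Backbone identifier; `"tiny2d"` is built in.
#' @param config An `ecg_train_config`; `config$seed` fixes initialisation.
#' @param input_shape Input `(height, width, channels)`
#'   (default `c(224, 224, 1)`).
#' @return An object of class `ecg_model`.
#' @export
build_classifier <- function(backbone = "tiny2d", config = train_config(),
                             input_shape = c(224L, 224L, 1L)) {
  if (!identical(backbone, "tiny2d"))
    ecg_abort(paste0("unknown backbone: ", backbone,
                     " (built-in backbones: tiny2d)"), "config")
  layers <- list()
  sh <- as.integer(input_shape)
  layers[[1]] <- nn_conv(sh, filters = 8L, kh = 3L)
  layers[[2]] <- nn_pool(stack_out_shape(layers[1]), 4L, 4L)
  layers[[3]] <- nn_conv(layers[[2]]$out_shape, filters = 16L, kh = 3L)
  layers[[4]] <- nn_pool(layers[[3]]$out_shape, 2L, 2L)
  layers[[5]] <- nn_conv(layers[[4]]$out_shape, filters = 32L, kh = 3L)
  layers[[6]] <- nn_pool(layers[[5]]$out_shape, 2L, 2L)
  feat_dim <- layers[[6]]$out_shape[3L]   # global average pooling
  head <- list(nn_dense(feat_dim, config$head_hidden_units, "relu"),
               nn_dense(config$head_hidden_units, 2L, "linear"))
  model <- structure(
    list(kind = "image2d", backbone = backbone,
         input_shape = sh, branches = list(layers), reduce = "gap",
         branch_feat_dim = feat_dim, head = head,
         freeze_backbone = config$freeze_backbone,
         config = config, trained = FALSE),
    class = "ecg_model")
  init_model_params(model, config$seed)
}

#' Build the four-branch 1-D CNN baseline
#'
#' The conventional waveform-domain comparator: each of the four panel leads
#' (II, V3, V5, aVR; 5000 samples) feeds an independent branch of four 1-D
#' convolution + max-pool blocks; the branch features are concatenated and
#' classified by a single fully connected layer.
#'
#' @param config An `ecg_train_config`.
#' @param n_samples Samples per lead (default 5000).
#' @return An object of class `ecg_model`.
#' @export
build_1d_baseline <- function(config = train_config(), n_samples = 5000L) {
  make_branch <- function() {
    layers <- list()
    sh <- c(as.integer(n_samples), 1L, 1L)
    filt <- c(8L, 16L, 16L, 16L)
    for (i in 1:4) {
      layers[[2L * i - 1L]] <- nn_conv(sh, filters = filt[i], kh = 9L, kw = 1L)
      layers[[2L * i]] <- nn_pool(layers[[2L * i - 1L]]$out_shape, 4L, 1L)
      sh <- layers[[2L * i]]$out_shape
    }
    layers
  }
  branches <- lapply(seq_along(PANEL_LEADS), function(i) make_branch())
  feat_dim <- prod(stack_out_shape(branches[[1L]]))  # flattened per branch
  head <- list(nn_dense(feat_dim * length(branches), 2L, "linear"))
  model <- structure(
    list(kind = "leads1d", backbone = "cnn1d4",
         input_shape = c(as.integer(n_samples), 1L, 1L),
         branches = branches, reduce = "flatten",
         branch_feat_dim = rep(feat_dim, length(branches)), head = head,
         freeze_backbone = FALSE, config = config, trained = FALSE),
    class = "ecg_model")
  init_model_params(model, config$seed)
}

init_model_params <- function(model, seed) {
  with_seed(seed, {
    for (b in seq_along(model$branches)) {
      for (i in seq_along(model$branches[[b]])) {
        if (model$branches[[b]][[i]]$type == "conv")
          model$branches[[b]][[i]] <- conv_init(model$branches[[b]][[i]])
      }
    }
    for (i in seq_along(model$head))
      model$head[[i]] <- dense_init(model$head[[i]])
  })
  # normalise branch_feat_dim to a per-branch vector
  if (length(model$branch_feat_dim) == 1L && length(model$branches) > 1L)
    model$branch_feat_dim <- rep(model$branch_feat_dim,
                                 length(model$branches))
  model
}

#' Count model parameters
#'
#' @param model An `ecg_model`.
#' @param trainable_only Count only parameters that receive updates
#'   (head layers, plus backbone when not frozen).
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, trainable_only = FALSE) {
  count_layer <- function(l) length(layer_weight(l)) + length(l$b)
  total <- 0L
  if (!trainable_only || !model$freeze_backbone) {
    for (br in model$branches)
      for (l in br) if (l$type == "conv") total <- total + count_layer(l)
  }
  for (l in model$head) total <- total + count_layer(l)
  total
}

#' @export
print.ecg_model <- function(x, ...) {
  cat(sprintf("<ecg_model> backbone %s (%s), %d parameter(s) (%d trainable)%s\n",
              x$backbone, x$kind, n_parameters(x),
              n_parameters(x, trainable_only = TRUE),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

# ---- datasets ---------------------------------------------------------------

#' Assemble an image dataset from encoded panels and labels
#'
#' Each patient contributes exactly `segments` items (one per segment image),
#' all carrying the patient's label: 0 for survivor, 1 for non-survivor.
#'
#' @param panels List of `ecg_image_panel` objects.
#' @param labels Named character or numeric vector mapping patient id to
#'   label (`"survivor"`/`"non_survivor"` or 0/1).
#' @return An object of class `ecg_image_dataset`.
#' @export
image_dataset <- function(panels, labels) {
  labels <- normalise_labels(labels)
  items <- list()
  for (p in panels) {
    lab <- labels[[p$patient_id]]
    assert_that(!is.null(lab) && !is.na(lab),
                paste0("no label for patient ", p$patient_id), "parse")
    for (i in seq_along(p$images)) {
      items[[length(items) + 1L]] <- list(
        x = p$images[[i]], patient_id = p$patient_id,
        segment_index = p$segment_index[i], label = lab)
    }
  }
  structure(list(items = items, kind = "image2d"),
            class = "ecg_image_dataset")
}

#' Assemble a lead dataset (1-D baseline input) from panels and labels
#'
#' @param panels List of `ecg_lead_panel` objects.
#' @param labels As in [image_dataset()].
#' @return An object of class `ecg_lead_dataset`; one item per patient.
#' @export
lead_dataset <- function(panels, labels) {
  labels <- normalise_labels(labels)
  items <- lapply(panels, function(p) {
    lab <- labels[[p$patient_id]]
    assert_that(!is.null(lab) && !is.na(lab),
                paste0("no label for patient ", p$patient_id), "parse")
    list(x = do.call(rbind, p$leads_in_order), patient_id = p$patient_id,
         segment_index = 0L, label = lab)
  })
  structure(list(items = items, kind = "leads1d"),
            class = "ecg_lead_dataset")
}

normalise_labels <- function(labels) {
  assert_that(!is.null(names(labels)) || is.data.frame(labels),
              "labels must be named or a data frame", "parse")
  if (is.data.frame(labels)) {
    v <- labels$label
    names(v) <- labels$patient_id
    labels <- v
  }
  if (is.character(labels)) {
    assert_that(all(labels %in% c("survivor", "non_survivor")),
                "labels must be survivor/non_survivor", "parse")
    nms <- names(labels)
    labels <- as.integer(labels == "non_survivor")
    names(labels) <- nms
  }
  as.list(labels)
}

dataset_patients <- function(ds)
  unique(vapply(ds$items, `[[`, character(1), "patient_id"))

dataset_subset <- function(ds, patient_ids) {
  keep <- vapply(ds$items, function(it) it$patient_id %in% patient_ids,
                 logical(1))
  out <- ds
  out$items <- ds$items[keep]
  out
}

# Convert dataset items to the engine's input tensors. Images are normalised
# to trace-positive [0, 1] (background 0); leads are used in mV as-is.
dataset_tensors <- function(ds, model) {
  n <- length(ds$items)
  assert_that(n >= 1L, "empty dataset", "empty_input")
  y <- vapply(ds$items, function(it) as.integer(it$label), integer(1))
  if (ds$kind == "image2d") {
    H <- model$input_shape[1L]; W <- model$input_shape[2L]
    xs <- array(0, c(H, W, n, 1L))
    for (i in seq_len(n)) {
      img <- ds$items[[i]]$x
      assert_that(all(dim(img) == c(H, W)),
                  sprintf("image %d is %dx%d, expected %dx%d", i,
                          nrow(img), ncol(img), H, W), "shape")
      xs[, , i, 1L] <- (255 - img) / 255
    }
    list(xs = list(xs), y = y)
  } else {
    L <- model$input_shape[1L]
    xs <- lapply(seq_along(PANEL_LEADS), function(b) array(0, c(L, 1L, n, 1L)))
    for (i in seq_len(n)) {
      m <- ds$items[[i]]$x
      assert_that(is.matrix(m) && nrow(m) == length(PANEL_LEADS) &&
                    ncol(m) == L,
                  sprintf("lead item %d must be %d x %d", i,
                          length(PANEL_LEADS), L), "shape")
      for (b in seq_along(PANEL_LEADS)) xs[[b]][, 1L, i, 1L] <- m[b, ]
    }
    list(xs = xs, y = y)
  }
}

subset_tensors <- function(tensors, idx) {
  list(xs = lapply(tensors$xs, function(a) a[, , idx, , drop = FALSE]),
       y = tensors$y[idx])
}

# ---- training ---------------------------------------------------------------

#' Train a classifier
#'
#' Mini-batch Adam on the softmax cross-entropy, deterministic given
#' `config$seed`. Training and validation sets must not share patients;
#' overlap raises a leakage error. The model returned is the final-epoch
#' model (no early stopping); the history records per-epoch loss and
#' accuracy on both sets.
#'
#' @param model An `ecg_model` from [build_classifier()] or
#'   [build_1d_baseline()].
#' @param train_set,val_set Datasets of the model's input kind.
#' @param config An `ecg_train_config`; defaults to the model's own.
#' @return List with elements `model` (trained) and `history` (data frame
#'   with one row per epoch: `epoch`, `train_loss`, `train_acc`, `val_loss`,
#'   `val_acc`).
#' @export
train <- function(model, train_set, val_set, config = model$config) {
  stopifnot(inherits(model, "ecg_model"))
  assert_that(length(train_set$items) >= 1L, "empty training set",
              "empty_input")
  assert_that(length(val_set$items) >= 1L, "empty validation set",
              "empty_input")
  overlap <- intersect(dataset_patients(train_set), dataset_patients(val_set))
  if (length(overlap))
    ecg_abort(paste0("patient(s) in both train and validation: ",
                     paste(utils::head(overlap, 5L), collapse = ", ")),
              "leakage")
  tr <- dataset_tensors(train_set, model)
  va <- dataset_tensors(val_set, model)
  n_tr <- length(tr$y)
  state <- adam_init(model)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        batch <- subset_tensors(tr, idx)
        fw <- model_forward(model, batch$xs, store = TRUE)
        yhot <- matrix(0, 2L, length(idx))
        yhot[cbind(batch$y + 1L, seq_along(idx))] <- 1
        eps <- 1e-12
        ep_loss <- ep_loss -
          sum(log(pmax(fw$probs[cbind(batch$y + 1L, seq_along(idx))], eps)))
        ep_correct <- ep_correct +
          sum((fw$probs[2L, ] >= 0.5) == (batch$y == 1L))
        dlogits <- (fw$probs - yhot) / length(idx)
        bw <- model_backward(model, fw, dlogits, want_params = TRUE)
        upd <- adam_step(model, state, bw$grads, config$learning_rate)
        model <- upd$model
        state <- upd$state
      }
      val_eval <- evaluate_tensors(model, va)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / n_tr,
        train_acc = ep_correct / n_tr,
        val_loss = val_eval$loss, val_acc = val_eval$acc))
    }
  })
  model$trained <- TRUE
  list(model = model, history = history)
}

# mean cross-entropy and accuracy of a model on prepared tensors
evaluate_tensors <- function(model, tensors, batch = 64L) {
  n <- length(tensors$y)
  loss <- 0; correct <- 0L
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    b <- subset_tensors(tensors, idx)
    fw <- model_forward(model, b$xs, store = FALSE)
    loss <- loss - sum(log(pmax(fw$probs[cbind(b$y + 1L, seq_along(idx))],
                                1e-12)))
    correct <- correct + sum((fw$probs[2L, ] >= 0.5) == (b$y == 1L))
  }
  list(loss = loss / n, acc = correct / n)
}

#' Per-image death probability
#'
#' Runs one image through a 2-D classifier and returns the probability of
#' the non-survivor class, in `[0, 1]`. Deterministic for a fixed model.
#'
#' @param model An `ecg_model` of kind `image2d`.
#' @param image `height` x `width` intensity matrix (8-bit scale).
#' @return Scalar probability of death.
#' @export
predict_image <- function(model, image) {
  stopifnot(inherits(model, "ecg_model"))
  assert_that(model$kind == "image2d",
              "predict_image requires an image-input model", "config")
  H <- model$input_shape[1L]; W <- model$input_shape[2L]
  assert_that(is.matrix(image) && all(dim(image) == c(H, W)),
              sprintf("image must be %d x %d", H, W), "shape")
  x <- array((255 - image) / 255, c(H, W, 1L, 1L))
  fw <- model_forward(model, list(x), store = FALSE)
  as.numeric(fw$probs[2L, 1L])
}

#' Class scores for one input (both classes)
#'
#' @param model An `ecg_model`.
#' @param x For `image2d` models, an intensity matrix; for `leads1d` models,
#'   a 4 x n_samples matrix of lead amplitudes (mV), rows in panel order.
#' @return Numeric vector `c(survivor, non_survivor)` summing to 1.
#' @export
predict_scores <- function(model, x) {
  if (model$kind == "image2d") {
    p <- predict_image(model, x)
    return(c(survivor = 1 - p, non_survivor = p))
  }
  L <- model$input_shape[1L]
  assert_that(is.matrix(x) && nrow(x) == length(PANEL_LEADS) && ncol(x) == L,
              sprintf("lead input must be %d x %d", length(PANEL_LEADS), L),
              "shape")
  xs <- lapply(seq_len(nrow(x)), function(b)
    array(x[b, ], c(L, 1L, 1L, 1L)))
  fw <- model_forward(model, xs, store = FALSE)
  c(survivor = fw$probs[1L, 1L], non_survivor = fw$probs[2L, 1L])
}

#' Per-item death probabilities for a whole dataset
#'
#' @param model A trained `ecg_model`.
#' @param dataset A dataset of the model's input kind.
#' @param batch Prediction batch size (default 64).
#' @return Data frame with `patient_id`, `segment_index`, `prob` (death
#'   probability) and `label`.
#' @export
predict_dataset <- function(model, dataset, batch = 64L) {
  tensors <- dataset_tensors(dataset, model)
  n <- length(tensors$y)
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- model_forward(model, subset_tensors(tensors, idx)$xs)
    probs[idx] <- fw$probs[2L, ]
  }
  data.frame(
    patient_id = vapply(dataset$items, `[[`, character(1), "patient_id"),
    segment_index = vapply(dataset$items, function(it)
      as.integer(it$segment_index), integer(1)),
    prob = probs,
    label = tensors$y)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file of the model object plus a JSON sidecar
#' (`<path>.json`) recording the backbone, training configuration and a
#' digest of the parameter values.
#'
#' @param model An `ecg_model`.
#' @param path Checkpoint path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(backbone = model$backbone, kind = model$kind,
               trained = model$trained,
               n_parameters = n_parameters(model),
               config = unclass(model$config),
               param_sum = sum(vapply(trainable_keys(model), function(k) {
                 l <- get_layer(model, k); sum(layer_weight(l)) + sum(l$b)
               }, numeric(1))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ecg_model"))
  m
}
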