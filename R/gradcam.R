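# GradCAM attribution for the image classifier: class-gradient-weighted
# combination of the final convolution's feature maps.

#' Compute a GradCAM heatmap
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class's logit with respect to the final convolution's activation maps is
#' averaged spatially to one weight per channel; the weighted sum of the
#' activation channels is rectified (negative values zeroed), upsampled
#' bilinearly to the image size, and divided by its maximum. An identically
#' zero map (e.g. a dead ReLU path) is returned as all zeros with
#' `empty = TRUE` rather than divided.
#'
#' @param model An image-input `ecg_model` containing at least one
#'   convolution layer.
#' @param image Intensity matrix matching the model's input size.
#' @param target_class 0 (survivor) or 1 (non-survivor): whose logit is
#'   attributed.
#' @return An `ecg_heatmap`: list with `raw` (feature-map resolution,
#'   non-negative), `upsampled` (image resolution, max 1 unless empty),
#'   `target_class` and `empty`.
#' @export
compute_gradcam <- function(model, image, target_class = 1L) {
  stopifnot(inherits(model, "ecg_model"))
  assert_that(model$kind == "image2d",
              "GradCAM requires an image-input model", "unsupported_model")
  has_conv <- any(vapply(model$branches[[1L]],
                         function(l) l$type == "conv", logical(1)))
  assert_that(has_conv, "model has no convolutional layers",
              "unsupported_model")
  assert_that(target_class %in% c(0L, 1L), "target_class must be 0 or 1",
              "config")
  H <- model$input_shape[1L]; W <- model$input_shape[2L]
  assert_that(is.matrix(image) && all(dim(image) == c(H, W)),
              sprintf("image must be %d x %d", H, W), "shape")
  x <- array((255 - image) / 255, c(H, W, 1L, 1L))  # (H, W, N=1, C=1)
  fw <- model_forward(model, list(x), store = TRUE)
  dlogits <- matrix(0, 2L, 1L)
  dlogits[target_class + 1L, 1L] <- 1
  bw <- model_backward(model, fw, dlogits, want_params = FALSE,
                       act_grad_branch = 1L)
  # activations of the last conv layer (post-activation) and their gradient
  layers <- model$branches[[1L]]
  last_conv <- max(which(vapply(layers, function(l) l$type == "conv",
                                logical(1))))
  act <- x
  for (i in seq_len(last_conv)) {
    lay <- layers[[i]]
    act <- if (lay$type == "conv") conv_forward(lay, act)$out
           else pool_forward(lay, act)$out
  }
  A <- act[, , 1L, , drop = TRUE]              # (h, w, channels)
  dA <- bw$act_grad[, , 1L, , drop = TRUE]
  if (length(dim(A)) == 2L) {                  # single-channel conv
    dim(A) <- c(dim(A), 1L)
    dim(dA) <- dim(A)
  }
  alpha <- apply(dA, 3L, mean)                 # per-channel weight
  raw <- matrix(0, dim(A)[1L], dim(A)[2L])
  for (ch in seq_along(alpha)) raw <- raw + alpha[ch] * A[, , ch]
  raw <- pmax(raw, 0)
  empty <- max(raw) == 0
  up <- bilinear_upsample(raw, H, W)
  if (!empty) up <- up / max(up) else up[] <- 0
  structure(list(raw = raw, upsampled = up,
                 target_class = as.integer(target_class), empty = empty),
            class = "ecg_heatmap")
}

# bilinear upsampling with pixel-center alignment
bilinear_upsample <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  src_of <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sy <- src_of(out_h, in_h); sx <- src_of(out_w, in_w)
  y0 <- pmin(floor(sy), in_h - 2); y1 <- y0 + 1; wy <- sy - y0
  x0 <- pmin(floor(sx), in_w - 2); x1 <- x0 + 1; wx <- sx - x0
  if (in_h == 1L) { y0 <- y1 <- rep(0, out_h); wy <- rep(0, out_h) }
  if (in_w == 1L) { x0 <- x1 <- rep(0, out_w); wx <- rep(0, out_w) }
  top <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx) +
    m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
  bot <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx) +
    m[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  top + bot
}

# blue -> cyan -> yellow -> red piecewise-linear colormap on [0, 1];
# returns a (n x 3) matrix of 0-255 RGB values
heat_colormap <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(3 * v - 1.5, 0), 1)
  g <- pmin(pmax(1.5 - abs(3 * v - 1.5), 0), 1)
  b <- pmin(pmax(1.5 - 3 * v, 0), 1)
  cbind(r, g, b) * 255
}

#' Overlay a GradCAM heatmap on an ECG image
#'
#' Applies a blue-to-red colormap to the upsampled heatmap (blue = low
#' attribution, red = high) and alpha-blends it over the grayscale image.
#' Deterministic.
#'
#' @param heatmap An `ecg_heatmap`.
#' @param image Grayscale intensity matrix of the same size as
#'   `heatmap$upsampled`.
#' @param alpha Blend weight of the colormap in `[0, 1]` (default 0.4);
#'   `alpha = 0` returns the image replicated to RGB, `alpha = 1` the pure
#'   colormap.
#' @return `height` x `width` x 3 numeric array of 0-255 RGB values.
#' @export
overlay <- function(heatmap, image, alpha = 0.4) {
  stopifnot(inherits(heatmap, "ecg_heatmap"))
  assert_that(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]", "config")
  hm <- heatmap$upsampled
  assert_that(is.matrix(image) && all(dim(image) == dim(hm)),
              "image and heatmap dimensions differ", "shape")
  col <- heat_colormap(as.vector(hm))
  out <- array(0, c(dim(hm), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * image +
      alpha * matrix(col[, ch], nrow(hm), ncol(hm))
  }
  out
}

#' Write an overlay as an RGB PNG
#'
#' @param rgb Array from [overlay()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' Per-lead (and per-time-bin) attribution shares
#'
#' Integrates the upsampled heatmap mass over each lead's row band in the
#' stacked layout, optionally split into time bins along the width. Shares
#' are fractions of the total heatmap mass (including gap rows), so lead
#' shares sum to at most 1; gap-row mass is excluded from every band.
#'
#' @param heatmap An `ecg_heatmap` at the composed-image resolution.
#' @param config The `ecg_render_config` describing the layout.
#' @param n_time_bins Number of equal column bins (default 1).
#' @return List with `lead_shares` (named numeric, one per panel lead) and
#'   `share_matrix` (leads x time bins).
#' @export
strip_attribution <- function(heatmap, config = render_config(),
                              n_time_bins = 1L) {
  stopifnot(inherits(heatmap, "ecg_heatmap"))
  hm <- heatmap$upsampled
  assert_that(all(dim(hm) == c(config$out_size, config$out_size)),
              "heatmap resolution does not match the layout", "layout")
  bands <- strip_row_bands(config)
  total <- sum(hm)
  n_time_bins <- as.integer(n_time_bins)
  bin_edges <- floor(seq(0, config$out_size, length.out = n_time_bins + 1L))
  shares <- matrix(0, nrow(bands), n_time_bins,
                   dimnames = list(bands$lead, NULL))
  for (i in seq_len(nrow(bands))) {
    for (j in seq_len(n_time_bins)) {
      cols <- (bin_edges[j] + 1L):bin_edges[j + 1L]
      mass <- sum(hm[bands$start[i]:bands$end[i], cols])
      shares[i, j] <- if (total > 0) mass / total else 0
    }
  }
  list(lead_shares = rowSums(shares), share_matrix = shares)
}
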