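# Independent oracles used by the tests. These deliberately share no code
# with the package implementation: plain scalar loops and direct formulas.

# Direct (non-separable, per-output-pixel) Lanczos resampling: for every
# output pixel, accumulate the normalised product kernel over all
# contributing input pixels.
oracle_lanczos_resize <- function(grid, out_w, out_h, a = 3) {
  lanc <- function(x) {
    if (x == 0) return(1)
    if (abs(x) >= a) return(0)
    a * sin(pi * x) * sin(pi * x / a) / (pi * x)^2
  }
  axis_weights <- function(n_in, n_out) {
    scale <- n_in / n_out
    fs <- max(scale, 1)
    lapply(seq_len(n_out), function(j) {
      center <- (j - 0.5) * scale - 0.5
      src <- floor(center - a * fs):ceiling(center + a * fs)
      w <- vapply(src, function(i) lanc((i - center) / fs), numeric(1))
      src <- pmin(pmax(src, 0), n_in - 1)
      list(src = src + 1, w = w / sum(w))
    })
  }
  wr <- axis_weights(nrow(grid), out_h)
  wc <- axis_weights(ncol(grid), out_w)
  out <- matrix(0, out_h, out_w)
  for (r in seq_len(out_h)) {
    for (cc in seq_len(out_w)) {
      acc <- 0
      for (u in seq_along(wr[[r]]$src)) {
        for (v in seq_along(wc[[cc]]$src)) {
          acc <- acc + wr[[r]]$w[u] * wc[[cc]]$w[v] *
            grid[wr[[r]]$src[u], wc[[cc]]$src[v]]
        }
      }
      out[r, cc] <- acc
    }
  }
  matrix(floor(pmin(pmax(out, 0), 255) + 0.5), out_h, out_w)
}

# Mann-Whitney AUC: exhaustive loop over all positive/negative pairs,
# counting wins and half-crediting ties.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) wins <- wins + 1
      else if (p == q) wins <- wins + 0.5
    }
  }
  wins / (length(pos) * length(neg))
}

# brute-force confusion counting and percent rates
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sens = if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_,
       spec = if (fp + tn > 0) tn / (fp + tn) * 100 else NA_real_,
       acc = (tp + tn) / length(pred) * 100)
}

# hand-built single-filter linear model: conv(1 filter, linear) -> global
# average pooling -> dense(2, linear) with known weights. For this network
# the class gradient at every feature-map cell is w_c / (H*W), so the
# heatmap has the closed form relu(w_c / (H*W) * A).
oracle_gradcam_model <- function(size = 16L, kernel, w_dense) {
  conv <- ecg2img:::nn_conv(c(size, size, 1L), filters = 1L, kh = 3L,
                            activation = "linear")
  conv$Wt <- matrix(kernel, ncol = 1)
  conv$b <- 0
  dense <- ecg2img:::nn_dense(1L, 2L, activation = "linear")
  dense$W <- w_dense
  dense$b <- c(0, 0)
  structure(list(kind = "image2d", backbone = "oracle",
                 input_shape = c(size, size, 1L),
                 branches = list(list(conv)), reduce = "gap",
                 branch_feat_dim = 1L, head = list(dense),
                 freeze_backbone = TRUE,
                 config = train_config(), trained = TRUE),
            class = "ecg_model")
}

# direct zero-padded same 3x3 convolution by scalar loops; the kernel
# vector order is (dh fast, dw), matching the engine's weight layout
oracle_conv_same <- function(img, kernel3) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (dh in -1:1) {
        for (dw in -1:1) {
          si <- i + dh; sj <- j + dw
          v <- if (si >= 1 && si <= H && sj >= 1 && sj <= W) img[si, sj] else 0
          acc <- acc + v * kernel3[(dh + 2) + 3 * (dw + 1)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# crude R-peak detector: local maxima above a fraction of the global max,
# deduplicated within a refractory window
detect_r_peaks <- function(sig, rate = 500, min_frac = 0.5,
                           refractory_s = 0.3) {
  thr <- min_frac * max(sig)
  cand <- which(sig > thr)
  cand <- cand[cand > 1 & cand < length(sig)]
  cand <- cand[sig[cand] >= sig[cand - 1] & sig[cand] >= sig[cand + 1]]
  peaks <- integer()
  for (i in cand) {
    if (!length(peaks) || i - peaks[length(peaks)] > refractory_s * rate)
      peaks <- c(peaks, i)
    else if (sig[i] > sig[peaks[length(peaks)]])
      peaks[length(peaks)] <- i
  }
  peaks
}

# mean amplitude over per-beat ST windows (seconds after each R peak)
st_window_mean <- function(sig, peaks, rate = 500,
                           window_s = c(0.06, 0.19)) {
  vals <- c()
  for (p in peaks) {
    lo <- p + round(window_s[1] * rate)
    hi <- p + round(window_s[2] * rate)
    if (hi <= length(sig)) vals <- c(vals, sig[lo:hi])
  }
  mean(vals)
}
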