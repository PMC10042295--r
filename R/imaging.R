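# Waveform-to-image encoding: segmentation, polyline rendering, Lanczos
# reduction and stacked-lead composition.

#' Rendering configuration for the stacked-lead image encoder
#'
#' Geometry and intensity settings of the encoder. The default layout stacks
#' the four panel leads top-to-bottom with 40 background pixels between
#' consecutive strips inside a 224x224 image, which forces a strip height of
#' 26 px (4*26 + 3*40 = 224). Traces are rendered dark-on-light.
#'
#' @param segments Number of time segments per record (default 3).
#' @param out_size Output image side in pixels (default 224).
#' @param strip_height_px Height of each reduced lead strip (default 26).
#' @param inter_lead_gap_px Background rows between strips (default 40).
#' @param amp_range_mv Symmetric amplitude range mapped onto a strip's full
#'   height; samples outside `[-amp_range_mv, +amp_range_mv]` clip to the
#'   edge rows (default 2.0 mV). A fixed physical range keeps amplitudes
#'   comparable across segments and patients.
#' @param native_strip_height_px Pre-reduction render height (default 256).
#' @param trace_intensity,background_intensity 8-bit intensities of the trace
#'   and the background (defaults 0 and 255).
#' @param lanczos_taps Lobe count of the Lanczos kernel (default 3).
#' @return An object of class `ecg_render_config`.
#' @export
render_config <- function(segments = 3L, out_size = 224L,
                          strip_height_px = 26L, inter_lead_gap_px = 40L,
                          amp_range_mv = 2.0, native_strip_height_px = 256L,
                          trace_intensity = 0L, background_intensity = 255L,
                          lanczos_taps = 3L) {
  cfg <- list(segments = as.integer(segments),
              out_size = as.integer(out_size),
              strip_height_px = as.integer(strip_height_px),
              inter_lead_gap_px = as.integer(inter_lead_gap_px),
              amp_range_mv = as.numeric(amp_range_mv),
              native_strip_height_px = as.integer(native_strip_height_px),
              trace_intensity = as.integer(trace_intensity),
              background_intensity = as.integer(background_intensity),
              lanczos_taps = as.integer(lanczos_taps))
  assert_that(cfg$segments >= 1L, "segments must be >= 1", "config")
  assert_that(cfg$amp_range_mv > 0, "amp_range_mv must be positive", "config")
  assert_that(cfg$trace_intensity != cfg$background_intensity,
              "trace and background intensities must differ", "config")
  n_leads <- length(PANEL_LEADS)
  assert_that(n_leads * cfg$strip_height_px +
                (n_leads - 1L) * cfg$inter_lead_gap_px == cfg$out_size,
              sprintf("layout mismatch: %d strips of %d px + %d gaps of %d px != %d px",
                      n_leads, cfg$strip_height_px, n_leads - 1L,
                      cfg$inter_lead_gap_px, cfg$out_size), "config")
  structure(cfg, class = "ecg_render_config")
}

#' Read a rendering configuration from a JSON or YAML file
#'
#' The file holds any subset of [render_config()]'s arguments by name;
#' unspecified fields keep their defaults. YAML files require the `yaml`
#' package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `ecg_render_config`.
#' @export
read_render_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      ecg_abort("reading YAML configs requires the 'yaml' package", "config")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(render_config))
  bad <- setdiff(names(vals), known)
  assert_that(length(bad) == 0L,
              paste0("unknown render config field(s): ",
                     paste(bad, collapse = ", ")), "config")
  do.call(render_config, vals)
}

#' Split samples into contiguous time segments
#'
#' Partitions a sample vector into `n` contiguous, ordered segments whose
#' lengths differ by at most one; earlier segments take the extra samples,
#' so 5000 samples split three ways into 1667, 1667 and 1666.
#'
#' @param samples Numeric vector.
#' @param n Number of segments (default 3).
#' @return List of `n` numeric vectors whose concatenation equals `samples`.
#' @export
split_segments <- function(samples, n = 3L) {
  n <- as.integer(n)
  assert_that(n >= 1L, "segment count must be >= 1", "partition")
  len <- length(samples)
  assert_that(n <= len,
              sprintf("cannot split %d sample(s) into %d segments", len, n),
              "partition")
  base <- len %/% n
  extra <- len %% n
  sizes <- rep(base, n) + c(rep(1L, extra), rep(0L, n - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n), function(i) samples[starts[i]:ends[i]])
}

# Map amplitudes (mV) to fractional row positions: +amp_range -> row 0 (top),
# -amp_range -> bottom row. Values outside the range are clipped first.
amp_to_row <- function(v, amp_range, height_px) {
  v <- pmin(pmax(v, -amp_range), amp_range)
  (amp_range - v) / (2 * amp_range) * (height_px - 1)
}

#' Render a sample vector as a one-pixel polyline strip
#'
#' Maps samples uniformly onto `x in [0, width_px - 1]`, linearly
#' interpolates the amplitude at every output column, and draws a connected
#' one-pixel trace: each column is painted at its interpolated row, plus the
#' vertical run joining it to the previous column's row, so steep deflections
#' stay connected. Positive amplitude is up (row 0 is the image top).
#'
#' @param samples Numeric amplitudes (mV), non-empty.
#' @param width_px,height_px Strip dimensions in pixels (both >= 2).
#' @param config An `ecg_render_config` (intensities and amplitude range).
#' @return `height_px` x `width_px` numeric matrix of 8-bit intensities.
#' @export
render_strip <- function(samples, width_px, height_px,
                         config = render_config()) {
  assert_that(length(samples) >= 1L, "no samples to render", "empty_input")
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  assert_that(width_px >= 2L && height_px >= 2L,
              "strip dimensions must be >= 2 px", "dimension")
  n <- length(samples)
  y <- amp_to_row(as.numeric(samples), config$amp_range_mv, height_px)
  cols <- seq_len(width_px) - 1L
  if (n == 1L) {
    yc <- rep(y, width_px)
  } else {
    xs <- (seq_len(n) - 1) * (width_px - 1) / (n - 1)
    yc <- stats::approx(xs, y, xout = cols, rule = 2)$y
  }
  r <- as.integer(floor(yc + 0.5))
  r <- pmin(pmax(r, 0L), height_px - 1L)
  prev <- c(r[1L], r[-width_px])
  lo <- pmin(r, prev); hi <- pmax(r, prev)
  lens <- hi - lo + 1L
  rows <- sequence(lens, from = lo)
  colv <- rep(cols, lens)
  grid <- matrix(as.numeric(config$background_intensity), height_px, width_px)
  grid[cbind(rows + 1L, colv + 1L)] <- config$trace_intensity
  grid
}

# --- Lanczos resampling -----------------------------------------------------

lanczos_fn <- function(x, a) {
  out <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  out[x == 0] <- 1
  px <- pi * x[nz]
  out[nz] <- a * sin(px) * sin(px / a) / (px * px)
  out
}

# Row-normalised resampling weight matrix (n_out x n_in). For reduction the
# kernel is dilated by the scale factor so its support covers `taps` input
# pixels per output pixel on each side; edges are handled by clamping source
# indices (replicate padding). Memoised: the encoder reuses a handful of
# shapes thousands of times.
.lanczos_cache <- new.env(parent = emptyenv())

lanczos_weights <- function(n_in, n_out, a) {
  key <- paste(n_in, n_out, a, sep = "_")
  hit <- .lanczos_cache[[key]]
  if (!is.null(hit)) return(hit)
  scale <- n_in / n_out
  fscale <- max(scale, 1)
  support <- a * fscale
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    center <- (j - 0.5) * scale - 0.5
    i0 <- floor(center - support)
    idx <- i0:ceiling(center + support)
    w <- lanczos_fn((idx - center) / fscale, a)
    idx <- pmin(pmax(idx, 0), n_in - 1)
    wv <- numeric(n_in)
    for (t in seq_along(idx)) wv[idx[t] + 1] <- wv[idx[t] + 1] + w[t]
    W[j, ] <- wv / sum(wv)
  }
  .lanczos_cache[[key]] <- W
  W
}

#' Resize an intensity grid with Lanczos resampling
#'
#' Separable windowed-sinc (Lanczos) resampling with `taps` lobes, the
#' classical high-quality reduction filter. The kernel is normalised per
#' output pixel, so constant images are preserved exactly; output is clamped
#' to `[0, 255]` and rounded to 8-bit levels.
#'
#' @param grid Numeric matrix (rows = height).
#' @param out_w,out_h Output width and height in pixels (>= 1).
#' @param taps Kernel lobe count (default 3).
#' @return `out_h` x `out_w` numeric matrix with values in `[0, 255]`.
#' @export
resize_lanczos <- function(grid, out_w, out_h, taps = 3L) {
  assert_that(is.matrix(grid) && all(dim(grid) >= 1L),
              "grid must be a non-empty matrix", "dimension")
  out_w <- as.integer(out_w); out_h <- as.integer(out_h)
  assert_that(out_w >= 1L && out_h >= 1L,
              "output dimensions must be positive", "dimension")
  Wr <- lanczos_weights(nrow(grid), out_h, taps)
  Wc <- lanczos_weights(ncol(grid), out_w, taps)
  out <- Wr %*% grid %*% t(Wc)
  out <- pmin(pmax(out, 0), 255)
  matrix(floor(out + 0.5), out_h, out_w)
}

#' Stack four lead strips into one square image
#'
#' Places the four strips top-to-bottom in the fixed panel order with
#' `inter_lead_gap_px` background rows between consecutive strips. Under the
#' default layout, strip `k` (0-based) occupies rows `[k*66, k*66 + 26)`.
#'
#' @param strips List of four matrices, each `strip_height_px` x `out_size`.
#' @param config An `ecg_render_config`.
#' @return `out_size` x `out_size` numeric matrix.
#' @export
compose_panel <- function(strips, config = render_config()) {
  n_leads <- length(PANEL_LEADS)
  assert_that(is.list(strips) && length(strips) == n_leads,
              sprintf("expected %d strips", n_leads), "shape")
  for (s in strips) {
    assert_that(is.matrix(s) && nrow(s) == config$strip_height_px &&
                  ncol(s) == config$out_size,
                sprintf("each strip must be %d x %d",
                        config$strip_height_px, config$out_size), "shape")
  }
  img <- matrix(as.numeric(config$background_intensity),
                config$out_size, config$out_size)
  step <- config$strip_height_px + config$inter_lead_gap_px
  for (k in seq_len(n_leads) - 1L) {
    r0 <- k * step
    img[(r0 + 1L):(r0 + config$strip_height_px), ] <- strips[[k + 1L]]
  }
  img
}

# Row bands (1-based start/end) occupied by each lead strip in the composed
# image; used by composition, GradCAM attribution and tests.
strip_row_bands <- function(config = render_config()) {
  step <- config$strip_height_px + config$inter_lead_gap_px
  k <- seq_along(PANEL_LEADS) - 1L
  data.frame(lead = PANEL_LEADS, start = k * step + 1L,
             end = k * step + config$strip_height_px)
}

#' Encode a four-lead panel as three stacked-lead images
#'
#' The full waveform-to-image pipeline for one patient: each lead is split
#' into `segments` contiguous time segments; per segment, each lead is
#' rendered as a polyline strip at native resolution (width = segment length,
#' height = `native_strip_height_px`), reduced with Lanczos resampling to
#' `out_size` x `strip_height_px`, and the four reduced strips are stacked
#' into one `out_size` x `out_size` image. Deterministic: identical inputs
#' produce identical images.
#'
#' @param panel An `ecg_lead_panel`.
#' @param config An `ecg_render_config`.
#' @return An `ecg_image_panel`: list with `patient_id`, `images` (list of
#'   `segments` matrices) and `segment_index` (0-based).
#' @export
encode_patient <- function(panel, config = render_config()) {
  stopifnot(inherits(panel, "ecg_lead_panel"))
  segs <- lapply(panel$leads_in_order, split_segments, n = config$segments)
  images <- lapply(seq_len(config$segments), function(s) {
    strips <- lapply(segs, function(lead_segs) {
      x <- lead_segs[[s]]
      native <- render_strip(x, width_px = length(x),
                             height_px = config$native_strip_height_px,
                             config = config)
      resize_lanczos(native, out_w = config$out_size,
                     out_h = config$strip_height_px,
                     taps = config$lanczos_taps)
    })
    compose_panel(strips, config)
  })
  structure(list(patient_id = panel$patient_id, images = images,
                 segment_index = seq_len(config$segments) - 1L),
            class = "ecg_image_panel")
}

#' @export
print.ecg_image_panel <- function(x, ...) {
  d <- dim(x$images[[1L]])
  cat(sprintf("<ecg_image_panel> patient %s: %d image(s) of %d x %d\n",
              x$patient_id, length(x$images), d[1L], d[2L]))
  invisible(x)
}

#' Write an image panel as 8-bit grayscale PNG files
#'
#' One file per segment, named `<patient_id>_seg<k>.png` (k 0-based).
#'
#' @param panel An `ecg_image_panel`.
#' @param dir Output directory (created if absent).
#' @return Character vector of file paths.
#' @export
write_panel_png <- function(panel, dir) {
  stopifnot(inherits(panel, "ecg_image_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(panel$images))
  for (i in seq_along(panel$images)) {
    paths[i] <- file.path(dir, sprintf("%s_seg%d.png", panel$patient_id,
                                       panel$segment_index[i]))
    png::writePNG(panel$images[[i]] / 255, paths[i])
  }
  paths
}

#' Read an 8-bit grayscale PNG as an intensity matrix
#'
#' @param path PNG file path.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * 255)
}
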