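# Small fixtures built in code.

# an image panel object with given random images (for harness tests that do
# not need real waveforms)
toy_panel <- function(patient_id, size = 32L, n_images = 3L,
                      maker = function(k) matrix(stats::runif(size * size,
                                                              0, 255),
                                                 size, size)) {
  structure(list(patient_id = patient_id,
                 images = lapply(seq_len(n_images) - 1L, maker),
                 segment_index = seq_len(n_images) - 1L),
            class = "ecg_image_panel")
}

# balanced toy image dataset: class 1 darker than class 0, `n_per_class`
# patients each, deterministic given seed
toy_image_dataset <- function(n_per_class, size = 32L, seed = 1,
                              separable = TRUE) {
  panels <- list()
  labels <- character()
  ids <- character()
  k <- 0L
  set.seed(seed)
  for (cls in 0:1) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      pid <- sprintf("T%d_%02d", cls, i)
      base <- if (separable && cls == 1L) 40 else 215
      panels[[k]] <- toy_panel(pid, size = size,
                               maker = function(kk)
                                 matrix(pmin(pmax(base +
                                                    stats::rnorm(size * size,
                                                                 0, 10),
                                                  0), 255), size, size))
      ids <- c(ids, pid)
      labels <- c(labels, c("survivor", "non_survivor")[cls + 1L])
    }
  }
  image_dataset(panels, data.frame(patient_id = ids, label = labels))
}

# a synthetic waveform record quantised to the MFER fixture resolution, so
# binary round-trips are exact
grid_aligned_record <- function(seed = 7, resolution = 1e-3) {
  rec <- gen_patient("survivor", seed = seed)
  rec$leads <- lapply(rec$leads, function(v) round(v / resolution) * resolution)
  rec
}
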