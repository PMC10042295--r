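test_that("segment splitting is contiguous, ordered and ceil-first", {
  s <- split_segments(seq_len(5000), 3)
  expect_equal(lengths(s), c(1667, 1667, 1666))
  expect_identical(unlist(s), seq_len(5000))
  expect_identical(split_segments(1:7, 1), list(1:7))
  expect_identical(split_segments(1:5, 2), list(1:3, 4:5))
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    len <- n + sample(0:200, 1)
    x <- stats::rnorm(len)
    parts <- split_segments(x, n)
    expect_identical(unlist(parts), x)
    expect_lte(diff(range(lengths(parts))), 1)
    expect_true(all(diff(lengths(parts)) <= 0))   # extras go to the front
  }
  expect_error(split_segments(1:2, 3), class = "ecg2img_partition_error")
})

test_that("strip rendering maps amplitude to rows with clipping", {
  cfg <- render_config()
  # zero signal: one horizontal trace at the midline row, rest background
  g <- render_strip(numeric(100) , 100, 27, cfg)
  trace_rows <- which(apply(g, 1, function(r) any(r == cfg$trace_intensity)))
  expect_equal(trace_rows, 14)              # floor(26/2 + 0.5) + 1 (1-based)
  expect_true(all(g[-14, ] == cfg$background_intensity))
  expect_true(all(g[14, ] == cfg$trace_intensity))
  # samples pinned at +range live in row 1 (top)
  g2 <- render_strip(c(cfg$amp_range_mv, cfg$amp_range_mv), 10, 8, cfg)
  expect_true(all(g2[1, ] == cfg$trace_intensity))
  expect_true(all(g2[-1, ] == cfg$background_intensity))
  # values beyond the range clip to the edge rows
  g3 <- render_strip(c(10, -10), 50, 20, cfg)
  expect_true(any(g3[1, ] == cfg$trace_intensity))
  expect_true(any(g3[20, ] == cfg$trace_intensity))
  expect_error(render_strip(numeric(), 10, 10),
               class = "ecg2img_empty_input_error")
})

test_that("negating the signal mirrors the strip vertically", {
  set.seed(9)
  for (rep in 1:5) {
    x <- stats::rnorm(120, sd = 0.7)
    a <- render_strip(x, 150, 33)
    b <- render_strip(-x, 150, 33)
    expect_identical(b, a[nrow(a):1, ])     # brute-force pixel flip
  }
})

test_that("Lanczos resize has identity, DC and oracle agreement", {
  set.seed(21)
  g <- matrix(stats::runif(48 * 48, 0, 255), 48, 48)
  expect_equal(resize_lanczos(g, 48, 48), matrix(floor(g + 0.5), 48, 48))
  flat <- matrix(137, 30, 40)
  expect_true(all(resize_lanczos(flat, 13, 9) == 137))
  for (rep in 1:3) {
    g <- matrix(stats::runif(64 * 64, 0, 255), 64, 64)
    mine <- resize_lanczos(g, 26, 22)
    ref <- oracle_lanczos_resize(g, 26, 22)
    expect_lte(max(abs(mine - ref)), 1)
  }
  expect_error(resize_lanczos(g, 0, 5), class = "ecg2img_dimension_error")
})

test_that("panel composition places strips at the 26/40 layout rows", {
  cfg <- render_config()
  bg <- matrix(255, 26, 224)
  img <- compose_panel(list(bg, bg, bg, bg), cfg)
  expect_true(all(img == 255))
  expect_equal(dim(img), c(224, 224))

  marked <- lapply(1:4, function(k) matrix(k * 10, 26, 224))
  img2 <- compose_panel(marked, cfg)
  for (k in 0:3) {
    rows <- (k * 66 + 1):(k * 66 + 26)
    expect_true(all(img2[rows, ] == (k + 1) * 10))
  }
  gaps <- setdiff(seq_len(224), unlist(lapply(0:3, function(k)
    (k * 66 + 1):(k * 66 + 26))))
  expect_true(all(img2[gaps, ] == 255))

  # permuting strips permutes the bands and nothing else
  img3 <- compose_panel(marked[c(2, 1, 3, 4)], cfg)
  expect_true(all(img3[1:26, ] == 20) && all(img3[67:92, ] == 10))
  expect_identical(img3[133:224, ], img2[133:224, ])

  expect_error(compose_panel(list(bg, bg, bg, matrix(0, 25, 224)), cfg),
               class = "ecg2img_shape_error")
})

test_that("layout arithmetic is validated at configuration time", {
  expect_error(render_config(strip_height_px = 30),
               class = "ecg2img_config_error")
  expect_error(render_config(trace_intensity = 255),
               class = "ecg2img_config_error")
  cfg <- render_config(out_size = 112, strip_height_px = 13,
                       inter_lead_gap_px = 20)
  expect_equal(cfg$out_size, 112)
})

test_that("render configs load from JSON and YAML files", {
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('{"amp_range_mv": 1.5, "lanczos_taps": 2}', jpath)
  cfg <- read_render_config(jpath)
  expect_equal(cfg$amp_range_mv, 1.5)
  expect_equal(cfg$lanczos_taps, 2L)
  expect_equal(cfg$out_size, 224L)
  skip_if_not_installed("yaml")
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines("amp_range_mv: 2.5", ypath)
  expect_equal(read_render_config(ypath)$amp_range_mv, 2.5)
  jbad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"no_such_field": 1}', jbad)
  expect_error(read_render_config(jbad), class = "ecg2img_config_error")
})

test_that("patient encoding yields three deterministic 224x224 8-bit images", {
  rec <- gen_patient("non_survivor", seed = 17)
  pan <- select_panel(rec)
  p1 <- encode_patient(pan)
  expect_length(p1$images, 3)
  for (img in p1$images) {
    expect_equal(dim(img), c(224, 224))
    expect_true(all(img >= 0 & img <= 255))
    expect_true(all(img == floor(img)))
  }
  # determinism down to PNG bytes
  p2 <- encode_patient(pan)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_panel_png(p1, d1); f2 <- write_panel_png(p2, d2)
  for (i in 1:3) {
    expect_identical(readBin(f1[i], raw(), file.size(f1[i])),
                     readBin(f2[i], raw(), file.size(f2[i])))
    # PNG round-trip preserves every pixel
    expect_equal(read_image_png(f1[i]), p1$images[[i]])
  }
  expect_match(basename(f1), "_seg[0-2]\\.png")
})

test_that("an all-zero panel encodes to four midline traces per image", {
  pan <- lead_panel("flat", list(II = numeric(5000), V3 = numeric(5000),
                                 V5 = numeric(5000), aVR = numeric(5000)))
  enc <- encode_patient(pan)
  cfg <- render_config()
  for (img in enc$images) {
    for (k in 0:3) {
      band <- img[(k * 66 + 1):(k * 66 + 26), ]
      darkest <- which.min(rowSums(band))
      expect_equal(darkest, 14)      # the reduced midline row of each strip
      expect_true(all(band[darkest, ] < 255))
      # rows far from the midline stay background
      expect_true(all(band[c(1:8, 20:26), ] == 255))
    }
    gaps <- setdiff(seq_len(224), unlist(lapply(0:3, function(k)
      (k * 66 + 1):(k * 66 + 26))))
    expect_true(all(img[gaps, ] == 255))
  }
})

test_that("raising an amplitude never moves its trace row downwards", {
  cfg <- render_config()
  base <- rep(0.3, 60)
  rows_of <- function(x) {
    g <- render_strip(x, 60, 40, cfg)
    apply(g, 2, function(col) min(which(col == cfg$trace_intensity)))
  }
  r1 <- rows_of(base)
  for (bump in c(0.1, 0.5, 1.2)) {
    r2 <- rows_of(base + bump)
    expect_true(all(r2 <= r1))
  }
})
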