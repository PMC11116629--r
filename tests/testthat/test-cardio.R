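analytic_trace <- function(bpm, duration_s, fps, d0 = 28, c = 0.2, phase = 0) {
  tt <- (seq_len(floor(duration_s * fps)) - 1) / fps
  d0 * (1 - c * (1 + sin(2 * pi * bpm / 60 * tt + phase)) / 2)
}

test_that("kymograph construction: shape, constancy and bilinear sampling", {
  v <- video_stack(array(7, c(32, 32, 5)), 1.3, 50, "BFP")
  ln <- chamber_line(c(4, 16), c(28.5, 16))
  ky <- build_kymograph(v, ln)
  expect_equal(dim(ky$matrix), c(ceiling(ln$length) + 1, 5))
  expect_true(all(ky$matrix == 7))
  # bilinear interpolation is exact on a linear intensity field
  grad <- outer(seq_len(32), seq_len(32), function(y, x) 2 * x + 3 * y)
  vg <- video_stack(array(rep(grad, 2), c(32, 32, 2)), 1, 10, "BFP")
  lnd <- chamber_line(c(3, 5), c(20, 25))
  kyd <- build_kymograph(vg, lnd)
  tt <- seq(0, 1, length.out = nrow(kyd$matrix))
  expect_equal(kyd$matrix[, 1],
               2 * (3 + tt * 17) + 3 * (5 + tt * 20), tolerance = 1e-10)
  # validation
  expect_error(build_kymograph(v, chamber_line(c(4, 16), c(40, 16))), "bounds")
  expect_error(chamber_line(c(1, 1), c(3, 3)), "at least 8 px")
  v1 <- video_stack(array(1, c(16, 16, 1)), 1, 10)
  expect_error(build_kymograph(v1, chamber_line(c(2, 8), c(14, 8))),
               "at least 2 frames")
})

test_that("diameter trace measures outermost above-threshold extent", {
  m <- matrix(0, 60, 4)
  m[10:50, 1:4] <- 100
  ky <- structure(list(matrix = m, sample_spacing_px = 1,
                       frame_interval_s = 0.01, pixel_size_um = 1,
                       chamber = "ventricle"), class = "kymograph")
  tr <- extract_diameter_trace(ky, 50)
  expect_equal(tr, rep(40, 4))
  ky$matrix[, 2] <- 0   # empty column suppressed by the 3-frame median
  tr2 <- extract_diameter_trace(ky, 50)
  expect_equal(tr2[2], 40)
  ky$matrix[] <- 0
  expect_equal(extract_diameter_trace(ky, 50), rep(0, 4))
})

test_that("beat detection counts analytic beats and recovers rates", {
  # 10 beats in the standard 2.8 s acquisition at the default rate
  tr <- analytic_trace(214.3, 2.8, 96.8)
  b <- detect_beats(tr, 96.8)
  expect_equal(b$n_beats, 10L)
  expect_equal(b$bpm, 214.3, tolerance = 0.05)
  # 2 Hz over 3 s -> 6 beats, 120 bpm within frame quantization
  b2 <- detect_beats(analytic_trace(120, 3, 96.8), 96.8)
  expect_equal(b2$n_beats, 6L)
  expect_lt(abs(b2$bpm - 120), 1)  # one frame-quantization error
  # constant trace: no beats, bpm missing
  b0 <- detect_beats(rep(5, 100), 96.8)
  expect_equal(b0$n_beats, 0L)
  expect_true(is.na(b0$bpm))
  # frequency recovery across the physiological range, within 5%
  for (bpm in c(100, 150, 214.3, 300)) {
    br <- detect_beats(analytic_trace(bpm, 2.8, 96.8, phase = 1), 96.8)
    expect_lt(abs(br$bpm - bpm) / bpm, 0.05)
  }
})

test_that("ejection fraction follows the squared-diameter formula", {
  tr <- rep(c(100, 80), 50)
  b <- detect_beats(tr, 10)
  m <- beat_metrics(tr, b, 10, pixel_size_um = 1)
  expect_equal(m$ejection_fraction, (100^2 - 80^2) / 100^2)
  mc <- beat_metrics(rep(90, 100),
                     list(peak_times_s = numeric(0), n_beats = 0L,
                          bpm = NA_real_), 10)
  expect_equal(mc$ejection_fraction, 0)  # no contraction detected
  expect_equal(mc$d_max_um, mc$d_min_um)
  expect_true(is.na(mc$mean_beat_length_s))
})

test_that("metrics recovered from a rendered beating ventricle", {
  m <- heart_model(fhf_area_fraction = 0, heart_rate_bpm = 214.3,
                   contraction_fraction = 0.2, phase = 0)
  # noiseless video: diameter-derived metrics against the contraction model
  v0 <- render_video(m, 2.8, 96.8, "BFP", c(128, 128),
                     silent_noise(background_level = 400))
  thr0 <- calibrate_threshold(v0)
  v08 <- v0; v08$frames <- larvalheart:::rescale_to_8bit(v0$frames)
  ln <- chamber_line(c(12, 64), c(116, 64))
  tr0 <- extract_diameter_trace(build_kymograph(v08, ln), thr0)
  b0 <- detect_beats(tr0, 96.8)
  expect_equal(b0$n_beats, 10L)
  met <- beat_metrics(tr0, b0, 96.8, v0$pixel_size_um)
  # EF = 1 - (1 - c)^2 = 0.36; max/min diameter ratio = 1 / (1 - c)
  expect_equal(met$ejection_fraction, 0.36, tolerance = 0.10)
  expect_equal(max(tr0) / min(tr0[tr0 > 0]), 1 / 0.8, tolerance = 0.05)
  expect_equal(met$mean_beat_length_s, 60 / 214.3, tolerance = 0.02)
  expect_true(met$qt_s > 0 && met$qt_s < 60 / 214.3)
  expect_equal(met$qtc_s, met$qt_s + 0.154 * (1 - met$mean_beat_length_s),
               tolerance = 1e-9)

  # noisy video: beat count and chamber-line rotation robustness
  set.seed(21)
  v <- render_video(m, 2.8, 96.8, "BFP", c(128, 128),
                    noise_params(n_distractors = 0))
  thr <- calibrate_threshold(v)
  v8 <- v; v8$frames <- larvalheart:::rescale_to_8bit(v$frames)
  tr <- extract_diameter_trace(build_kymograph(v8, ln), thr)
  b <- detect_beats(tr, 96.8)
  expect_equal(b$n_beats, 10L)
  # rotating the chamber line by +/- 10 degrees changes bpm by < 2%
  for (ang in c(-10, 10) * pi / 180) {
    r <- 52
    p1 <- c(64 - r * cos(ang), 64 - r * sin(ang))
    p2 <- c(64 + r * cos(ang), 64 + r * sin(ang))
    trr <- extract_diameter_trace(build_kymograph(v8, chamber_line(p1, p2)),
                                  thr)
    br <- detect_beats(trr, 96.8)
    expect_lt(abs(br$bpm - b$bpm) / b$bpm, 0.02)
  }
})

test_that("full cardiac driver returns one row per chamber", {
  m <- small_model(fhf_area_fraction = 0)
  set.seed(22)
  v <- render_video(m, 1.4, 96.8, "BFP", small_frame)
  out <- analyze_cardiac_function(
    v, list(chamber_line(c(8, 32), c(56, 32), "ventricle"),
            chamber_line(c(32, 12), c(32, 52), "atrium")))
  expect_equal(out$chamber, c("ventricle", "atrium"))
  expect_true(all(out$ejection_fraction >= 0 & out$ejection_fraction <= 1))
  expect_true(all(out$d_min_um <= out$d_max_um))
  expect_true(all(out$n_beats >= 2))
})
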