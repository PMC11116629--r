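# exhaustive between-class-variance scan: independent oracle for the
# histogram-split threshold
otsu_scan <- function(values, levels = 256) {
  h <- tabulate(pmin(pmax(round(values), 0), levels - 1) + 1, nbins = levels)
  p <- h / sum(h)
  best <- -Inf; best_t <- 0
  mu_total <- sum((seq_len(levels) - 1) * p)
  w0 <- 0; mu0 <- 0
  for (t in seq_len(levels - 1)) {
    w0 <- w0 + p[t]; mu0 <- mu0 + (t - 1) * p[t]
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    between <- (mu_total * w0 - mu0)^2 / (w0 * w1)
    if (between > best) { best <- between; best_t <- t - 1 }
  }
  best_t
}

noiseless_control <- function(model, t = 0.11, frames = 1) {
  # bimodal frame: background 10, compartments 100
  m <- model
  m$intensity <- list(bfp = 90, mcherry = 90, bulbus = 0, background = 10)
  arr <- array(0, c(small_frame, frames))
  for (k in seq_len(frames))
    arr[, , k] <- render_frame(m, t + (k - 1) * 0.01, "BFP", small_frame,
                               silent_noise(background_level = 10))
  video_stack(arr, 1.3, 96.8, "BFP")
}

test_that("calibrated threshold matches the between-class-variance oracle", {
  v <- noiseless_control(small_model(fhf_area_fraction = 0))
  thr <- calibrate_threshold(v)
  # reproduce the pooled smoothed provisional frame independently
  v8 <- round(255 * (v$frames - min(v$frames)) / diff(range(v$frames)))
  sm <- larvalheart:::smooth_gaussian(v8[, , 1], 2)
  expect_lte(abs(thr - otsu_scan(sm)), 1.5)
  # threshold separates the two modes strictly
  expect_gt(thr, 0)
  expect_lt(thr, 255)
  expect_error(calibrate_threshold(video_stack(array(7, c(8, 8, 2)), 1, 1)),
               "constant")
  expect_error(calibrate_threshold(list()), "empty")
})

test_that("noiseless full chain recovers analytic areas within 2%", {
  for (fhf in c(0, 0.55)) {
    m <- heart_model(fhf_area_fraction = fhf, heart_rate_bpm = 150, phase = 0,
                     intensity = list(bfp = 4000, mcherry = 4000, bulbus = 0,
                                      background = 400))
    v <- video_stack(array(
      render_frame(m, 0, "BFP", c(128, 128), silent_noise(background_level = 400)),
      c(128, 128, 1)), 1.3, 96.8, "BFP")
    thr <- calibrate_threshold(v)
    seg <- segment_ventricle(v, thr)
    ab <- heart_geometry_at(m, 0)
    truth <- (1 - fhf) * pi * ab["a"] * ab["b"]
    expect_equal(seg$area_px, truth, tolerance = 0.02, ignore_attr = TRUE)
    expect_equal(seg$area_um2, seg$area_px * 1.3^2)
  }
})

test_that("raising the threshold never increases the measured area", {
  set.seed(9)
  v <- render_video(small_model(), 0.3, 96.8, "BFP", small_frame)
  thr <- calibrate_threshold(v)
  areas <- vapply(c(thr - 30, thr, thr + 30, thr + 60),
                  function(t) segment_ventricle(v, t, frame_index = 5)$area_px,
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("systole frame minimizes the area trace, ties to earliest", {
  m <- small_model(heart_rate_bpm = 120, phase = 0)
  set.seed(10)
  v <- render_video(m, 1.0, 50, "BFP", small_frame, silent_noise())
  thr <- calibrate_threshold(v)
  idx <- select_systole_frame(v, thr)
  # analytic systole: sin = 1 at t = period/4; frames at (k-1)/50 s
  t_star <- (60 / 120) / 4
  expect_lte(abs(idx - (t_star * 50 + 1)), 2)
  trace <- attr(idx, "area_trace")
  expect_equal(trace[idx], min(trace))
  # tie-break: a constant video has all frames equal; earliest wins
  vc <- video_stack(array(rep(render_frame(m, 0, "BFP", small_frame,
                                           silent_noise()), 3),
                          c(small_frame, 3)), 1.3, 50, "BFP")
  expect_equal(as.integer(select_systole_frame(vc, thr)), 1L)
  # single frame video
  v1 <- video_stack(v$frames[, , 1, drop = FALSE], 1.3, 50, "BFP")
  expect_equal(as.integer(select_systole_frame(v1, thr)), 1L)
  # everything below threshold is an error
  expect_error(select_systole_frame(v1, 300), "below the threshold")
})

test_that("systole area never exceeds the maximum-area frame", {
  set.seed(11)
  v <- render_video(small_model(), 0.6, 96.8, "BFP", small_frame)
  thr <- calibrate_threshold(v)
  idx <- select_systole_frame(v, thr)
  trace <- attr(idx, "area_trace")
  a_sys <- segment_ventricle(v, thr, frame_index = as.integer(idx))$area_px
  a_dia <- segment_ventricle(v, thr, frame_index = which.max(trace))$area_px
  expect_lte(a_sys, a_dia)
})

test_that("largest-component rule discards bulbus and small blobs", {
  lbl <- matrix(0L, 40, 40)
  lbl[5:25, 5:25] <- 1L   # 441 px
  lbl[30:35, 30:35] <- 2L # 36 px
  kept <- exclude_bulbus(lbl)
  expect_equal(sum(kept), 441)
  expect_true(all(which(kept, arr.ind = TRUE) <= 25))
  # single component is the identity
  one <- matrix(FALSE, 10, 10); one[2:4, 2:4] <- TRUE
  expect_equal(exclude_bulbus(one), one)
  # polygon override removes the larger blob first
  poly <- cbind(c(4, 26, 26, 4), c(4, 4, 26, 26))
  kept2 <- exclude_bulbus(lbl, exclude_poly = poly)
  expect_equal(sum(kept2), 36)
  # empty input stays empty
  expect_equal(sum(exclude_bulbus(matrix(0L, 5, 5))), 0)
})

test_that("an attached-free bulbus leaves the ventricle area unchanged", {
  base <- list(bfp = 4000, mcherry = 4000, background = 400)
  m_b <- small_model(fhf_area_fraction = 0,
                     intensity = c(base, bulbus = 3500))
  m_0 <- small_model(fhf_area_fraction = 0, intensity = c(base, bulbus = 0))
  nz <- silent_noise(background_level = 400)
  v_b <- video_stack(array(render_frame(m_b, 0, "BFP", small_frame, nz),
                           c(small_frame, 1)), 1.3, 96.8, "BFP")
  v_0 <- video_stack(array(render_frame(m_0, 0, "BFP", small_frame, nz),
                           c(small_frame, 1)), 1.3, 96.8, "BFP")
  thr <- calibrate_threshold(v_0)
  seg_b <- segment_ventricle(v_b, thr)
  seg_0 <- segment_ventricle(v_0, thr)
  expect_equal(seg_b$area_px, seg_0$area_px, tolerance = 0.02)
})

test_that("empty frames give area 0 with a flag, and unit conversion holds", {
  fr <- matrix(0, 16, 16); fr[6:11, 6:11] <- 255
  v <- video_stack(array(fr, c(16, 16, 1)), 1.3, 96.8, "BFP")
  seg <- segment_ventricle(v, 100)
  expect_gt(seg$area_px, 0)
  # area in um^2 is always px * pixel_size^2 (10,000 px at 1.3 um -> 16,900)
  expect_equal(seg$area_um2, seg$area_px * 1.69)
  expect_equal(10000 * 1.3^2, 16900)
  blank <- video_stack(array(0, c(8, 8, 1)), 1.3, 96.8, "BFP")
  seg0 <- segment_ventricle(blank, 10)
  expect_equal(seg0$area_px, 0)
  expect_equal(seg0$flag, "empty")
})
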