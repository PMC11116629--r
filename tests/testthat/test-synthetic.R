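test_that("contraction model: identities and periodicity", {
  m0 <- small_model(contraction_fraction = 0)
  for (t in c(0, 0.1, 0.33, 1.7))
    expect_equal(unname(heart_geometry_at(m0, t)),
                 m0$diastolic_semi_axes)

  # sine at its maximum forces a = (1 - c) * a0
  m <- small_model(contraction_fraction = 0.2, heart_rate_bpm = 60, phase = 0)
  ab <- heart_geometry_at(m, 0.25)  # sin(2*pi*0.25) = 1
  expect_equal(unname(ab["a"]), 0.8 * m$diastolic_semi_axes[1], tolerance = 1e-12)
  expect_equal(unname(ab["b"]), 0.8 * m$diastolic_semi_axes[2], tolerance = 1e-12)

  # minimum over one period equals a0 * (1 - c)
  tt <- seq(0, 1, by = 1e-4)
  traj <- heart_geometry_at(m, tt)
  expect_equal(min(traj[, "a"]), 0.8 * m$diastolic_semi_axes[1], tolerance = 1e-6)

  # the default rate completes 10 full periods in a 2.8 s acquisition
  md <- heart_model()
  expect_equal(md$heart_rate_bpm / 60 * 2.8, 10, tolerance = 1e-3)
  p <- 60 / md$heart_rate_bpm
  expect_equal(heart_geometry_at(md, 0.3), heart_geometry_at(md, 0.3 + p),
               tolerance = 1e-9)
})

test_that("chord offset reproduces analytic sector area fractions", {
  # oracle: numeric integration of the unit-disc sector area
  for (f in c(0.25, 0.5, 0.55, 0.8)) {
    q <- fhf_chord_offset(f)
    xs <- seq(-1, q, length.out = 2e5)
    frac <- sum(2 * sqrt(pmax(0, 1 - xs^2))) * (q + 1) / 2e5 / pi
    expect_equal(frac, f, tolerance = 1e-3)
  }
  expect_equal(fhf_chord_offset(0), -1)
  expect_equal(fhf_chord_offset(1), 1)
  expect_equal(fhf_chord_offset(0.5), 0, tolerance = 1e-9)
})

test_that("noiseless renders match analytic compartment areas within 2%", {
  for (fhf in c(0, 0.55)) {
    for (t in c(0, 0.11)) {
      m <- heart_model(fhf_area_fraction = fhf, heart_rate_bpm = 150,
                       intensity = list(bfp = 100, mcherry = 100,
                                        bulbus = 0, background = 0))
      fr <- render_frame(m, t, "BFP", c(128, 128), silent_noise())
      ab <- heart_geometry_at(m, t)
      expect_equal(sum(fr > 0), (1 - fhf) * pi * ab["a"] * ab["b"],
                   tolerance = 0.02, ignore_attr = TRUE)
      fm <- render_frame(m, t, "mCherry", c(128, 128), silent_noise())
      if (fhf == 0) {
        expect_true(all(fm == 0))  # no FHF sector: all-background frame
      } else {
        expect_equal(sum(fm > 0), fhf * pi * ab["a"] * ab["b"],
                     tolerance = 0.02, ignore_attr = TRUE)
      }
    }
  }
})

test_that("distractors form separate components outside the ventricle", {
  m <- small_model(intensity = list(bfp = 100, mcherry = 100, bulbus = 0,
                                    background = 0))
  fr <- render_frame(m, 0, "BFP", small_frame,
                     silent_noise(n_distractors = 3,
                                  distractor_intensity = 50,
                                  distractor_radius = 3))
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fr > 0)))
  expect_gte(max(labels), 4)  # ventricle + 3 distractors
  # distractor pixels lie outside the ellipse
  out <- fr == 50
  xs <- col(out)[out]; ys <- row(out)[out]
  u <- (xs - 32) / 20; v <- (ys - 32) / 14
  expect_true(all(u^2 + v^2 > 1))
})

test_that("render rejects impossible geometry", {
  expect_error(render_frame(small_model(), 0, "BFP", c(-1, 64)), "positive")
  expect_error(render_frame(heart_model(), 0, "BFP", c(32, 32)), "too small")
})

test_that("cohort simulation: counts, naming and ground-truth invariants", {
  scn <- scenario(list(
    scenario_group("negative_control", 1, recombined = FALSE),
    scenario_group("not_ablated", 1),
    scenario_group("ablated", 1, ablated = TRUE,
                   ablation_survival_fraction = 0.03,
                   bfp_ratio_by_timepoint = c(TP1 = .45, TP2 = .65, TP3 = .85))),
    duration_s = 0.1, frame_rate_fps = 50, frame_shape = c(64, 64),
    heart = small_model(), seed = 5)
  out <- file.path(tempdir(), "lh-tiny-cohort")
  sim <- simulate_cohort(scn, out, force = TRUE)
  tifs <- list.files(out, pattern = "\\.tif$")
  expect_length(tifs, 3 * 3 * 2)         # groups x timepoints x channels
  expect_equal(nrow(sim$plate), 18)
  expect_equal(nrow(sim$ground_truth), 9) # one row per larva-timepoint
  expect_true(all(grepl("^[A-H][0-9]+_TP[123]_(BFP|mCherry)\\.tif$", tifs)))
  gt <- sim$ground_truth
  expect_true(all(gt$true_dmin_px <= gt$true_dmax_px))
  expect_true(all(gt$true_bfp_area_um2 >= 0))
  # wells persist across timepoints (longitudinal key)
  expect_equal(length(unique(gt$well)), 3)
  expect_true(all(table(gt$well) == 3))
  # refuses to clobber without force
  expect_error(simulate_cohort(scn, out), "force")
})

test_that("identical scenario and seed reproduce bit-identical videos", {
  scn <- scenario(list(scenario_group("g", 2)),
                  timepoints = "TP1", duration_s = 0.1, frame_rate_fps = 50,
                  frame_shape = c(64, 64), heart = small_model(), seed = 11)
  d1 <- file.path(tempdir(), "lh-det-1"); d2 <- file.path(tempdir(), "lh-det-2")
  s1 <- simulate_cohort(scn, d1, force = TRUE)
  s2 <- simulate_cohort(scn, d2, force = TRUE)
  h1 <- unname(tools::md5sum(sort(list.files(d1, "\\.tif$", full.names = TRUE))))
  h2 <- unname(tools::md5sum(sort(list.files(d2, "\\.tif$", full.names = TRUE))))
  expect_identical(h1, h2)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$plate[, setdiff(names(s1$plate), "path")],
                   s2$plate[, setdiff(names(s2$plate), "path")])
})

test_that("generator ground truth encodes the configured trajectory", {
  co <- get_test_cohort()
  gt <- co$sim$ground_truth
  target <- c(TP1 = 45, TP2 = 65, TP3 = 85)
  for (tp in names(target)) {
    nc <- gt$true_bfp_area_um2[gt$group == "negative_control" &
                                 gt$timepoint == tp]
    abl <- gt$true_bfp_area_um2[gt$group == "ablated" & gt$timepoint == tp]
    ratio <- 100 * mean(abl) / mean(nc)
    # Monte-Carlo error of a ratio of means at n = 24, CV 10%
    mc_se <- target[[tp]] * 0.10 * sqrt(2 / 24)
    expect_lt(abs(ratio - target[[tp]]), 3 * mc_se)
    expect_lt(max(gt$true_mcherry_area_um2[gt$group == "ablated" &
                                             gt$timepoint == tp]),
              min(gt$true_mcherry_area_um2[gt$group == "not_ablated" &
                                             gt$timepoint == tp]))
  }
})
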