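# Shared fixtures. All synthetic data is generated in code at test time.

# small heart/frame for fast unit tests
small_model <- function(...) {
  heart_model(center_xy = c(32, 32), diastolic_semi_axes = c(20, 14),
              bulbus_offset_xy = c(0, -22), bulbus_radius = 4, ...)
}

silent_noise <- function(background_level = 0, gaussian_sd = 0,
                         n_distractors = 0, ...) {
  noise_params(background_level = background_level, gaussian_sd = gaussian_sd,
               n_distractors = n_distractors, ...)
}

small_frame <- c(64, 64)

# the paper-calibrated cohort shared by the acceptance tests; simulated once
# per test run (n = 24/group; 0.7 s acquisitions keep the suite fast while
# still covering >= 2 full beats, which is all the systolic readout needs)
.cohort_cache <- new.env(parent = emptyenv())
get_test_cohort <- function() {
  if (!is.null(.cohort_cache$res)) return(.cohort_cache$res)
  dir <- file.path(tempdir(), "lh-acceptance-cohort")
  scn <- default_scenario(n_larvae = 24, seed = 101, duration_s = 0.7)
  sim <- simulate_cohort(scn, dir, force = TRUE)
  plate <- load_plate(sim$plate_csv)
  thr_bfp <- calibrate_plate(plate, "BFP", "negative_control")
  thr_mch <- calibrate_plate(plate, "mCherry", "not_ablated")
  res <- list(
    scn = scn, sim = sim, plate = plate,
    thr_bfp = thr_bfp, thr_mch = thr_mch,
    areas_bfp = segment_plate(plate, "BFP", thr_bfp),
    areas_mch = segment_plate(plate, "mCherry", thr_mch))
  .cohort_cache$res <- res
  res
}
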