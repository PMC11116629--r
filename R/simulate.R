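#' Simulate a calibrated cohort of dual-channel beating-heart videos
#'
#' Generates one BFP and one mCherry multi-page TIFF per larva and timepoint,
#' a plate metadata CSV and a ground-truth CSV. Per-larva diastolic ventricle
#' area varies lognormally (CV `scenario$size_cv`) around the baseline
#' anatomy; the per-larva size multiplier, beat phase and distractor layout
#' are fixed across timepoints, mirroring longitudinal imaging of the same
#' animal in the same well. Group means of true BFP+ systolic area follow
#' each group's `bfp_ratio_by_timepoint` times the negative-control mean
#' (regrowth is rendered as a proportionally smaller all-BFP ventricle);
#' ablated larvae retain a surviving mCherry+ patch occupying
#' `ablation_survival_fraction` of their original FHF area.
#'
#' Identical `(scenario, seed)` pairs produce byte-identical outputs. The
#' session RNG state is restored on exit.
#'
#' @param scn a [scenario()].
#' @param out_dir output directory; must not already exist unless
#'   `force = TRUE`.
#' @param seed integer seed (defaults to `scn$seed`).
#' @param force overwrite an existing output directory.
#' @return (invisibly) a list with `plate_csv`, `ground_truth_csv`,
#'   `plate` and `ground_truth` data.frames.
#' @export
simulate_cohort <- function(scn, out_dir, seed = scn$seed, force = FALSE) {
  stopifnot(inherits(scn, "scenario"))
  if (dir.exists(out_dir) && !force)
    stop("output directory exists (use force = TRUE to overwrite): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  n_total <- sum(vapply(scn$groups, `[[`, integer(1), "n_larvae"))
  if (n_total > 96) stop("scenario exceeds a 96-well plate (", n_total, " larvae)")
  wells <- paste0(LETTERS[(seq_len(n_total) - 1) %/% 12 + 1],
                  (seq_len(n_total) - 1) %% 12 + 1)

  base <- scn$heart
  f_fhf <- base$fhf_area_fraction
  cfrac <- base$contraction_fraction
  sdlog <- sqrt(log(1 + scn$size_cv^2))
  px2 <- scn$pixel_size_um^2

  # draw all larva-level randomness up front in a fixed order so that the
  # render stream is independent of it
  larvae <- list(); idx <- 0L
  for (g in scn$groups) {
    for (j in seq_len(g$n_larvae)) {
      idx <- idx + 1L
      size_mult <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      phase <- runif(1, 0, 2 * pi)
      dxy <- default_distractor_xy(scn$noise$n_distractors, scn$frame_shape,
                                   base$center_xy)
      if (nrow(dxy) > 0)
        dxy <- dxy + matrix(runif(length(dxy), -4, 4), nrow(dxy))
      larvae[[idx]] <- list(well = wells[idx], group = g$name, grp = g,
                            axes = base$diastolic_semi_axes * sqrt(size_mult),
                            phase = phase, distractor_xy = dxy)
    }
  }

  meta <- list(); truth <- list(); row <- 0L
  for (lv in larvae) {
    g <- lv$grp
    noise_lv <- scn$noise
    noise_lv$distractor_xy <- lv$distractor_xy
    r1 <- if (!is.null(g$bfp_ratio_by_timepoint))
      g$bfp_ratio_by_timepoint[[scn$timepoints[1]]] else 1
    for (tp in scn$timepoints) {
      r_tp <- if (!is.null(g$bfp_ratio_by_timepoint))
        g$bfp_ratio_by_timepoint[[tp]] else 1
      r_adj <- r1 + g$effect_multiplier * (r_tp - r1)
      if (g$ablated) {
        axes_tp <- lv$axes * sqrt(r_adj)
        residual <- g$ablation_survival_fraction * f_fhf *
          ellipse_area(lv$axes[1], lv$axes[2])
        fhf_tp <- 0
      } else {
        axes_tp <- lv$axes * sqrt(r_adj)
        residual <- NULL
        fhf_tp <- if (g$recombined) f_fhf else 0
      }
      model <- heart_model(center_xy = base$center_xy,
                           diastolic_semi_axes = axes_tp,
                           contraction_fraction = cfrac,
                           heart_rate_bpm = base$heart_rate_bpm,
                           phase = lv$phase,
                           fhf_area_fraction = fhf_tp,
                           mcherry_residual_area = residual,
                           bulbus_offset_xy = base$bulbus_offset_xy,
                           bulbus_radius = base$bulbus_radius,
                           intensity = base$intensity)
      a_sys <- axes_tp[1] * (1 - cfrac); b_sys <- axes_tp[2] * (1 - cfrac)
      if (g$ablated) {
        bfp_sys <- ellipse_area(a_sys, b_sys)
        mch_sys <- residual * (1 - cfrac)^2
      } else if (g$recombined) {
        bfp_sys <- (1 - f_fhf) * ellipse_area(a_sys, b_sys)
        mch_sys <- f_fhf * ellipse_area(a_sys, b_sys)
      } else {
        bfp_sys <- ellipse_area(a_sys, b_sys)
        mch_sys <- 0
      }
      for (ch in c("BFP", "mCherry")) {
        vid <- render_video(model, duration_s = scn$duration_s,
                            frame_rate_fps = scn$frame_rate_fps,
                            channel = ch, frame_shape = scn$frame_shape,
                            noise = noise_lv,
                            pixel_size_um = scn$pixel_size_um)
        fn <- file.path(out_dir, paste0(lv$well, "_", tp, "_", ch, ".tif"))
        write_video(vid, fn)
        row <- row + 1L
        meta[[row]] <- data.frame(well = lv$well, group = lv$group,
                                  timepoint = tp, channel = ch, path = fn,
                                  pixel_size_um = scn$pixel_size_um,
                                  frame_rate_fps = scn$frame_rate_fps,
                                  stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        well = lv$well, group = lv$group, timepoint = tp,
        true_bfp_area_um2 = bfp_sys * px2,
        true_mcherry_area_um2 = mch_sys * px2,
        true_heart_rate_bpm = base$heart_rate_bpm,
        true_dmax_px = 2 * axes_tp[1],
        true_dmin_px = 2 * axes_tp[1] * (1 - cfrac),
        stringsAsFactors = FALSE)
    }
  }
  plate <- do.call(rbind, meta)
  gt <- do.call(rbind, truth)
  plate_csv <- file.path(out_dir, "plate.csv")
  gt_csv <- file.path(out_dir, "ground_truth.csv")
  write.csv(plate, plate_csv, row.names = FALSE)
  write.csv(gt, gt_csv, row.names = FALSE)
  invisible(list(plate_csv = plate_csv, ground_truth_csv = gt_csv,
                 plate = plate, ground_truth = gt))
}
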