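#' Define one experimental group of a synthetic cohort
#'
#' @param name group label (e.g. `"negative_control"`).
#' @param n_larvae number of larvae (>= 1).
#' @param recombined has the Cre switch fired (FHF expresses mCherry)?
#'   Negative-control larvae are not recombined: their whole ventricle stays
#'   BFP+ and carries no mCherry.
#' @param ablated was the prodrug applied (FHF pool killed)?
#' @param ablation_survival_fraction fraction of the mCherry+ pool surviving
#'   ablation (area fraction of the original FHF); ignored unless `ablated`.
#' @param bfp_ratio_by_timepoint named numeric, target ratio of this group's
#'   mean BFP+ systolic area to the negative-control mean at each timepoint.
#' @param effect_multiplier modifier applied to the regeneration increments
#'   after the first timepoint (1 = unmodified; < 1 emulates an
#'   anti-regenerative drug or crispant, > 1 a pro-regenerative one).
#' @return a list of class `scenario_group`.
#' @export
scenario_group <- function(name, n_larvae = 24, recombined = TRUE,
                           ablated = FALSE, ablation_survival_fraction = 1,
                           bfp_ratio_by_timepoint = NULL,
                           effect_multiplier = 1) {
  stopifnot(n_larvae >= 1)
  if (ablation_survival_fraction < 0 || ablation_survival_fraction > 1.5)
    stop("ablation_survival_fraction must be in [0, 1.5]")
  if (!is.null(bfp_ratio_by_timepoint) &&
      (any(bfp_ratio_by_timepoint < 0) || any(bfp_ratio_by_timepoint > 1.5)))
    stop("bfp ratios must be in [0, 1.5]")
  structure(list(name = name, n_larvae = as.integer(n_larvae),
                 recombined = recombined, ablated = ablated,
                 ablation_survival_fraction = ablation_survival_fraction,
                 bfp_ratio_by_timepoint = bfp_ratio_by_timepoint,
                 effect_multiplier = effect_multiplier),
            class = "scenario_group")
}

#' Synthetic-cohort scenario
#'
#' Bundles groups, timepoints, imaging geometry, heart anatomy and noise into
#' one validated configuration. Identical `(scenario, seed)` pairs reproduce
#' bit-identical videos and metadata.
#'
#' @param groups list of [scenario_group()]s.
#' @param timepoints character vector of timepoint labels.
#' @param duration_s,frame_rate_fps,pixel_size_um,frame_shape imaging
#'   parameters; defaults are the standard acquisition (2.8 s at 96.8 fps,
#'   1.3 um effective pixel after 2x2 binning, 128 x 128 frames).
#' @param heart a [heart_model()] giving the baseline anatomy shared by the
#'   cohort (per-larva sizes vary around it).
#' @param noise a [noise_params()].
#' @param size_cv lognormal coefficient of variation of per-larva diastolic
#'   ventricle area (default 10%).
#' @param seed default integer seed for [simulate_cohort()].
#' @return a list of class `scenario`.
#' @export
scenario <- function(groups, timepoints = c("TP1", "TP2", "TP3"),
                     duration_s = 2.8, frame_rate_fps = 96.8,
                     pixel_size_um = 1.3, frame_shape = c(128, 128),
                     heart = heart_model(), noise = noise_params(),
                     size_cv = 0.10, seed = 1L) {
  stopifnot(length(groups) >= 1, length(timepoints) >= 1)
  if (!all(vapply(groups, inherits, logical(1), "scenario_group")))
    stop("groups must be a list of scenario_group objects")
  if (duration_s * frame_rate_fps < 2)
    stop("duration_s * frame_rate_fps must cover at least 2 frames")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("group names must be unique")
  for (g in groups) {
    if (!is.null(g$bfp_ratio_by_timepoint)) {
      miss <- setdiff(timepoints, names(g$bfp_ratio_by_timepoint))
      if (length(miss))
        stop("group ", g$name, " lacks bfp ratio for: ",
             paste(miss, collapse = ", "))
    }
  }
  names(groups) <- nm
  structure(list(groups = groups, timepoints = timepoints,
                 duration_s = duration_s, frame_rate_fps = frame_rate_fps,
                 pixel_size_um = pixel_size_um,
                 frame_shape = as.integer(frame_shape),
                 heart = heart, noise = noise, size_cv = size_cv,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' The calibrated default scenario
#'
#' Three groups of an ablation-regeneration experiment:
#' \describe{
#'   \item{negative_control}{not recombined; whole ventricle BFP+, no
#'     mCherry.}
#'   \item{not_ablated}{recombined, prodrug withheld; intact mCherry+ FHF
#'     sector (~55% of ventricular area) plus BFP+ SHF remainder.}
#'   \item{ablated}{recombined and ablated; 3% of the mCherry+ pool survives
#'     (a 97% loss) and the BFP+ pool regrows the ventricle from 45% of the
#'     negative-control mean at TP1 through 65% (TP2) to 85% (TP3).}
#' }
#'
#' @param n_larvae larvae per group (default 24, one 96-well plate condition).
#' @param seed default seed.
#' @param ... overrides passed on to [scenario()] (e.g. `duration_s`).
#' @return a [scenario()].
#' @export
default_scenario <- function(n_larvae = 24, seed = 1L, ...) {
  ratios_ctrl <- c(TP1 = 1, TP2 = 1, TP3 = 1)
  groups <- list(
    scenario_group("negative_control", n_larvae, recombined = FALSE,
                   bfp_ratio_by_timepoint = ratios_ctrl),
    scenario_group("not_ablated", n_larvae, recombined = TRUE,
                   bfp_ratio_by_timepoint = ratios_ctrl),
    scenario_group("ablated", n_larvae, recombined = TRUE, ablated = TRUE,
                   ablation_survival_fraction = 0.03,
                   bfp_ratio_by_timepoint = c(TP1 = 0.45, TP2 = 0.65,
                                              TP3 = 0.85))
  )
  scenario(groups, seed = seed, ...)
}

#' Read a scenario from a YAML or JSON file
#'
#' The file mirrors the [scenario()] constructor: top-level keys
#' `timepoints`, `duration_s`, `frame_rate_fps`, `pixel_size_um`,
#' `frame_shape`, `size_cv`, `seed`, optional `heart` and `noise` blocks
#' (fields as in [heart_model()] / [noise_params()]) and a `groups` list
#' whose entries hold [scenario_group()] fields.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return a [scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$groups)) stop("scenario file must define groups")
  groups <- lapply(raw$groups, function(g) {
    ratios <- if (!is.null(g$bfp_ratio_by_timepoint))
      unlist(g$bfp_ratio_by_timepoint) else NULL
    scenario_group(name = g$name,
                   n_larvae = g$n_larvae %||% 24,
                   recombined = g$recombined %||% TRUE,
                   ablated = g$ablated %||% FALSE,
                   ablation_survival_fraction =
                     g$ablation_survival_fraction %||% 1,
                   bfp_ratio_by_timepoint = ratios,
                   effect_multiplier = g$effect_multiplier %||% 1)
  })
  heart <- if (is.null(raw$heart)) heart_model() else
    do.call(heart_model, lapply(raw$heart, unlist))
  noise <- if (is.null(raw$noise)) noise_params() else
    do.call(noise_params, raw$noise)
  scenario(groups,
           timepoints = raw$timepoints %||% c("TP1", "TP2", "TP3"),
           duration_s = raw$duration_s %||% 2.8,
           frame_rate_fps = raw$frame_rate_fps %||% 96.8,
           pixel_size_um = raw$pixel_size_um %||% 1.3,
           frame_shape = raw$frame_shape %||% c(128, 128),
           heart = heart, noise = noise,
           size_cv = raw$size_cv %||% 0.10,
           seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
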