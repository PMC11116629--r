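#' Parametric beating-heart model
#'
#' Geometric model of a larval ventricle imaged ventrally: an ellipse whose
#' semi-axes contract sinusoidally at the heart rate. The ventricle is split
#' into a first-heart-field (FHF, mCherry+) sector and a second-heart-field
#' (SHF, BFP+) remainder by a chord placed so that the FHF sector occupies
#' `fhf_area_fraction` of the ellipse area. A bulbus arteriosus disc with weak
#' BFP signal sits offset from the ventricle. At 6 dpf the FHF pool is the
#' larger portion of the ventricle (~55% of its area), which is the default.
#'
#' Both semi-axes share a phase and contract by the same relative amount, so
#' the compartment area fractions are constant over the beat and the
#' instantaneous area is periodic with period `60/heart_rate_bpm` seconds.
#' The default heart rate of 214.3 beats/min yields exactly 10 beats in a
#' standard 2.8 s acquisition.
#'
#' @param center_xy numeric(2), ellipse center in pixels (x, y), 1-based.
#' @param diastolic_semi_axes numeric(2), semi-axes (a0, b0) at full diastole,
#'   pixels. Defaults correspond to a ~114 x 78 um ventricle at 1.3 um/px.
#' @param contraction_fraction fractional reduction of both semi-axes at peak
#'   systole, in `[0, 1)`.
#' @param heart_rate_bpm heart rate, beats per minute.
#' @param phase beat phase offset, radians.
#' @param fhf_area_fraction share of ventricular area occupied by the mCherry+
#'   FHF sector, in `[0, 1]`. Use 0 for non-recombined (all-BFP) hearts.
#' @param mcherry_residual_area after ablation the mCherry+ pool survives only
#'   as a compact patch of cells; diastolic area of that patch in px^2, or
#'   `NULL` for an intact FHF sector. When set, `fhf_area_fraction` is ignored
#'   for the mCherry channel and the BFP compartment fills the whole ellipse.
#' @param bulbus_offset_xy offset of the bulbus disc center from the ventricle
#'   center, pixels.
#' @param bulbus_radius bulbus disc radius, pixels.
#' @param intensity named list of mean fluorophore intensities (16-bit
#'   arbitrary units): `bfp`, `mcherry`, `bulbus` (weak BFP in the bulbus) and
#'   `background`.
#' @return an object of class `heart_model`.
#' @examples
#' m <- heart_model()
#' heart_geometry_at(m, 0)
#' @export
heart_model <- function(center_xy = c(64, 64),
                        diastolic_semi_axes = c(44, 30),
                        contraction_fraction = 0.2,
                        heart_rate_bpm = 214.3,
                        phase = 0,
                        fhf_area_fraction = 0.55,
                        mcherry_residual_area = NULL,
                        bulbus_offset_xy = c(0, -44),
                        bulbus_radius = 9,
                        intensity = list(bfp = 4000, mcherry = 4000,
                                         bulbus = 1200, background = 400)) {
  stopifnot(length(center_xy) == 2, length(diastolic_semi_axes) == 2)
  if (any(diastolic_semi_axes <= 0))
    stop("diastolic semi-axes must be strictly positive")
  if (contraction_fraction < 0 || contraction_fraction >= 1)
    stop("contraction_fraction must be in [0, 1)")
  if (heart_rate_bpm <= 0) stop("heart_rate_bpm must be positive")
  if (fhf_area_fraction < 0 || fhf_area_fraction > 1)
    stop("fhf_area_fraction must be in [0, 1]")
  if (!is.null(mcherry_residual_area) && mcherry_residual_area < 0)
    stop("mcherry_residual_area must be non-negative")
  needed <- c("bfp", "mcherry", "bulbus", "background")
  if (!all(needed %in% names(intensity)))
    stop("intensity must name: ", paste(needed, collapse = ", "))
  structure(list(center_xy = as.numeric(center_xy),
                 diastolic_semi_axes = as.numeric(diastolic_semi_axes),
                 contraction_fraction = contraction_fraction,
                 heart_rate_bpm = heart_rate_bpm,
                 phase = phase,
                 fhf_area_fraction = fhf_area_fraction,
                 mcherry_residual_area = mcherry_residual_area,
                 bulbus_offset_xy = as.numeric(bulbus_offset_xy),
                 bulbus_radius = bulbus_radius,
                 intensity = intensity),
            class = "heart_model")
}

#' @export
print.heart_model <- function(x, ...) {
  cat("<heart_model>\n")
  cat(sprintf("  diastolic semi-axes : %.1f x %.1f px\n",
              x$diastolic_semi_axes[1], x$diastolic_semi_axes[2]))
  cat(sprintf("  contraction fraction: %.2f\n", x$contraction_fraction))
  cat(sprintf("  heart rate          : %.1f bpm\n", x$heart_rate_bpm))
  cat(sprintf("  FHF area fraction   : %.2f\n", x$fhf_area_fraction))
  if (!is.null(x$mcherry_residual_area))
    cat(sprintf("  mCherry residual    : %.1f px^2 (ablated)\n",
                x$mcherry_residual_area))
  invisible(x)
}

#' Instantaneous ellipse semi-axes
#'
#' Semi-axes of the contracting ventricle at time `t`:
#' `a(t) = a0 * (1 - c * (1 + sin(2*pi*f*t + phi)) / 2)` with
#' `f = heart_rate_bpm / 60` and analogously for `b(t)`. The minimum over one
#' period is `a0 * (1 - c)` (peak systole), the maximum `a0` (full diastole).
#'
#' @param model a [heart_model()].
#' @param t time in seconds (vectorized); `t >= 0`.
#' @return if `t` is scalar, a named numeric(2) `c(a, b)`; otherwise a matrix
#'   with columns `a` and `b`.
#' @export
heart_geometry_at <- function(model, t) {
  stopifnot(inherits(model, "heart_model"), all(t >= 0))
  f <- model$heart_rate_bpm / 60
  scale <- 1 - model$contraction_fraction *
    (1 + sin(2 * pi * f * t + model$phase)) / 2
  a <- model$diastolic_semi_axes[1] * scale
  b <- model$diastolic_semi_axes[2] * scale
  if (length(t) == 1L) c(a = a, b = b) else cbind(a = a, b = b)
}

#' Chord offset delimiting an elliptical sector of given area fraction
#'
#' The FHF/SHF boundary is a chord perpendicular to the major axis. In
#' normalized coordinates (`u = (x - cx) / a`) the sector `u <= q` of the unit
#' disc has area fraction `1 - (acos(q) - q * sqrt(1 - q^2)) / pi`; the same
#' fraction holds for the ellipse because the affine map preserves area
#' ratios. This solves for `q` given the fraction.
#'
#' @param fraction target area fraction in `[0, 1]`.
#' @return chord offset `q` in `[-1, 1]`.
#' @keywords internal
#' @export
fhf_chord_offset <- function(fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(-1)
  if (fraction == 1) return(1)
  frac_of_q <- function(q) 1 - (acos(q) - q * sqrt(1 - q^2)) / pi
  stats::uniroot(function(q) frac_of_q(q) - fraction,
                 interval = c(-1, 1), tol = 1e-12)$root
}

# analytic areas used by ground truth and oracle tests
ellipse_area <- function(a, b) pi * a * b

systolic_semi_axes <- function(model) {
  model$diastolic_semi_axes * (1 - model$contraction_fraction)
}
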