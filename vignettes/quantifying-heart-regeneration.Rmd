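---
title: "Quantifying larval heart regeneration: models, parameters and design choices"
author: "larvalheart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval heart regeneration}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larvalheart)
```

## The assay and what the package measures

Genetic ablation of the first-heart-field (FHF) cardiomyocyte pool — the
mCherry-labelled ~55% of the larval ventricle after Cre recombination —
produces a reproducible cardiac injury. The surviving BFP+ second-heart-field
(SHF) pool regrows the ventricle over three days; imaging each larva ventrally
in its 96-well position at three timepoints (TP1 = 0 dpi, TP2 = 1 dpi,
TP3 = 3 dpi) yields the regeneration-kinetics readout: the BFP+ ventricular
area at systole, normalized so the negative-control group mean is exactly 100
at each timepoint.

The package implements the full measurement chain (segmentation, kinetics,
kymograph-based cardiac function, statistics) together with a synthetic video
generator calibrated to the assay's reported effect sizes, so that every stage
can be validated against ground truth without microscope data.

## The synthetic heart model

The ventricle is modelled as an ellipse whose semi-axes contract
sinusoidally and in phase:

$$a(t) = a_0\,\Big(1 - c\,\tfrac{1 + \sin(2\pi f t + \varphi)}{2}\Big),$$

and identically for $b(t)$, with $f$ the heart rate in Hz and $c$ the
contraction fraction. This is deliberately the simplest periodic model with
analytic extrema: the systolic minimum is $a_0 (1 - c)$, the instantaneous
area $\pi a(t) b(t)$ is periodic with period $60/\mathrm{bpm}$ seconds, and
because both axes share the same relative contraction, compartment *area
fractions* are constant over the beat. Real ventricular wall motion is
asymmetric and peristaltic; none of the downstream readouts depend on that
asymmetry, so it is not modelled.

The FHF/SHF partition is a chord perpendicular to the major axis placed so
the FHF sector occupies `fhf_area_fraction` of the ellipse (default 0.55,
the FHF share of the 6 dpf ventricle). The true anatomy is 3-D and
interdigitated — a declared simplification. A bulbus arteriosus disc with
weak BFP signal sits offset from the ventricle (the protocol explicitly
discards bulbus signal), and autofluorescent "distractor" discs with
sub-threshold intensity emulate the off-target structures a correct
threshold must exclude.

Key defaults, with rationale:

| parameter | default | why |
|---|---|---|
| heart rate | 214.3 bpm | 10 full beats in a standard 2.8 s acquisition |
| acquisition | 2.8 s @ 96.8 fps, 1.3 µm/px | the platform's video settings (2×2 binning) |
| diastolic semi-axes | 44 × 30 px (114 × 78 µm) | realistic 6 dpf ventricle; sized so the smallest rendered structure (the 3% surviving mCherry patch, r ≈ 3.7 px) spans multiple widths of the mandated σ = 2 px blur |
| contraction fraction | 0.2 | mid-range fractional shortening; gives EF = 1 − 0.8² = 0.36 |
| FHF area fraction | 0.55 | FHF share of ventricular area at 6 dpf |
| ablation survival | 0.03 | 97% loss of the mCherry+ pool after ablation |
| BFP ratios | 0.45 / 0.65 / 0.85 | regeneration trajectory vs negative control at TP1/TP2/TP3 |
| n per group | 24 | one 96-well-plate condition |
| inter-larva size CV | 10% (lognormal, on area) | plausible biological variability; not reported for the real assay |
| noise SD | 5% of compartment intensity | declared, not inferred — real SNR is unpublished |

A scientific point about the surviving mCherry+ pool: ablation leaves ~3% of
the mCherry+ *cells*, so the generator renders a compact full-intensity patch
occupying 3% of the original FHF area (contracting with the heart), rather
than scaling the mCherry intensity down by 97% — an intensity at 3% of
normal would sit below any control-calibrated threshold and the measured
loss would saturate at 100%, which is not what the assay reports.

The generator does **not** render pericardial edema, gross larval morphology,
3-D optics or a PSF, photobleaching, motion blur, or larval dropout. Passing
tests on synthetic cohorts therefore demonstrate that the measurement chain
is correct and well-calibrated on data satisfying the model's assumptions —
they cannot certify performance on real videos with out-of-model artifacts
(debris touching the ventricle, failed autofocus, edema displacing the
heart).

## Segmentation: automating the stated protocol

The protocol picks the systole frame, converts to 8-bit, applies a Gaussian
blur (σ = 2), thresholds at a value chosen from negative-control larvae of
the same timepoint, and measures the ROI in µm², discarding bulbus signal.
Design decisions where the protocol left freedom:

* **Threshold rule.** Humans set thresholds by eye; reproducibility demands
  an algorithmic default. We pool the σ-smoothed provisional systole frames
  of the control videos (provisional systole = minimum total intensity) and
  maximize between-class variance over the 256-bin histogram — an exhaustive
  Otsu scan, written in the package and cross-checked in the tests against an
  independently coded scan. A manual `threshold` override preserves
  faithfulness to the original workflow. The calibrated threshold sits
  slightly below the half-maximum level, which dilates masks by a fraction of
  a pixel; normalization cancels most of the resulting bias (it is shared by
  numerator and denominator groups).
* **Systole selection** uses the per-frame above-threshold area of the
  largest connected component (ties → earliest frame), not raw intensity;
  the protocol only states that the systolic minimum is measured.
* **Bulbus exclusion** is the largest-component rule, with an optional
  user polygon subtracted first (the manual protocol discards the bulbus by
  hand).
* **8-bit conversion** is a per-video min–max rescale (mirroring the "convert
  to 8-bit" step); it is lossy and documented as such. σ = 2 is interpreted
  in pixels of the stored (binned) image.
* **Degenerate inputs**: an empty mask is reported as area 0 with a flag
  rather than an error — an ablated mCherry channel legitimately has almost
  no signal. Constant-intensity calibration frames are an error (no split
  exists).
* **Indexing**: frame indices and pixel coordinates are 1-based, the R
  convention.

Known numerical behaviour, quantified in the tests: large compartments are
recovered to well under 2% of their analytic areas (noiseless) and ~5% with
default noise; structures only a few pixels across are systematically eroded
by the σ = 2 blur plus thresholding (the 3%-of-FHF surviving patch measures
~75–85% of its true area). That erosion is real segmentation physics, not a
bug; at the default anatomy it keeps the measured ablation loss within the
reported 97 ± 2 band.

## Kinetics and statistics

Normalization divides by the mean of non-outlier control areas per
timepoint, pinning the control mean to exactly 100 (assertable, and
asserted). ROUT (Q = 1%) outlier flagging runs per group × timepoint
*before* normalization statistics, matching how Prism users remove outliers
and then analyze; whether the original normalization excluded flagged
controls is unstated — excluding is our declared default. Larvae lost across
timepoints keep `NA` gaps, never imputed.

ROUT is implemented for the constant model (robust location via an
iteratively reweighted Lorentzian fit; RSDR from the 68.27th percentile of
absolute residuals scaled by $n/(n-K)$, $K = 1$; t-probabilities tested
outside-in against the FDR schedule $Q(n-i+1)/n$). Full
nonlinear-regression ROUT is out of scope — applied to kinetics columns the
fit *is* a location.

The two-way ANOVA uses Type-II sums of squares: the real layouts are
unbalanced (dropout), the original analysis says only "ordinary two-way
ANOVA", and Type-II is the better-powered convention for testing main
effects in that case; Type-III is available behind `ss_type = 3`.
Tukey–Kramer comparisons use the studentized-range distribution with the
Kramer unequal-n adjustment and the full-model residual mean square, applied
within each timepoint. The t-test is pooled-variance (the Prism default),
with Welch behind a flag. Normality of residuals is checked by
Anderson–Darling and Shapiro–Wilk, advisory only, reported as missing below
n = 8.

## Cardiac function from kymographs

Chamber positions are user-supplied lines (semi-automatic, as in the
original workflow; no automatic chamber detection). The kymograph samples
each frame bilinearly at unit spacing; the diameter trace is the outermost
above-threshold extent per frame, median-filtered over 3 frames. Beat
detection is autocorrelation-guided peak finding (dominant period from the
first off-zero autocorrelation maximum; peaks need topographic prominence
≥ 25% of the trace amplitude and separation ≥ 0.4 periods) — more tolerant
of mild arrhythmia than a Fourier estimate. With $n$ beats,
$\mathrm{bpm} = 60(n-1)/(t_n - t_1)$.

The reference implementation of these readouts is proprietary and its
formulas unpublished, so two of them are declared substitutes and labelled
as such in the outputs: ejection fraction is the single-plane approximation
$(d_{max}^2 - d_{min}^2)/d_{max}^2$ with robust (2nd/98th percentile)
extrema, and the "linearly corrected QT interval" is an additive linear rate
correction $QT_c = QT + 0.154\,(1 - RR)$ (Framingham-style slope,
configurable), with QT measured between the trace falling below and
returning above 90% of the local diastolic diameter.

## Problem sizes and reproducibility

Validation cohorts use n = 24 per group in three groups and three
timepoints (432 videos). For cohort-scale runs the acquisition is shortened
to 0.7 s (68 frames, ≥ 2 full beats): the systolic-area readouts are
invariant to duration once a full beat is recorded, and this keeps a full
simulate→segment→normalize→test cycle at a few minutes on one core. The
beat-counting validation always uses the full 2.8 s acquisition, where the
default-rate heart completes exactly 10 beats. Gaussian smoothing is a
separable truncated-kernel convolution (border-renormalized), roughly 5×
faster than FFT-based filtering at this frame size.

Every stochastic step runs off a single integer seed: identical
(scenario, seed) pairs produce byte-identical videos, metadata and stage
outputs (hash-checked in the tests). `scripts/acceptance.R --seed N --out f`
re-runs the whole validation from scratch. Plain multi-page 16-bit TIFF is
the native video format; pixel size and frame rate travel in the plate CSV
(supplied arguments always win over embedded tags), and OME-XML metadata is
not written.

## Limitations

* The generator's variance components (size CV, noise SD) are declared
  choices, not estimates from real data; recovery tolerances quoted in the
  tests are calibrated to those choices.
* Segmentation of structures at the scale of the blur kernel is biased low
  (quantified above); the pipeline should not be trusted for objects smaller
  than ~3× the smoothing σ without recalibration.
* EF and QTc are approximations standing in for unpublished reference
  formulas; compare trends, not absolute values, against other tools.
* Cross-sectional statistics only: timepoints are analyzed independently,
  matching the original workflow; no mixed-model longitudinal inference.
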