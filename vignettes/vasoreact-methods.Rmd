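---
title: "Methods: models, parameters and design choices in vasoreact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in vasoreact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoreact)
```

This vignette documents the models behind each processing stage, the
parameters a user may want to touch (with units and defaults), what the
synthetic generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. Spectral inversion

The imaging model assumes that changes in oxy- and deoxyhemoglobin are
the dominant sources of attenuation change in diffuse reflectance at
568 nm and 630 nm. Per pixel and frame,

$$\begin{bmatrix}\Delta[\mathrm{HbO_2}](t)\\ \Delta[\mathrm{HbR}](t)\end{bmatrix}
= E^{-1}\begin{bmatrix}\ln(R_{568}(0)/R_{568}(t))/L_{568}\\
\ln(R_{630}(0)/R_{630}(t))/L_{630}\end{bmatrix},$$

with $E$ the 2×2 molar-extinction matrix. Choices made here:

* **Baseline reference $R(0)$** is the temporal mean over the whole
  baseline window rather than the first frame: with multiplicative
  noise of relative sd $\sigma$, averaging $m$ baseline frames reduces
  the reference error by $\sqrt{m}$ and removes a systematic bias that a
  single noisy frame would imprint on every later time point.
* **Pathlengths** default to $L = 1$ cm for both wavelengths, so
  concentration changes come out in arbitrary units. All reactivity
  metrics are percent-of-baseline quantities and are invariant to this
  scale. True differential pathlength factors can be supplied.
* **Extinction defaults** are the standard compiled whole-blood values
  (568 nm: 44496 / 42736; 630 nm: 610 / 5148.8 L mol⁻¹ cm⁻¹ for
  HbO₂/HbR). The inversion only requires the matrix to be well
  conditioned; `extinction_set()` rejects singular matrices explicitly.
* **Percent normalization.** Whether the percent trace is normalized to
  a per-compartment baseline [HbT] or to a global one is exposed through
  the `baseline_hbt` argument of `roi_timeseries()`; synthetic cohorts
  generate percent traces directly, so group statistics do not depend
  on this choice.

The artery/vein hint (`vessel_class_hint()`) exploits the strong HbR
absorbance at 630 nm: venous ROIs show a larger 630/568 baseline
absorbance ratio. It is advisory; explicit labels always win.

## 2. Reactivity metrics

All three metrics operate on a smoothed trace (centered moving average,
default 30 s; `smooth_window = 0` disables it). Smoothing stabilizes
minimum and crossing detection on noisy traces; the closed-form test
cases are run unsmoothed so they hit their analytic values.

* **Peak response** (%) — minimum of the smoothed trace after the
  stimulus. Measured on the smoothed trace by default because a raw
  minimum is biased low by the noise floor; the residual bias of the
  smoothed minimum (≈ −0.2% at the default noise level) is well inside
  the group SEMs it is compared against.
* **Recovery time** (min) — first time after the nadir at which the
  smoothed trace rises above (baseline mean − k·baseline sd) and stays
  there for at least `dwell` = 60 s. The band width k (default 1) and
  the dwell are the genuinely free parameters of this stage: the source
  definition ("return to the range of baseline") does not pin down a
  band, so both are configuration keys. Baseline statistics come from
  the raw pre-stimulus samples (or can be supplied), so the band does
  not shrink when the smoothing window changes. A trace that never
  leaves the band reports RT = 0 with a "no response" note; one that
  never returns reports the record length with `recovered = FALSE`.
* **Integrated reactivity** (%·min) — signed trapezoidal area of the
  smoothed trace from the stimulus to RT, endpoint interpolated. Units
  are declared %·min (reported elsewhere as a.u.).

Group comparisons use the pooled-variance two-tailed t-test and, for
sex effects, a two-way ANOVA with Type-II sums of squares. Type II was
chosen because the cohorts are only near-balanced (4/6 animals per sex
per group); with balanced cells Type I/II/III coincide, so the choice
costs nothing in the balanced case. The Bonferroni family is the four
pairwise sex×group comparisons per metric.

## 3. Doppler velocimetry

`phase_difference()` implements the phase-subtraction method: the
Doppler phase is the argument of the conjugate product of adjacent
A-scans, phasor-averaged over a running window (default 4 pairs —
averaging in the complex domain, not on wrapped angles, so values near
±π do not cancel). `phase_to_velocity()` applies
$v = \lambda_0\,\Delta\varphi/(4\pi n T \cos\theta)$ with defaults
λ₀ = 0.00131 mm, n = 1.38, T = 0.000167 s (a 6k A-lines/s line rate)
and θ = 0. Choices:

* **θ = 0 globally**, with a per-vessel override, because cortical
  penetrating flow is near-axial but individual vessels are oblique.
* **Wrapping**: phases are wrapped to (−π, π], flagged when |Δφ|
  exceeds 0.8π, and never unwrapped by default — true wrap detection
  from a single pair product is impossible, so the flag is a
  conservative advisory and unwrapping is opt-in.
* **ROI statistic**: per-ROI mean phase by default; a `"max"` option
  exists because the velocity equation is sometimes quoted with the
  maximum phase shift of a vessel cross-section.
* Vessels whose mean |v| falls below 0.01 mm/s are reported as 0 with
  an occlusion-like flag rather than as a small noisy number.

`axial_resolution()` evaluates the coherence length
$L_c = 2\ln 2\,\lambda^2/(\pi\,\Delta\lambda_{FWHM})$ (3.44 µm in air at
1310/220 nm; 2.49 µm in tissue at n = 1.38) and
`transverse_resolution()` the diffraction-limited spot 0.61 λ/NA
(≈ 3.2 µm at NA 0.25).

## 4. Morphology

The Frangi vesselness (β = 0.5, structureness scale c defaulting to half
the per-scale maximum) is computed from the σ²-normalized Hessian of the
Gaussian-smoothed image and maximized over scales. Small
(σ = 1–5 px) and large (σ = 5–25 px) passes are thresholded separately
— Otsu on the nonzero response by default, with a fixed-threshold
override — and unioned, because one scale range cannot serve both
capillaries and 80-px trunks. Two refinements follow:

* **Hole filling**: large flat-interior vessels respond mainly at their
  walls; enclosed holes in the union are filled.
* **Intensity refinement** (on by default): the vesselness response
  spills roughly one scale beyond thin vessels, so the merged mask is
  trimmed to pixels whose intensity clears an Otsu threshold computed
  over the mask neighbourhood. Vesselness localizes; intensity
  delineates. With it, bar phantoms of widths 5–80 px segment at
  IoU ≥ 0.9.

Diameters: the mask is thinned (two-subiteration thinning that
preserves connectivity and endpoints) and each centerline pixel gets
φ = 2·EDT − 1 pixels, which is exact for odd-width axis-aligned bars
and within 1 px at 45°. The 3×1 median despeckler's orientation (along
the fast-scan axis) is a configuration key since scan geometry varies.
Vessel order labels (1st/2nd) are supplied by the user — automated
branch-topology ordering is out of scope — and per-order summaries are
mean ± SEM with pooled t-tests. Diameters are measured on 2D maximum
intensity projections; a 3D path is deliberately not implemented.

## 5. Density mapping

`binarize_skeletonize()` reuses the vesselness filter (small scales,
default σ = 1–3 px, aimed at capillaries) without the median despeckler
— a 3×1 median would erase structures one pixel wide, which is exactly
what a capillary skeleton is. `repair_skeleton()` closes gaps ≤ 2 px
with a 3×3 disk (configurable) and re-thins. The fill factor divides
the skeleton count in a w×w window (w = 60) by w², with zero padding:
off-image area contains no vessels, and the subsequent Gaussian
(σ = 3, reflective boundaries, mass-conserving away from borders)
stabilizes the border taper. The 0.00–0.15 scale is display clipping
only; statistics always use unclipped FF. Density ROIs are validated
against a diameter map: any ROI containing a vessel wider than 50 µm is
rejected rather than silently accepted.

## 6. Synthetic data: what it does and does not emulate

`gen_dwi_stack()` applies the exact Beer–Lambert forward model per
compartment (artery/vein/tissue, three disjoint ROIs each) with a
gamma-variate dip $h(u) = u^a e^{a(1-u)}$ ($u = t/t_{nadir}$,
$a = t_{nadir}/\tau$) and multiplicative Gaussian noise, and returns the
exact concentration fields used — enabling round-trip tests at 1e-9.
The frame interval defaults to 1 s per two-wavelength pair and the
epochs to 10 min baseline + 30 min post; only relative timing matters
to the metrics.

`gen_oct_phantom()` rasterizes straight or curved tubes (plug or
parabolic profiles; the parabolic lumen mean is v_max/2) with the
Doppler phase encoded per voxel and wrapped after encoding, so
downstream wrap handling is exercised; it warns when the encoding
violates Nyquist. Capillaries are smoothed 3D random walks rasterized
at 1-voxel width, added until the skeleton voxel fraction reaches its
target (within 10%). The angiogram is the structure mask with mild
multiplicative speckle — no interferogram, speckle-statistics or photon
transport simulation is attempted.

`gen_cohort()` draws per-animal true metrics from normal distributions
whose defaults are the published group values, treating the printed
dispersion as the per-animal sd of the draw. Reactivity triples are
then realized as actual noisy traces. A dip family needs enough freedom
to satisfy a drawn (peak, IR, RT) triple simultaneously: a one-τ
gamma-variate tail cannot — its area-to-peak ratio is capped near
$1/\ln(\mathrm{peak}/\mathrm{threshold}) \approx 0.29$, while the
published WT artery triple implies ≈ 0.60 — so cohort traces use a
rise–plateau–exponential dip (power-law rise over 1.5 min, plateau,
exponential release) whose plateau length and τ solve the triple in
closed form; infeasible draws are clamped to the nearest feasible
shape. Per-ROI noise is scaled so the per-class mean trace has the
configured baseline sd (default 0.5%), keeping the generator's
recovery-threshold definition and the estimator's measured baseline
band consistent.

Flow, diameter and density entries of a cohort are per-animal
measurement records, not rendered volumes: the published group
statistics summarize per-animal numbers, and the image-level paths are
exercised separately by the tube and capillary phantoms. Consequently,
passing cohort tests demonstrates correct metric extraction, statistics
and power at the stated effect sizes — not robustness to motion,
bulk-flow artifacts, segmentation errors on real angiograms, or any
physiology beyond the stated group distributions.

## 7. Numerical choices and problem sizes

* Moving averages and box counts use cumulative sums (exact integer
  counts for the fill factor); Gaussian smoothing is separable with
  reflective padding.
* Otsu thresholds are computed on the nonzero response only, since the
  zero background would otherwise dominate the histogram.
* The thinning pass runs until a fixed point; closing-then-rethinning
  makes `repair_skeleton()` idempotent on already-thin straight
  structures.
* Degenerate inputs fail loudly: singular extinction matrices,
  nonpositive reflectances (with the offending frame named), empty ROI
  masks, empty vessel masks, empty sex×group cells, zero pooled
  variance with unequal means.
* Test and validation problem sizes were chosen to exercise every path
  at comfortable margins on a single CPU: 24–32 px spectral phantoms,
  ~150 px angiograms, 200-seed Monte-Carlo runs at the published group
  sizes, and 500-animal cohorts for parameter-recovery means.

## 8. Known limitations

* Only the phase-subtraction Doppler reconstruction is implemented; the
  intensity-based variant sometimes used alongside it has no published
  formula to implement.
* No motion correction, bulk-phase correction, or registration between
  the wide-field and OCT coordinate frames (ROI and order labels are
  supplied by the user).
* Density and diameters are 2D-projection quantities; slab-wise 3D
  variants are not implemented.
* The cohort generator reproduces group-level distributions, not
  animal-level physiology; sex differences are not modelled by default
  (the two-way ANOVA machinery is exercised with configurable cohorts).
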