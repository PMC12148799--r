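---
title: "Phantom-based CBCT image quality analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based CBCT image quality analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package measures

Cone beam CT (CBCT) mounted on a treatment machine is used both to position
patients and, increasingly, to calculate dose directly on the daily image.
That second use stands or falls on two things: the scanner's mapping from
Hounsfield units (HU) to relative electron density (RED), and its basic
image quality — uniformity, contrast-to-noise, spatial resolution, geometric
fidelity. `cbctqa` implements a complete, automated analysis of both, built
around two standard phantoms:

* an **electron-density phantom**: an elliptical solid-water body
  (400 × 300 mm) holding sixteen 30 mm rods — ten inserts of known RED from
  0.28 (lung substitute) to 1.78 (cortical bone substitute) and six
  solid-water reference rods at RED 1.00;
* a **four-section cylindrical image-quality phantom** (200 mm diameter):
  a uniform slab, low-contrast rods (nominal 1%, 0.5%, 0.3%, about 10, 5
  and 3 HU), a geometry section (23° tilted-wire ramps, a 50 mm hole
  square, ten sensitometry targets, a 50 µm wire), and 1–5 lp/cm bar
  patterns.

Because clinical scanner data cannot ship with a package, `cbctqa` also
contains a voxel renderer for both phantoms. The renderer is first-class,
tested code: every analysis routine is validated against images whose ground
truth is known by construction.

## The metrics

**RED vs HU calibration.** A 10 mm radius circular ROI at each rod center,
averaged over five consecutive slices at the phantom's axial midpoint; the
across-slice standard deviation is the HU uncertainty. The six solid-water
rods are pooled into a single RED 1.00 point. Calibration curves are fit
piecewise — RED < 1 and RED ≥ 1 separately, the 1.00 reference belonging to
the high branch — by ordinary least squares of RED on HU, so slopes carry
the conventional 10⁻⁶ RED/HU units. Unweighted OLS is used deliberately:
point uncertainties differ (bone inserts spread several times more than
lung), but a weighting rule would be an invention; the high-branch intercept
landing within 1% of RED = 1 is a useful internal check of this convention.
Multi-site cohorts are screened for outliers with the maximum absolute
z-score using the sample (n−1) standard deviation — appropriate for the
small cohorts (~6 scanners) this screen targets — and the package reports
both defensible slope aggregations: mean ± sd of per-site slopes, and a
single pooled fit on all sites' points.

**Uniformity.** Three section-1 metrics, each computed per slice over the
five-slice section window with the across-slice sd as its uncertainty:

* radial uniformity `RU = mean(ROI_borders) − ROI_center` (four 10 mm
  border ROIs centered 20 mm in from the phantom edge);
* uniformity index `UI = 100 · RU / ROI_center` — note the ~10 HU
  background makes UI numerically volatile by construction;
* integral nonuniformity `InU = (Max − Min)/(Max + Min)` over centered
  vertical and horizontal profiles.

The InU profile conditioning is this package's own construction (the
formula itself says nothing about sampling): profiles span the central 80%
of the diameter, are smoothed with a 5-sample moving average before taking
extrema, and per-slice uncertainty is first-order propagation
`2·sqrt(Min²σ_Max² + Max²σ_Min²)/(Max+Min)²` with σ taken as the local sd
in each extremum's smoothing window.

**Contrast-to-noise ratio.** `CNR = (S_ROI − S_BKG) / ((σ_ROI + σ_BKG)/2)`
for the 15 mm diameter 1% and 0.5% rods, with background from two
same-sized ROIs 20 mm inward and outward of the rod along the radial
direction (their means averaged; σ_BKG the population sd of the pooled
voxels). The ROI radius defaults to 5 mm, strictly inside the rod: an ROI
larger than the target dilutes the measured contrast by the area ratio and
folds the rim transition into the noise term, which destroys the
interpretation of CNR as plateau-contrast over noise. The 0.3% set is
rendered but not scored by default — at these noise levels its
signal-to-noise ratio does not support a stable estimate.

**Slice thickness.** A wire inclined 23° to the axial plane crosses a slab
of thickness `t` over an in-plane run of `t/tan 23°`, so the full width at
half maximum (FWHM) of its bright trace, times `tan 23°`, recovers the
slice thickness. The FWHM uses linear interpolation between the samples
bracketing half maximum after median-baseline subtraction. Each of the four
ramps is measured on all five slices of the section window and averaged:
the trace advances a non-integer number of pixels per slice, so the window
samples different edge-to-grid phases and cancels the half-pixel
discretization any single slice exhibits (up to ~5% on a 2 mm slice at
1.05 mm pixels; under 1% after windowing). The reported uncertainty is the
sd over the four ramps. A `scale_by_tan = FALSE` flag exposes the raw trace
FWHM for anyone wanting the unscaled convention.

**Circular symmetry.** The four 3 mm air holes at the corners of the 50 mm
square are located per slice by intensity-weighted centroid (weight =
background − HU, clipped at zero) inside a 5 mm search disc around each
nominal corner; the mean of the four side lengths, averaged over the window,
is reported with the across-slice sd. Sub-pixel accuracy comes from the
centroid, not the grid: tests hold recovery to half a pixel across sub-pixel
phantom offsets.

**Sensitometry CT numbers.** 5 mm radius ROIs on each of the ten targets,
five-slice mean ± across-slice sd, labeled by material. Nominal values are
configurable generator inputs, not asserted truths.

**MTF.** A 10 mm square ROI is centered on the 50 µm wire; its two lateral
projections (column sums vs x, row sums vs y) are baseline-subtracted
(median of the ROI border pixels), recentered on their sub-pixel centroids,
averaged, zero-padded to 256 samples and Fourier-transformed; the magnitude,
normalized to 1 at zero frequency, is the MTF. Recentering is applied as an
exact phase shift in the frequency domain — resampling the projection onto
a shifted grid with linear interpolation would convolve a triangle kernel
into the spread function and bias the curve low. f50 and f10 are the first
crossings of 50% and 10%, linearly interpolated, with half the bracketing
frequency gap as uncertainty. On a 538 mm / 512 grid the Nyquist frequency
is 0.476 mm⁻¹; an f10 beyond that is reported as `NA` rather than
extrapolated.

**Line pairs.** For each bar set in increasing frequency, the profile
across the bars is taken on the single best slice of the window (largest
profile range — the one convention that does not use the five-slice window,
since averaging across slices would blur sub-pixel bar alignment). Peaks
and valleys come from `pracma::findpeaks` with a minimum spacing of 0.6
periods and a prominence floor of 10% of the profile range — a
user-independent stand-in for visual inspection. A set is resolved when the
expected number of bar peaks is found and the mean peak-to-valley
difference exceeds 30% of the maximum over baseline; scanning stops at the
first unresolved set.

## The synthetic volume generator

`render_aed()` and `render_catphan()` rasterize the layouts on the
protocol grid (512 × 512 over a 538 mm field of view; 206 mm and 154 mm
depths respectively, 2 mm slices for the reference protocols), then apply
an isotropic Gaussian blur and i.i.d. Gaussian noise in HU. Rendering is a
pure function of (configuration, layout): a seed fixes the volume exactly.

* **HU realism comes from measured medians, not physics.** The mapping
  from RED to HU is a piecewise-linear interpolation through the median HU
  measured across six institutions for the eleven inserts, one anchor set
  per tube potential (100/125/140 kVp). Beam-spectrum simulation is out of
  scope; the anchors are the only printed truth available, and they give
  the generator the correct protocol dependence (HU at RED 1.78 falls from
  1720 to 1380 HU as kVp rises).
* **Geometry.** Structures are rasterized with 5×5 supersampled area
  weighting at their edges. Sub-voxel structures are deposited preserving
  integrated signal; the 50 µm wire specifically is added *after* the
  scene blur with its exact analytic response — Gaussian point spread
  integrated over each pixel aperture — because depositing it first and
  convolving with a point-sampled kernel misrepresents the pixel aperture's
  transfer at high frequency.
* **Noise and blur defaults are tuning choices, documented as such.** No
  per-protocol noise figures are published. The defaults (20, 10, 5 HU for
  head / thorax / pelvis-large; other protocols scaled by 1/√mAs from
  thorax) were set once so the rendered 1%-rod CNR lands near the measured
  0.5 / 1 / 2, and the default point-spread sigma of 0.55 mm puts f50 near
  0.35 mm⁻¹ — qualitative realism, never asserted as equality in any test.
* **Layout positions are reconstructions.** Angular rod and target
  placements are not published as coordinates; the shipped defaults are
  editable reconstructions (YAML round-trip supported), and every analysis
  reads positions from the layout rather than hard-coding them. The MTF
  wire sits at (0.25, 0.25) mm — a generic sub-pixel position; (0, 0) lies
  exactly on a pixel corner of the default grid, a knife-edge alignment no
  physical setup would hold.
* **What is not emulated:** scatter, beam hardening, ring and motion
  artifacts, reconstruction (volumes are consumed downstream of it), streak
  noise correlations. Passing tests therefore demonstrate the correctness
  of the measurement pipeline on images with known truth, not robustness
  to every artifact a clinical CBCT can produce.

## Volume I/O and conventions

Volumes live in continuous physical millimetres: voxel `(i, j, k)` has its
center at `(index − 0.5) × spacing` from the grid corner. ROI membership is
voxel-center-in-disc with no partial-volume weighting — brute-force
checkable, and at a 10 mm radius on ~1.05 mm pixels the discretization
error on a mean is negligible. Per-slice ROI noise is the population sd;
across-slice repeatability is the sample sd of per-slice means.

DICOM support is deliberately narrow — single-frame CT, one file per slice,
explicit little-endian, axial orientation — implemented in the package and
cross-checked against an independent reader in the tests. HU are stored as
signed 16-bit with slope 1 / intercept −1024, so writing rounds to integer
HU (the native granularity of CT data); integer volumes round-trip exactly.

## Numerical choices and degenerate inputs

* Interpolation: profiles are bilinear; FWHM crossings and MTF fraction
  crossings are linear between bracketing samples; the MTF recentring is
  an exact spectral phase shift.
* Zero-noise inputs: CNR raises an error (zero denominator is a flagged
  condition, not a number); an MTF that never falls to the requested
  fraction below Nyquist yields `NA`; uniformity on a constant section is
  exactly zero.
* Z-scores require n ≥ 3 and nonzero spread; cohorts of identical sites
  report the screen as not applicable.
* Section localization uses the layout's axial offsets (bead-reference
  equivalents); automatic bead detection is out of scope, and a roll angle
  can be supplied through the configuration rather than estimated.

## Problem sizes

The test-suite renders are full-resolution in plane (512 × 512) but span
only the slices each analysis needs: 5–7 slices for a section or a rod
measurement window. The six-site cohort checks render five-slice
electron-density volumes per site. The acceptance script renders the
seven-slice geometry section at full resolution. These sizes were chosen as
the smallest volumes that exercise every code path at the study's true
in-plane resolution.

## Known limitations

* The f10 resolution metric usually lies beyond the 0.476 mm⁻¹ Nyquist
  limit of the 538 mm / 512 grid and is then honestly `NA`; comparing f10
  across sites requires a finer reconstruction grid.
* The uniformity index divides by a ~10 HU background and inherits its
  volatility; treat UI sds at face value.
* The line-pair score depends on bar-to-grid alignment near the resolution
  limit, as it does on real scanners; only order relations (more blur,
  fewer line pairs) are stable properties.
* Multi-site aggregation summarizes calibration curves; it does not yet
  pool the image-quality metrics beyond carrying them in site reports.
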