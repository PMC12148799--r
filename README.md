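# cbctqa

Automated phantom-based image-quality analysis for radiotherapy cone beam
CT (CBCT), for medical physicists commissioning or monitoring O-ring linac
CBCT systems. The package measures everything a periodic image-quality
program needs from two standard phantoms — an elliptical electron-density
phantom with rods of known relative electron density (RED), and a
four-section cylindrical image-quality phantom — and aggregates results
across scanners. A seeded synthetic-volume generator renders both phantoms
with protocol-dependent HU, Gaussian blur and noise, so the whole pipeline
is testable without scanner data.

## What it computes

* **RED vs HU calibration**: per-rod ROI means (10 mm radius, five-slice
  window), piecewise linear fits of RED on HU split at RED = 1, slopes in
  10⁻⁶ RED/HU, and a max-|z| outlier screen across sites
  (z = (x − mean)/sd, sample sd).
* **Uniformity**: radial uniformity RU = mean(border ROIs) − center ROI;
  uniformity index UI = 100·RU/center; integral nonuniformity
  InU = (Max − Min)/(Max + Min) over centered profiles, with first-order
  error propagation.
* **Low contrast**: CNR = (S_ROI − S_BKG) / ((σ_ROI + σ_BKG)/2) on the
  15 mm rods at nominal 1% and 0.5% contrast.
* **Slice thickness**: FWHM of the 23° tilted-wire traces × tan 23°,
  averaged over four ramps.
* **Circular symmetry**: mean side length of the 50 mm hole square from
  sub-pixel hole centroids.
* **Sensitometry CT numbers** for ten labeled targets.
* **MTF** from the Fourier transform of the recentered, averaged lateral
  projections of a 50 µm wire; f50 and f10 by linear interpolation.
* **Spatial resolution** as the highest resolved line-pair set (1–5 lp/cm)
  under a peak/valley criterion (peak−valley > 30% of maximum over
  baseline).

DICOM I/O (single-frame CT series, explicit little endian) is built in;
layouts and protocols are editable configuration (YAML), not constants.

## Worked example

```r
library(cbctqa)

# one synthetic site, thorax protocol (125 kVp, 176 mAs, 2 mm slices)
cfg <- sim_config("thorax", seed = 1)

aed <- render_aed(cfg, n_slices = 5)
fit <- fit_piecewise(measure_rods(aed))
print(fit)
#> <piecewise_fit> RED<1: 1027.8 e-6 RED/HU (icpt 1.0007, n=4)
#>                RED>=1: 524.6 e-6 RED/HU (icpt 1.0050, n=7)

cat <- render_catphan(cfg)
lay <- default_catphan_layout()
radial_uniformity(cat, lay)   # RU -0.2 +/- 0.7 HU
cnr(cat, lay, 1)              # CNR(1%) 1.09 +/- 0.10
slice_thickness(cat, lay)     # 1.985 +/- 0.004 mm
circular_symmetry(cat, lay)   # 49.95 +/- 0.01 mm
compute_mtf(cat, lay)         # f50 0.276 +/- 0.002 /mm
max_line_pairs(cat, lay)      # 5 lp/cm
```

Reading: the high-branch calibration slope (524.6 × 10⁻⁶ RED/HU at
125 kVp) says each additional HU buys ~5 × 10⁻⁴ RED above water, with the
intercept pinned near RED = 1 at 0 HU, as a sound calibration should be.
The recovered slice thickness sits within 1% of the 2 mm reconstruction
nominal, the hole square reads within half a pixel of its 50 mm design,
and at this noise level (10 HU) the 1% contrast rod is at the edge of
visibility (CNR ≈ 1) while all five bar patterns still resolve.

Multi-site aggregation takes a list of per-site reports:

```r
reports <- lapply(1:6, function(i) {
  v <- render_aed(sim_config("thorax", seed = i, site = paste0("site", i)),
                  n_slices = 5)
  site_report(paste0("site", i), "thorax", measure_rods(v))
})
summarize_cohort(reports)  # per-RED median +/- sd, max |z|, slope panels
```

A thin command-line wrapper (`inst/cli/cbctqa`) exposes `simulate`,
`analyze-aed`, `analyze-catphan` and `aggregate` subcommands over DICOM
directories and YAML layouts.

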