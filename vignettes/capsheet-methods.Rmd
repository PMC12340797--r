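---
title: "Quantifying calcium-phosphate sheet aggregates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcium-phosphate sheet aggregates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsheet)
```

## The measurement problem

Primary cortical neuron cultures precipitate hyper-electron-dense, sheet-like
calcium-phosphate aggregates — plates roughly 1.85 nm thick that project as
curvilinear dark strokes in 2D cryo-EM micrographs. Characterizing them raises
three quantitative questions that this package answers:

1. **How large are they, and does culture condition change that?**
   Per-aggregate areas are measured from micrographs under manually drawn
   region masks, and conditions are compared nonparametrically.
2. **Are they octacalcium-phosphate (OCP)-like?** Low-dose selected-area
   electron diffraction (LDSAED) frames are reduced to radial profiles; an
   OCP-like material shows a broad band in the ~2.5–3.2 Å d-spacing window,
   which must be separated from the vitreous-ice maxima near 3.71 and
   2.15 Å.
3. **Is their location associated with a mitochondrial marker?** Counts of
   intracellular/extracellular, TOM20-positive/negative aggregates form a
   2×2 table tested with Fisher's exact test.

## Adaptive-threshold area measurement

Each masked region is measured independently. With `v` the masked pixel
intensities, the region is sign-normalized so the dense phase is high-valued,
`v' = max(v) − v`, anchored at zero, `v'' = v' − min(v')`, and binarized at

t = (max − min) − 1.5 · σ,

computed over the region's own `v''` values, with σ the **population**
standard deviation (the statistic describes that region's full pixel set, not
a sample from a larger population). A pixel is foreground iff `v'' ≥ t`, and
the area is the count of all foreground pixels in the mask, converted as
`area_nm2 = area_px · (pixel_size_A/10)²` (3.21 Å/px by default, the
acquisition setting for the area experiment).

Design choices worth stating explicitly:

* **Threshold orientation.** For a two-level region with dense-phase fraction
  f and contrast c, the anchored values are {0, c} and
  t = c·(1 − 1.5·sqrt(f(1−f))) . Since f(1−f) ≤ 1/4, t is always strictly
  positive and at most c: the `≥ t` rule keeps every dense-phase pixel and no
  background pixel, for *any* mask geometry. This is why noiseless recovery
  is exact, and it motivates normalizing to positive contrast before
  thresholding ("keep the most aggregate pixels over background").
* **Out-of-mask pixels are excluded**, not zeroed: multiplying the mask into
  the image and keeping zeros would poison min and σ with background values
  that are not part of "that specific area".
* **Degenerate regions.** A constant region has t = 0 and all v'' = 0, so the
  whole region counts as foreground under `≥`.
* **No connected-component filtering.** The quantity is total aggregate pixel
  area per drawn mask; a mask is presumed to contain one aggregate.
* **The 1.5 multiplier** was an empirical visualization choice; it is exposed
  as `std_multiplier` and area is monotone non-decreasing in it.
* **Invariances.** The measurement is exactly invariant to adding a constant
  to all intensities and to positive rescaling, so detector gain/offset do
  not matter.

The contrast convention (aggregates dark in the raw image, inverted before
thresholding) is recorded in each measurement's `orientation` field, since
raw-versus-inverted input is the one convention a user could hold
differently.

## LDSAED radial-profile analysis

* **Calibration** is linear in pixel radius: `q = r · q_N / (W/2)` with
  `q_N = 1.75 Å⁻¹` at half the image width (the 670 mm camera-length
  setting). Camera length itself is metadata only — the Nyquist value is the
  calibration.
* **Centering**: intensity-weighted centroid over the central quarter,
  refined by maximizing correlation between the frame and its 180°-rotation
  over a ±5 px grid at 0.5 px steps. Centers on the half-pixel grid map the
  pixel lattice onto itself, so the refinement needs no interpolation and
  recovers phantom centers exactly.
* **Radial averaging** uses equal-width q bins (default one bin per pixel of
  radial extent); pixels beyond q_N are dropped. Bins below 0.03 Å⁻¹
  (beam-stop/saturated region) are excluded from normalization and band
  detection.
* **Normalization** divides by the profile's mean over 0.094–0.113 Å⁻¹, a
  band dominated by structureless background, making full, partial and
  background profiles mutually comparable. Both profiles are normalized
  *before* the ratio (the order is recorded in the outputs; normalizing after
  division would instead rescale the ratio by a band-dependent constant).
* **Background ratio** divides target by background bin-wise, masking — not
  fabricating — bins that are empty in either profile or whose background
  falls below 1e−6 of the band mean. Structure shared by both frames (the
  ice peaks) divides out to 1.
* **Band detection** smooths the ratio with a 3-bin moving average (the band
  is broad; single-bin argmax would be noise-dominated), finds the smoothed
  maximum inside 2.5–3.2 Å (ties break to the lowest d, deterministically),
  and calls the band present when the peak ratio exceeds 1.05.

## Statistics

* **Fisher's exact test**: two-sided conditional exact p-value (the sum of
  hypergeometric probabilities of tables no more probable than the observed
  one, at the conventional 1e−7 relative tolerance on "no more probable").
  The reported odds ratio is the **sample cross-product** (a·d)/(b·c) — on
  the location × TOM20 table (28, 18; 33, 3) this is 0.141 — with the
  conditional MLE (0.145 on that table) retained as `odds_ratio_cmle`. The
  95% CI comes from conditional exact inversion; other CI constructions
  (e.g. score or mid-p) give different intervals, so the method is recorded
  in the result rather than assumed. A table with a zero margin carries no
  information about association and returns p = 1 by convention.
* **Wilcoxon rank-sum**: the reported statistic is the first sample's rank
  sum on midranks; p is exact when min(n) ≤ 10 with no ties, otherwise the
  tie-corrected normal approximation with continuity correction — group
  sizes in the area experiment (~94–107) are squarely asymptotic. The test is
  invariant under strictly monotone transforms of the pooled values.
* **Benjamini–Hochberg** step-up adjustment is applied across exactly one
  experiment's family of pairwise tests (6 pairs for 4 conditions).

## What the phantoms emulate — and what they do not

The generators define the study conditions for every property test:

* **Sheet micrographs**: curvilinear constant-width strokes (random-walk
  polylines stamped with a disc of the plate thickness, 1.85 nm ≈ 6 px at
  3.21 Å/px) inside elliptical membrane-bounded regions, depressed by
  `aggregate_contrast = 1` below a flat background of 10, with additive
  Gaussian noise (`noise_sigma = 0.1`, i.e. 10% of contrast — the stress
  level at which the recovery property is stated) and optional Gaussian
  blur. Region masks are the true pixels dilated by 4 px, emulating a
  hand-drawn mask hugging the aggregate. A rectangular stroke mode gives
  exactly known areas for unit checks.
* **Diffraction frames**: radially symmetric about an offset center,
  background 10, a broad material band at 2.85 Å (σ_d = 0.35 Å, amplitude
  2 — FWHM ≈ 0.82 Å, spanning the 2.5–3.2 Å window) plus ice peaks at
  3.71/2.15 Å (σ_d = 0.3 Å, amplitude 2), with optional Poisson noise. Band
  widths are specified in d and converted to q as σ_q = σ_d/d².
* **Group areas**: log-normal with the four conditions' reported medians
  (99,318 / 88,134 / 66,782 / 56,475 nm²) and sample sizes (107/100/94/94);
  `sdlog = 0.6` (quartile ratio ≈ 2.3) is a realistic dispersion chosen once
  for the generator, as the source distributions are not published.

The phantoms deliberately omit the contrast transfer function, multislice
scattering, projection of 3D tomographic geometry, detector MTF and
non-uniform illumination. Passing tests therefore demonstrate that the
*measurement operations* are correct and calibrated, not that the pipeline is
robust to every real-data artifact; real micrographs additionally require the
manual masking step that the phantoms synthesize.

## Numerical choices and degenerate inputs

* Every generator is a pure function of (spec, seed); the RNG state of the
  session is saved and restored.
* Default problem sizes — 256² phantoms, 128 radial bins, 50 phantoms per
  recovery property, 5000 null simulations for type-I calibration — were
  chosen as the smallest sizes at which the stochastic properties are stable
  to well inside their stated tolerances.
* Empty masks, all-zero frames, zero-margin tables, out-of-range p-values,
  unoccupied normalization bands and fully-masked detection windows all fail
  with specific errors rather than propagating NaNs.
* MRC files are written in mode 2 (float32): one write quantizes doubles to
  float32, after which round trips are bit-identical.

## Known limitations

* The centering refinement assumes an approximately centrosymmetric pattern;
  strongly textured single-crystal patterns could in principle mislead it.
* TIFF micrographs are treated as uncalibrated (no resolution-tag parsing);
  the pixel size must be supplied.
* `find_center`'s ±5 px refinement window assumes the centroid lands near
  the true center; a beam far off the central quarter would need a larger
  search.
* The Fisher CI is conditional-exact only; alternative CI constructions are
  not implemented.
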