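# capsheet

Quantification of calcium-phosphate (CaP) sheet aggregates in cryo-EM data.

Primary cortical neuron cultures precipitate mitochondria-sized, sheet-like
CaP aggregates whose ultrastructure resembles octacalcium phosphate (OCP),
a bone-precursor phase forming ~1.85 nm plates. `capsheet` implements the
quantitative analyses used to characterize them, for microscopists and image
analysts who have micrographs, hand-drawn aggregate masks and low-dose
selected-area electron diffraction (LDSAED) frames:

* **Per-aggregate area measurement.** Each masked region is sign-normalized
  (dense phase high), anchored at zero, and binarized at the per-region
  adaptive threshold

  *t* = (max − min) − 1.5 · σ,

  with σ the population standard deviation of that region's pixels; the
  foreground pixel count is converted to nm² via
  `area_px · (pixel_size_A/10)²`. Group comparisons use pairwise Wilcoxon
  rank-sum tests with Benjamini–Hochberg correction.
* **LDSAED radial-profile analysis.** Frames are centered (centroid +
  180°-rotation correlation refinement), radially averaged with a linear
  q calibration (q = 1.75 Å⁻¹ at half the image width for the 670 mm camera
  length), normalized on the 0.094–0.113 Å⁻¹ band, divided by a matched
  background profile to suppress the vitreous-ice maxima (~3.71 / ~2.15 Å),
  converted to d-spacing (d = 1/q), and scanned for the diagnostic broad
  OCP-like band in the 2.5–3.2 Å window.
* **Location × marker association.** Two-sided Fisher's exact test with the
  sample odds ratio (a·d)/(b·c) and a conditional-exact 95% CI.
* **Synthetic phantoms.** Sheet micrographs, diffraction frames and group
  area tables with exact ground truth, so the full pipeline is testable
  without microscope data.

## Worked example

```r
library(capsheet)

## 1. A phantom micrograph with two aggregates, measured under its own masks
ph <- generate_sheet_micrograph(sheet_phantom_spec(n_aggregates = 2, seed = 7))
ph$truth$true_area_px
#> [1] 374 371
m <- binarize_and_measure(ph$micrograph, ph$truth$masks[[1]])
m
#> <aggregate_measurement> label 1: 374 / 986 px above t = 0.846 -> 38.537 nm^2
```

Even at Gaussian noise of 10% of the aggregate contrast, the 374 true pixels
are recovered exactly here: for a two-level region the threshold always falls
between the background and the dense phase (see the methods vignette).

```r
## 2. Diffraction: a band at 2.85 A plus ice peaks, against an ice-only background
target <- generate_diffraction_frame(diffraction_phantom_spec(
  bands = list(c(2.85, 0.35, 2)), center_offset_px = c(3, -2), seed = 1))
background <- generate_diffraction_frame(diffraction_phantom_spec(
  bands = list(), center_offset_px = c(3, -2), seed = 2))
tp  <- normalize_band(radial_average(target$frame, find_center(target$frame)))
bp  <- normalize_band(radial_average(background$frame, find_center(background$frame)))
rat <- background_ratio(tp, bp)
detect_band(rat)
#> <band_summary> window 2.50-3.20 A: peak at 2.868 A, ratio 1.185, band PRESENT
```

The ratio at the ice positions stays within 0.03 of 1 (shared structure
divides out); the injected band survives at ratio ≈ 1.19 and is localized to
within one radial bin of 2.85 Å.

```r
## 3. Association of aggregate location with TOM20 status
fisher_exact_2x2(28, 18, 33, 3)
#> <fisher_result> OR = 0.1414 (95% CI 0.0247-0.57), two-sided p = 0.001883
#>   two-sided conditional exact p; sample (cross-product) odds ratio; CI by conditional exact inversion
```

That is: 61% of extracellular versus 92% of intracellular aggregates are
TOM20-positive, a significant association between location and marker
status.

## Command line

A thin wrapper is installed at `inst/cli/capsheet`:

```sh
Rscript inst/cli/capsheet simulate-micrographs --seed 1 --out-dir out/
Rscript inst/cli/capsheet measure-areas --images out/micrograph_001.mrc \
    --labels out/labels_001.tif --pixel-size-A 3.21 --out-dir out/
Rscript inst/cli/capsheet fisher --table 28,18,33,3 --out-dir out/
```

Every run writes a `manifest.json` snapshotting the configuration, seed and
md5 digests of all inputs and outputs, so results are reproducible from the
manifest alone.

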