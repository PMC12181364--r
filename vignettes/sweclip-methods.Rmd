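---
title: "Quantifying muscle stiffness from shear wave elastography clips"
author: "sweclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle stiffness from shear wave elastography clips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweclip)
```

## The problem

Shear wave elastography (SWE) superimposes a color heatmap of tissue
stiffness — the elastogram — on the grayscale B-mode ultrasound image. The
underlying numeric stiffness field is usually not exported: what leaves the
scanner is a DICOM clip of rendered screens. Manufacturer software offers
manual measurement zones on single frames, which is slow, limited to small
regions, and exposed to rater expectations about where "representative"
tissue lies. In muscle, stiffness varies both across the image and from
frame to frame, so single-frame, small-zone readings generalize poorly.

`sweclip` recovers quantitative stiffness from the rendered clip itself. For
every frame it

1. locates the elastogram box from the colored frame line drawn around it,
2. calibrates mm-per-pixel from the on-screen measurement bar,
3. inverts each pixel's color back to Young's modulus in kPa,
4. computes a statistic vector over a user-chosen region of interest (ROI),

and then averages the per-frame results into a clip summary. A separate
statistics module implements the validation toolkit used to compare such an
analysis against a reference method: Spearman correlation, the full
Bland–Altman workflow, and an exact agreement hypothesis test.

## Decoding colors back to kPa

The display model is: a colormap color `c(v)` for relative stiffness
`v / e_max` is alpha-blended over the local B-mode gray `g`,

    p = alpha * c(v) + (1 - alpha) * g,        alpha = 0.5 by default,

then rounded to 8-bit channels. `e_max`, the maximum of the elasticity color
bar, is supplied by the user per clip; it must match the range set on the
device when the clip was exported.

Exact inversion is underdetermined because `g` differs per pixel and is
unknown. The decoder therefore performs a nearest-neighbour match over the
*achievable blended set*: the colormap is discretized into `n_lut = 256`
colors, gray levels are taken on a uniform grid (step 4 of 255), and the
observed pixel is assigned the stiffness index of the closest blend. Ties
break toward the lower index, which is deterministic and conservative. The
implementation computes, for each colormap index, the optimal grid gray in
closed form (the squared distance is convex in `g`, so the grid minimizer is
the grid point nearest the continuous minimizer); this is exactly the
brute-force minimum over all (index, gray) pairs, and the test suite asserts
that equivalence against a literal enumeration.

Classification precedes decoding. A pixel whose channel range is at most
`chroma_tol` (default 8) is grayscale — B-mode background, never decoded. A
chromatic pixel farther than `gamut_tol` (default 12) from every achievable
blend is out of gamut (text, frame line, UI elements) and is excluded by
default. The defaults tolerate ±1 rounding plus light compression noise;
both are exposed.

With rendering rounded half away from zero, the worst-case round-trip error
is bounded by the colormap quantization `e_max / (n_lut - 1)` plus a rounding
term `2 * e_max / (255 * span)`, where `span` is the smallest normalized
channel range of the colormap (1 for the default map). At `e_max = 300` kPa
that bound is ≈3.5 kPa; the measured worst case over a dense value × gray
grid is ≈2.4 kPa.

### The colormap itself

Vendors do not publish their colormap RGB values. Three sources are
supported, in order of preference: sampling the on-screen color bar
(`sample_colorbar()`, median color of evenly spaced bar rows — the bar is
the only in-image ground truth), a user-supplied `position,r,g,b` CSV, and a
built-in six-stop temperature map (blue, cyan, green, yellow, orange, red at
uniform positions). Whether scanner rendering pipelines are best inverted in
RGB or in an opponent color space is not documented; RGB nearest neighbour
over the blended set is the contract chosen here because it is simple,
testable by enumeration, and empirically stays within the quantization
bound. Only a single configured opacity is supported; decoding clips
rendered at other opacities than the configured one is undefined behavior by
design.

## Segmentation and physical scale

Exported clips draw an orange line around the elastogram; single-image
exports draw a white one. Detection matches the line color (orange default:
R ≥ 200, 80 ≤ G ≤ 180, B ≤ 80; white: all channels ≥ 245; both overridable
as center + tolerance), labels connected components, and accepts the largest
component whose bounding-box perimeter is at least 90% matched — this ring
test rejects stray orange glyphs. The interior box excludes the line itself,
with per-side line width estimated from runs of fully matched border
rows/columns. On rendered fixtures the detected box is exact for line widths
1–3 px.

The measurement bar is reduced to a brightness profile along its column
band; tick marks are runs above the half-range threshold, and
`mm_per_px = tick_interval_mm / median(inter-tick spacing)`. The tick
interval (default 10 mm) is the user's responsibility — the bar's format is
vendor-specific. Both detectors fail loudly with an instruction to fall back
to `manual_geometry()`; geometry from one reference frame (default the
first, configurable) is applied to all frames so the analyzed region is
consistent over time. If the reference frame lacks a detectable box, any
other frame can be designated instead.

## ROIs and statistics

Two ROI modes exist, matching common practice: a hand-specified rectangle in
mm relative to the box's top-left corner, and a tiling of square cells
(default 4 × 4 mm) for spatial analyses. Grid cells are anchored at the
box's top-left corner (no anchor is canonical; top-left is deterministic and
matches reading order), and partial boundary cells are excluded rather than
clipped so all cells have equal area. Pixel rectangles are half-open with
pixel-center inclusion, which eliminates double counting at shared edges.

Per frame, over the valid (colored) pixels inside the ROI:

* `fill_pct` — percentage of ROI pixels carrying an elasticity value. This
  is the image-quality proxy: devices do not expose stability metrics for
  all presets, so the share of successfully reconstructed pixels stands in.
* `mean`, `median`, `sd` (n−1 denominator), `iqr`
  (linear-interpolation quantiles, R type 7), `max` — all in kPa.
* `n_top`, `pct_top` — count and percentage of values exceeding the top 2%
  of the scale maximum, i.e. `> 0.98 * e_max`. The scale maximum is used,
  not the per-frame maximum: it is the only "maximum value" fixed before
  statistics are computed. The percentage is taken over valid pixels by
  default (`top_denominator = "roi"` switches to all ROI pixels). These
  flag near-saturation, which indicates a poorly chosen export range.

Every displayed frame is analyzed individually — no temporal smoothing, no
deduplication of repeated elastograms (optional downstream). Frames with
zero valid pixels carry no stiffness information and are excluded from the
clip means rather than imputed; the clip summary reports how many frames
were used.

## Units

Devices report Young's modulus E (kPa). Under incompressibility, E = 3μ with
μ the shear modulus, and μ = ρc² with c the shear-wave velocity, so
c = sqrt(E/(3ρ)) with E in Pa. ρ defaults to 1000 kg/m³, the standard
soft-tissue assumption, which reproduces the conversion arithmetic found in
the musculoskeletal SWE literature; it is exposed for other tissues. For
anisotropic muscle the recommended reporting unit is SWV, so output tables
carry kPa and m/s side by side (`units = "both"`), converted row-wise; the
clip-level SWV is the across-frame mean of per-frame converted values.
Shear modulus is provided as a conversion utility only and deliberately not
emitted in the output tables.

## Agreement statistics

`compare_methods()` implements the validation workflow for comparing two
analysis methods on matched per-clip values, with the difference convention
`d = a − b` (method A minus reference):

* **Spearman correlation** — Pearson correlation of average ranks. The
  p-value is by exact enumeration of rank permutations for n ≤ 8 and by the
  t approximation with n − 2 df above that (full enumeration grows
  factorially; at n = 8 it is 40,320 permutations, at n = 10 it would be
  3.6 million for no practical gain over the approximation).
* **Bland–Altman** — bias = mean(d), limits of agreement
  bias ± 1.96 · SD(d) with the fixed multiplier 1.96 (not t-based), bias CI
  from the t distribution with n − 1 df (common practice where the
  literature leaves z vs. t unstated), percentage of differences inside the
  limits, and an OLS regression of differences on means whose nonzero slope
  flags proportional bias. The log branch applies the identical pipeline to
  natural-log-transformed inputs (the standard Bland–Altman
  recommendation); a trend that survives the log transform indicates true
  proportional bias rather than mere non-normality.
* **Shieh's exact agreement test** — tests whether the population central
  95% range of differences, μ ± γσ with γ = 1.959964, lies within
  pre-specified margins δ. Exact one-sided 1 − α bounds come from the
  noncentral t distribution with n − 1 df and noncentrality √n · γ; the two
  bounds form the 90% interval at the default α = 0.05, and H0 is rejected
  (methods interchangeable) exactly when both bounds fall strictly inside
  the margins. The margins have **no default**: they are a clinical
  judgement (for instance a minimal detectable change) and silent defaults
  would invite misuse. The test suite verifies the bounds against a
  100,000-draw parametric bootstrap of the pivotal quantity and checks the
  type-I error at the null boundary by simulation.

Degenerate inputs are handled explicitly: zero-variance differences give
point bounds and a defined LoA of width zero; a perfect linear trend reports
F = ∞, p = 0 with an `exact_fit` flag; constant differences report F = 0,
p = 1.

## The synthetic renderer

`synthetic_clip_config()` renders complete screens — clipped Gaussian gray
noise for B-mode texture (mean 60, sd 25 by default), the blended
elastogram, frame line, tick bar and an opaque color bar — from a known
stiffness field, so every pipeline stage can be tested against ground truth
without patient data. Field models: `constant`, a horizontal `gradient`, and
`smooth` (white noise filtered with a Gaussian kernel of configurable
correlation length). The spatial pattern belongs to the clip; per-frame
temporal jitter (a scalar kPa offset) and signal dropout (gray holes)
emulate the frame-to-frame fluctuation and reconstruction failures seen in
muscle clips. Defaults emulate a clip exported with an individually adjusted
range — `e_max` = 100 kPa with fields around 40 kPa — reflecting the
practice of tuning the range so elastograms span a wide color band, rather
than the 300 kPa device maximum; dropout defaults to 10%.

What the generator deliberately does *not* emulate: acoustic speckle,
anisotropic fiber texture, compression artefacts, probe motion, or any
vendor compression. Passing the recovery suites therefore demonstrates that
the inversion, geometry and statistics are correct for the stated display
model — not that decoding is robust to every artefact of real exports, which
is why the classifier tolerances and the color-bar self-calibration are
user-adjustable and should be spot-checked on a small sample of real clips.

Given a seed, generation is bit-reproducible; clips round-trip losslessly
through both the PNG-stack dialect and uncompressed RGB multi-frame DICOM.

## Problem sizes and runtime choices

The test and acceptance suites run on 140 × 200 to 320 × 330 px frames with
2–4 frames per clip (decoding an 80 × 120 px elastogram takes well under a
second; a full-size 200 × 300 px box about one second per frame). Recovery
is checked on 3 field models × 3 seeds, segmentation on 10 randomized
layouts, interval coverage with 2,000 replicates, and the bootstrap oracle
for the exact bounds with 100,000 draws — sizes at which the Monte-Carlo
error is several times smaller than the tolerance being asserted.

## Known limitations

* Vertical screen layout only (elastogram above B-mode); side-by-side
  exports require manual segmentation.
* One opacity per clip; the configured alpha must match the export setting.
* Decoded values are quantized to `e_max / 255`; narrow export ranges give
  proportionally finer resolution, wide ranges coarser — mirroring the
  device-side recommendation to adjust the range before export.
* Ultrasound systems convert internally between SWV and Young's modulus
  with formulas that are known to differ slightly from the published ones
  (rounding behavior included); this package applies the published
  relations and does not emulate any vendor's internal pipeline.
* Free-form ROIs are not supported.
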