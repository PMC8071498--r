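---
title: "Methods: colorimetric arginine quantification and sex classification from fingermarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric arginine quantification and sex classification from fingermarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argmark)
```

## The measurement model

The Sakaguchi reaction develops a red complex whose color intensity is
linear in arginine concentration. The readout is a scanned 8-bit RGB image
of the device's detection window, and the quantitative signal is the
window's mean HSB saturation taken *after* a red→magenta channel
substitution.

Why this particular chain:

* The raw mean **red value** is a poor readout: a red complex at full
  brightness keeps `R` near 255 at every concentration; what changes is how
  far `G` and `B` fall below it.
* **Saturation**, `S = 100·(max − min)/max`, captures exactly that gap, and
  is invariant to uniform brightness scaling — a scanner exposing the page
  a little darker multiplies all channels by the same factor and leaves `S`
  unchanged.
* The **red→magenta tint** replaces `B` with a copy of `R`, `(R, G, B) →
  (R, G, R)`. For an ideal red pixel (`G = B`) it leaves saturation
  unchanged, but for real pixels where `B` has drifted away from `G`
  (scanner chroma noise, substrate tint) it anchors the maximum channel and
  removes blue-channel noise from the `min`, which is what tightens the
  calibration in practice. The operation is idempotent and never touches
  `R` or `G`.

Per-pixel saturations are computed in floating point and averaged directly.
A workflow that first quantises the saturation plane to an 8-bit image and
then averages introduces an extra rounding of up to 0.5/255 per pixel
(≤ 0.2 % saturation, ≈ 0.4 % worst case after the mean); we skip that
intermediate quantisation and accept a corresponding small systematic
difference from tools that do not.

## Segmentation

The detection window is isolated by color thresholding: keep pixels whose
hue lies in a circular interval through red (default 300°–60°, covering
red and post-tint magenta) with saturation ≥ 5 %, then take the largest
4-connected component, rejecting it if it covers less than 1 % of the
image. The published workflow used interactive thresholding with unstated
bounds; the defaults here are a deliberate, reproducible stand-in, and an
explicit rectangle ROI (`roi_mask()`) is accepted as a fallback wherever
thresholding fails. Whether interactive thresholding would have selected
the whole window or only its most-colored subregion is unknowable from the
published record; the largest-component rule is our design choice, and on
the synthetic images it selects the full window exactly.

## Calibration and inverse prediction

`fit_calibration()` is ordinary least squares of mean window saturation on
standard concentration over the 20–120 µM six-point series — *classical*
calibration (response regressed on concentration, then inverted), matching
the orientation in which such curves are plotted. Weighted regression and
prediction intervals on the inverse estimates are intentionally out of
scope. `invert_calibration()` solves `Ĉ = (S − a)/b`, clamps negative
estimates to zero and flags any saturation outside the span of the fitted
standards (`in_range = FALSE`); extrapolated values are reported, not
censored. The standard-addition spike applied during the wet chemistry is
identical for standards and samples, so it cancels in calibration and no
additive correction is applied — reported concentrations are directly
comparable to sweat literature values.

Degenerate designs raise errors rather than returning nonsense: all-equal
concentrations (singular design) and non-positive slope (a non-responsive
assay) both stop.

## The synthetic forward model

`forward_model()` renders what the scanner would see: a rectangular window
whose noise-free mean saturation is `a + b·C` percent (clamped to
[0, 100]) on a white background. Window pixels are pure red at full
brightness, `(255, 255(1−s), 255(1−s))`, so saturation alone encodes
concentration; i.i.d. Gaussian noise (SD 2 on the 0–255 scale by default)
is added per channel in the window, clipped and rounded to 8 bits. Defaults
`a = 5 %`, `b = 0.65 %/µM` put the 20–120 µM working range inside 18–83 %
saturation, away from both clamp bounds; the published calibration figure
carries no readable axis numbers, so these are the package's own choice,
fixed once.

`cohort_config()` adds the population layer: per-print concentration
`max(0, µ_sex + donor_effect + print_noise)` with the sex means at the
literature values (94.8 / 54.0 µM) and per-print total SDs backed out of
the blind study's reported SEMs and sample sizes (5.1·√33 ≈ 29.3 µM female,
5.3·√12 ≈ 18.4 µM male) — the only self-consistent total-spread estimate
the published summaries admit. The published record is silent on how that
variance splits between donors and prints; the default `between_fraction =
0.7` (70 % of variance between donors) reflects that donor identity, not
print-to-print chemistry, plausibly dominates — it is a configuration knob,
not an inference. Negative draws are truncated at zero on physical grounds.
Two artifact knobs emulate the harder substrate conditions: a
multiplicative `lifting_efficiency` (recovery loss when prints are lifted
from furniture or switches) and a `powder_artifact_fraction` of window
pixels overwritten with near-black, zero-saturation speckle (residual
fingerprint powder), which erodes the segmentation mask rather than
shifting the color signal. Defaults (1 and 0) are the direct-deposit,
unpowdered blind-study protocol.

What the generator does **not** emulate: fingerprint ridge structure,
reaction kinetics, scanner optics (vignetting, JPEG-style artifacts,
illumination gradients), or any dependence of noise on concentration.
Passing tests therefore demonstrate that the measurement chain is correct
and unbiased *for this image model*, not that a physical scanner would
achieve the same figures.

## Classification and cohort statistics

Donor means are taken over the index, middle and ring fingers only — thumb
and little-finger deposits track contact area, not concentration, and are
excluded. The classification rule is the midpoint threshold between the
literature means, 74.4 µM at the defaults: the published study never states
its decision rule, and the midpoint is the minimal-assumption separator
consistent with its outcomes. A donor mean exactly on the threshold is
`inconclusive` and scored conservatively as a mismatch.

Cohort summaries report mean, SEM (sample SD / √n) and a Student-t 95 % CI
(small cohorts; the published CI construction is unstated). Comparisons of
an observed cohort against a literature value known only through its mean
and SEM use a pooled-SEM normal test, `z = |m₁ − m₂| / √(SEM₁² + SEM₂²)`:
this reproduces the published female blind-study comparison (p = 0.908) to
three decimals. The published male p (0.914) and pilot-phase p values are
*not* reproduced by this test (it gives ≈ 0.92, ≈ 0.26, ≈ 0.38); the exact
procedure behind those numbers is unstated, so they are reported by the
replay script but not asserted anywhere. Two groups of raw per-print values
are compared with the Welch two-sample t test.

## Numerical and degenerate-input choices

* Hue follows the standard hexagonal formula; achromatic pixels get hue 0
  and saturation 0 (black included, by convention).
* 16-bit scans are reduced to 8 bits by integer division by 257
  (65535 → 255); grayscale images are replicated across channels.
* Coordinates are 0-based, row-major, origin top-left; ROIs are
  `(x, y, width, height)`.
* Ties in component size are broken by first label encountered
  (deterministic for a given image).
* `cohort_summary()` requires n ≥ 2; comparisons with both SEMs zero return
  p ∈ {0, 1} with a degeneracy flag rather than dividing by zero.

## Problem sizes

The test suite and the acceptance script exercise the full image pipeline
at 96×72-pixel images with a 60×40 window — large enough that 8-bit
rounding averages out (window mean saturation is within ±0.2 % of the
target before noise), small enough that a 200-donor × 3-print cohort (600
rendered, segmented and measured images) runs in well under a minute. The
end-to-end recovery checks use 200 donors per sex, for a Monte-Carlo
standard error of the recovered grand mean near 1.9 µM (female) and 1.1 µM
(male); recovery is asserted within two of those standard errors. Remaining
known biases at the defaults are small against that yardstick: truncation
at zero and saturation clamping at 100 % together shift the female grand
mean by ≈ −0.5 µM, and 8-bit rounding contributes < 0.3 µM.

## Known limitations

* The forward model is the package's own construction; its linearity is an
  assumption the real assay only approximates at range edges.
* The classification threshold is fixed, not learned; cohorts whose true
  means differ from the literature values will degrade accuracy in a way
  the midpoint rule cannot detect.
* Segmentation assumes one window per image; multi-window layouts must be
  cropped upstream.
* No weighted calibration, no inverse-prediction intervals, no correction
  for multiple comparisons (single planned contrasts only).
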