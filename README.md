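# argmark

Quantification of arginine in latent fingermark deposits from scanned
colorimetric assay images, and presumptive biological-sex classification of
the donors.

## The problem

Latent fingermarks carry eccrine-sweat metabolites, and the arginine
concentration in sweat differs roughly twofold between biological sexes
(literature means 94.8 ± 12.9 µM for females, 54.0 ± 12.6 µM for males,
± SEM). The Sakaguchi reaction (arginine + α-naphthol + sodium hypobromite
under alkaline conditions) produces a red complex whose intensity is linear
in arginine concentration, so a flatbed scan of the reaction's detection
window plus image analysis yields an objective, low-cost readout — no
spectrophotometer required.

The measurement chain this package implements:

1. **Segment** the detection window in the scanned RGB image by color
   thresholding (red hue interval, saturation floor, largest 4-connected
   component).
2. **Tint** the image red→magenta: every pixel `(R, G, B)` becomes
   `(R, G, R)`, boosting the red channel's contribution to saturation.
3. **Measure** the mean HSB saturation over the window,
   `S = 100·(max − min)/max` per pixel in percent.
4. **Calibrate**: ordinary least squares of mean saturation on standard
   concentration, `S = a + b·C`, over a 20–120 µM standard series
   (classical calibration).
5. **Invert** for unknowns, `Ĉ = (S − a)/b`, flagging extrapolation.
6. **Classify**: average the index, middle and ring fingers per donor
   (thumb and little finger are excluded as erratic) and call the donor
   female above the midpoint of the literature means (74.4 µM), male below.

A synthetic forward model (`forward_model()`, `generate_cohort()`) renders
detection-window images from known concentrations — window saturation
linear in concentration, Gaussian pixel noise, optional lifting-recovery
loss and powder speckle — and simulates two-level (between-donor /
within-donor) cohort variation, so the entire pipeline is testable without
scanner data.

## Worked example

```r
library(argmark)

# calibrate from a rendered six-point standard series (pixel noise SD 2)
std <- generate_standard_series(forward_model(pixel_noise_sd = 2), seed = 1)
cal <- calibrate_from_images(std)
print(cal)
#> calibration: S = 4.691 + 0.6521 * C  (n = 6, R^2 = 1.0000, residual SD 0.02%)

# quantify an unknown: segment, tint, measure, invert
img  <- render_detection_window(60, forward_model(pixel_noise_sd = 2), seed = 9)
sat  <- measure_window(img, segment_detection_window(img))$mean_saturation
invert_calibration(cal, sat)
#> # A tibble: 1 x 3
#>   saturation_used value in_range
#>             <dbl> <dbl> <lgl>
#> 1            43.8  60.0 TRUE

# replay the published 15-donor blind study table
score_blind_study(blind_study_table())
#> $matches
#> [1] 14
#> $total
#> [1] 15
#> $accuracy
#> [1] 93
```

The calibration line recovers the generator's settings (intercept 5 %,
slope 0.65 %/µM) to within the pixel-noise jitter; the 60 µM unknown comes
back at 60.0 µM; the blind-study replay reproduces the published 14/15
(93 %) accuracy.

The `analysis/` directory holds the same workflow as numbered drivers —
`01_simulate.R` (blind-study-shaped cohort of 11 female + 4 male donors,
3 prints each), `02_calibrate.R`, `03_quantify.R`, `04_classify.R`,
`05_published_replay.R` — each writing its tables under `results/`.

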