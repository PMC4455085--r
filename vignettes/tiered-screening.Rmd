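---
title: "Tiered screening of artemether-lumefantrine tablets: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered screening of artemether-lumefantrine tablets: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierscreen)
```

## The screening problem

Falsified antimalarials concentrate where malaria burden is highest and
laboratory capacity lowest, so field screening must be cheap, fast, and
sparing with reagents. This package implements a three-tier strategy for
fixed-dose artemether-lumefantrine (AMLF) tablets in which each tier costs
more and destroys more than the previous one:

1. **Tier I — physical.** Weight, diameter and thickness against the
   manufacturer's acceptance ranges. Nondestructive, needs only a balance
   and calipers.
2. **Tier II — photometric.** Two independent nondestructive sub-tests:
   tablet fluorescence under UV illumination, quantified as a mean gray
   value and compared with an authentic reference band; and laser
   transmission through the tablet read with and without a red filter,
   combined into the statistic `W = (I - I_filter)/(I_filter/I)` and
   compared with the range of W over authentic tablets.
3. **Tier III — colorimetric.** Destructive. The tablet is dissolved in
   glacial acetic acid: lumefantrine's inherent yellow is quantified from an
   RGB photograph of a 96-well plate as `RvsB = (R - B)/(R + B)`; adding
   concentrated sulfuric acid drives an endoperoxide-mediated oxidation of
   artemether to an orange/red product quantified as
   `RvsG = (R - G)/(R + G)` from a second photograph. Both ratios are linear
   in concentration over the working range, so content is reported as a
   percent of an authentic reference tablet run on the same plate.

A sample is `suspicious` as soon as any executed tier fails. This is
deliberately asymmetric: a tablet with correct content but anomalous
photometrics may be an expired or repackaged product, so a Tier III pass
never overrides a Tier II failure, and the rule is not configurable.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `spec_limits()` weight | 0.228–0.252 | g | manufacturer specification for the 20/120 mg tablet |
| `spec_limits()` thickness | 3.0–3.4 | mm | manufacturer specification |
| `spec_limits()` diameter | 9.1–9.2 | mm | range observed over a 12-tablet authentic panel |
| `band_k` | 3 | sds | conventional control-chart band; the underlying field practice is visual, so the band is an objective surrogate |
| `presence_thresholds` | 50 | % of reference | must admit a genuine-content sample at 111/135% and reject an absent ingredient at 0%; no official numeric limit exists, so it is configurable and documented as a gap |
| `dilution_design()` | 120/20 mg in 4 mL | mg, mL | label dose of one tablet; 100% level = 30 mg/mL LF, 5 mg/mL AM |
| `gating` | `"always"` | — | `"on_fail"` reserves Tier III (and its acids) for samples failing Tier I/II |

All interval endpoints are inclusive: the published measurement table treats
tablets at exactly 9.2 mm and 3.4 mm as passing, and the screen follows it.
Specification intervals are treated as closed acceptance ranges, not
one-sided tolerances.

## What the synthetic generator emulates

No raw images or device readings are deposited for this assay, so the
package ships a seeded generator whose defaults define the study conditions
used throughout the tests.

**Tablet dimensions.** Per-profile normal draws. The authentic profile
(weight 0.240 ± 0.003 g, diameter 9.15 ± 0.015 mm, thickness 3.2 ± 0.05 mm)
is validated so every ±2 sd interval lies inside the specification range;
with sd 0.015 mm, a 12-tablet panel spans about 0.05 mm, which prints as the
observed 9.1–9.2 mm range at one-decimal precision. The
counterfeit-dimension profile (0.300 g / 9.6 mm / 3.6 mm means) is
rejection-sampled until each tablet violates at least one range, mirroring
the observation that most falsified tablets fail on simple measurements.
The counterfeit-content profile has authentic dimensions: it passes Tier I
and must be caught downstream, the pattern shown by two of the six study
counterfeits.

**Well colour.** The colour model is parameterised in ratio space:
`RvsB = s_LF * c_LF` exactly (slope 0.5/36 per mg/mL, so the 120% level
reads 0.5), with the blue channel derived as `B = R(1 - sc)/(1 + sc)` for a
fixed red level of 240, and analogously `RvsG = s_AM * c_AM` (slope 0.5/6)
in the post-acid image only — the artemether product exists only after acid
treatment, while lumefantrine's yellow persists in both images. A
channel-linear model was rejected because it makes the ratio statistics
non-linear in concentration, contradicting both the assay's observed
linearity and the reference-ratio quantification the pipeline relies on.
Slopes are validated analytically (positive, and `s * c_max < 1`) before
rendering, which guarantees strictly increasing in-gamut responses. Pixel
noise is i.i.d. Gaussian per channel, rounded and clamped to 8 bits —
the simplest model that exercises ROI averaging.

**Fluorescence fields.** Non-overlapping discs at per-tablet intensities
(authentic 150 ± 5, counterfeit classes 190/110 ± 5 gray values) over a
uniform dark background, rendered gray-as-RGB. The generator refuses
configurations whose background is within 5 pixel-noise sds of the dimmest
disc, which is what licenses Otsu thresholding for disc detection.

**Laser readings.** The unfiltered intensity `I` and the filter ratio
`rho = (1 - t)/t` (with `t` the transmission fraction) are log-normal, so
`W = I * rho` is log-normal with population median exactly
`intensity_median * wratio_median`. The authentic default (2.0 × 0.94 =
1.88) anchors the population median to the value reported for authentic
tablets — a configuration input, not a reproduced output. The counterfeit
default median (0.40) sits far outside the authentic range, matching the
qualitative separation in the study, where every counterfeit fell outside
the authentic range (one as low as W = 0.30).

**Not emulated:** colour-development kinetics (the assay reads at 30–60
minutes; the model is time-free), plate-reader absorbance spectra,
perspective/white-balance artefacts of real photographs, packaging images,
and matrix effects (a real sample over-read AM by image analysis relative
to HPLC; the generator cannot produce that bias). Passing tests therefore
demonstrate the correctness of the measurement and decision chain, not
robustness to real-world imaging conditions.

## Numerical choices

* **Pixel convention.** 0-based coordinates, x right, y down; ROI
  membership by pixel-centre distance. Stated so extraction tests can be
  bit-exact against a per-pixel loop.
* **Gray conversion.** Default weights (1/3, 1/3, 1/3) — the plain RGB
  mean — configurable to luma weights; the upstream software choice is
  undocumented, so the simplest convention is the default.
* **Ratios from ROI means,** not per-pixel ratios averaged: matches the
  described workflow (channels are measured per well, then normalised) and
  is better conditioned at low intensity.
* **No blank subtraction by default**; the described assay uses none.
* **W formula as printed.** `(I - I_filter)/(I_filter/I)` is evaluated in
  its printed form rather than the algebraic simplification; they agree to
  floating point, and the printed form is the definition.
* **Exact Mann-Whitney.** Mid-ranks for ties; the exact null distribution
  of the rank-sum over all `choose(n, n_a)` assignments is computed by a
  generating-function recursion (equivalent to full enumeration, feasible
  for any `n <= 25`, where exactness matters for groups as small as 12 vs
  5); the two-sided p doubles the smaller tail, capped at 1. Larger samples
  use the tie-corrected normal approximation with continuity correction.
* **Degenerate calibrations.** Constant responses fit with `r_squared`
  defined as 0 and a warning flag rather than `NA`, so downstream code can
  rank curves without special-casing.
* **Disc ordering.** Detected discs are sorted row-major, grouping rows by
  vertical gaps larger than the median disc radius, so detection output
  aligns with row-major ground truth.
* **Percent API is clamped at 0** (a noisy response slightly below zero is
  reported as 0%, keeping the estimate in its physical range).

## Reference-panel size

The authentic W reference range is the inclusive min–max of the panel, so a
new authentic tablet falls outside it with probability `2/(n + 1)` by
exchangeability — 15% for a 12-tablet panel, 2% for a 100-tablet panel.
Small panels therefore dominate the false-alarm budget of the whole
pipeline. The 12-tablet panel matches the study design and is kept for the
group-comparison tests; for end-to-end verdict-accuracy simulations the
package's validation uses a 100-tablet reference panel, and deployments
that will screen many authentic samples should do the same. The
fluorescence band does not share this problem (its width is `k` sds, not a
range), and Tier I contributes about 0.1% false alarms under the authentic
dimension model.

## Problem sizes used in validation

The shipped validation uses plates of up to 49 wells at 7 px ROI radius
(images of roughly 230 × 160 px), fluorescence fields of up to 40 discs,
10,000-draw Monte-Carlo checks of the simulated W median, 200 replicates of
the 12-vs-5 exact group test, and a 40-sample end-to-end batch (20
authentic, 10 counterfeit-dimension, 10 counterfeit-content) with
100-tablet reference panels. These sizes give comfortable margins for every
stochastic bound tested while keeping the full suite in the tens of
seconds.

## Known limitations

* The fluorescence pass band is an objective surrogate for what is, in the
  field, a visual interobserver judgement; `k = 3` is a convention, not a
  validated operating point.
* A counterfeit whose fluorescence, transmission and content all mimic an
  authentic tablet would pass every tier; similarity to the reference never
  proves authenticity, and confirmatory chromatography remains the
  recommended follow-up for any positive colorimetric result.
* The colorimetric model assumes the acetic-acid extract's colour comes
  from the analytes alone; yellow interferents (documented in the bundled
  specificity table) can mimic lumefantrine, as happened for one study
  sample quantified at 121% LF with none detectable by HPLC.
* Quantification inherits 8-bit quantisation: zero-noise recovery is exact
  only to ±2 percentage points by design, and the low (10%) calibration
  level carries the largest relative quantisation error.
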