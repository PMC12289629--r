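---
title: "Colorimetric chlorophyll estimation: models, calibration and QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric chlorophyll estimation: models, calibration and QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafchroma)
```

## The measurement principle

Leaf chlorophyll absorbs strongly in the blue and red and weakly in
the green, so the apparent color of a leaf under a fixed white
illuminant carries information about its pigment content. A low-cost
RGBC photodiode sensor pressed against the leaf (with an internal LED
and a light shield, so ambient light is excluded) reports four raw
intensities: filtered red, green and blue channels (R', G', B') and an
unfiltered broadband "clear" channel (C), all in counts/µW/cm².

`leafchroma` implements everything downstream of those four numbers.

## Color features

`normalize_channels()` rescales each filtered channel by the clear
channel onto a 0–255 scale (`r = r_raw / c_raw * 255`, likewise g and
b). This cancels overall gain: multiplying all four channels by a
constant leaves r, g, b unchanged, which the test suite asserts as an
invariance property. No integer quantization is applied — rounding is
a sensor artifact, not part of the method.

`to_hsv()` applies the standard hexcone transform. Two conventions are
deliberate and load-bearing:

* **Scales.** Hue is in degrees on [0, 360); saturation and value on
  [0, 1], with value defined against the fixed 255 full scale
  (`v = max(r, g, b)/255`). The shipped model coefficients are only
  dimensionally sensible under this convention: a hue coefficient of
  0.008 against saturation/value coefficients of ~85 and ~−171 implies
  hue spans hundreds of units while s and v span one.
* **Achromatic inputs.** When max = min (including all-zero input),
  hue and saturation are defined as 0. The conversion must be total;
  zero is the common convention.

Hue and saturation are computed with `grDevices::rgb2hsv()`; the test
suite checks agreement with an independently hand-coded hexcone
conversion on 10<sup>4</sup> random triples to 10<sup>−9</sup>.

`derived_indices()` adds the ten ratio/product combinations. A zero
denominator raises a named error rather than emitting `NaN`: real leaf
readings never have a zero channel, and a silent `NaN` would corrupt a
calibration matrix long after the offending row was read. The full
vector from `extract_features()` has exactly 20 named features in a
fixed canonical order (4 raw channels, 3 normalized indices, 3 HSV,
10 combinations); note that the canonical order places the raw channel
`b_raw` before the normalized index `b`.

Replicates of one sample are averaged on the raw channels first and
features extracted once (`average_replicates()`). Averaging features
instead would not be equivalent for the nonlinear features (HSV,
ratios); channel-level averaging also matches how replicate summaries
are reported in instrument QC tables.

## Prediction models and the abnormality guard

`default_models()` carries the three calibrated five-feature models
(see the README for the equations). The two "blue" predictors are the
package's most confusable pair, so the naming is explicit and enforced:
`b` is the normalized blue index (0–255 scale), `b_raw` the raw blue
channel. The models are nearly additive by construction — the
total-chlorophyll coefficients equal the a + b sums exactly on h, s, v
and the intercept, and differ by ±0.001 on b and b_raw (third-decimal
rounding of the underlying fits) — giving the testable bound
|TCL − (CL-a + CL-b)| ≤ 0.001·(b + b_raw).

The device displays "detection error" instead of an implausible
number. The firmware's exact thresholds are not documented, so the
package defines the window itself: any negative content, or total
chlorophyll above 6 mg/g, is abnormal. The upper bound brackets the
largest total content observed on wheat and maize leaves (~4.9 mg/g)
with headroom; the window is a `predict_all()` argument, not a
constant. Internally all values keep full precision; rounding to 3
decimals happens only at the presentation layer (printing, CSV
output).

## Calibration workflow

`fit_mlr()` is ordinary least squares via `stats::lm()` with classical
homoscedastic t-test p-values — the style of significance table this
workflow screens against, with no robust-variance or multiple-testing
adjustment (raw p-values against α = 0.05). `select_significant()`
keeps features with p < α in canonical order; NA p-values (degenerate,
zero-residual fits) are treated as not significant, and α = 1 is
admitted as the "keep everything" limit. Reported R², RMSE and MAE are
fitting-set statistics, unadjusted and so labelled — they measure fit,
not out-of-sample performance.

`fit_plsr()` uses `mixOmics::pls()` in regression mode on centered,
unscaled predictors, reduced to its equivalent affine form so that a
PLSR fit and an MLR fit are the same kind of object. With as many
components as independent features PLSR reproduces the OLS solution
(asserted to 10<sup>−8</sup> in tests). When the component count is
not given it is chosen by leave-one-out cross-validated RMSE over
1..10 with ties broken toward fewer components — a standard choice
where the original workflow's count is unknown. The single-predictor
case is computed in closed form (the one PLS component spans the lone
centered predictor, so the fit is OLS on that feature).

Pooled fitting over both crops is the default, matching how the
shipped models were built; `run_evaluate(by_crop = TRUE)` stratifies
evaluation only.

## Reference assay

`arnon_concentrations()` maps the 645/663 nm absorbance pair of an
80 % acetone extract to pigment concentrations (mg/L) with the
canonical Arnon coefficient set for this wavelength pair
(12.7/2.69, 22.9/4.68, 20.2/8.02), exposed as a swappable matrix so a
national-standard variant can be substituted. A useful built-in
identity of this set: Ct − (Ca + Cb) = −0.01·A645 exactly (the A663
terms cancel; the residue is a rounding artifact of the published
coefficients). `content_per_mass()` applies the mass balance
`mg/g = mg/L × volume/1000 / mass`; intermediate dilution steps of the
extraction protocol collapse into the final volumetric-flask volume
(default 5 mL), which is all that enters the balance.
`check_reference_consistency()` validates any reference table against
additivity of total chlorophyll before calibration.

## Instrument QC

All coefficients of variation use the **population** (divide-by-n)
standard deviation. That choice is not cosmetic: it is the convention
that exactly reproduces, at three decimals, the per-channel stability
CVs of the bundled example timepoint data (0.911/1.103/0.941/0.771 %),
which sample-SD does not. `repeatability_report()` computes CVs from
raw replicates only; `cv_from_summary()` exists separately for
checking printed mean ± SD tables, whose 1-decimal rounded SDs cannot
always regenerate the tabulated CVs exactly.

## Synthetic data

The generator (`generator_config()` and friends) emulates the study
conditions the shipped example data come from:

* raw channels uniform within R' ∈ [24, 32], G' ∈ [22, 30],
  B' ∈ [17, 22], C ∈ [70, 90] counts/µW/cm² — the envelope of the
  bundled leaf readings — each filtered channel capped at C. Uniform
  sampling is assumption-minimal: no distributional shape for field
  leaf colors is documented;
* a default of 132 samples, the modeling-set size (71 wheat + 61
  maize, which is also the mixed-crop labelling proportion);
* contents generated **from the shipped models** plus Gaussian noise
  (default SD 0.1 mg/g, the order of those models' fitting RMSEs),
  rather than from an independent leaf-optics simulation. This makes
  the shipped models the planted ground truth that recovery tests can
  check exactly (noiseless data must return the coefficients to
  10<sup>−6</sup>);
* replicate jitter default 0.3 counts per channel, the typical
  replicate SD in the bundled repeatability data.

Rows are redrawn until both the noisy contents and the noise-free
model predictions fall inside the plausibility window, so generated
datasets both carry in-range references and measure "ok" end-to-end —
the full-pipeline closure property is then structural rather than
statistical. Empirically the generated total-chlorophyll minimum sits
around 0.5–0.8 mg/g across seeds.

What passing tests on this generator do **not** show: robustness to
real-leaf phenomena the generator omits — vein-induced channel
variance on narrow leaves, correlated channel noise, diurnal pigment
drift, or model misspecification (contents are generated from the very
models being recovered). Validation RMSEs on real leaves are a
property of field data this package cannot manufacture.

## Device workflow emulation

`device_step()` is the measurement state machine: INIT → WELCOME →
READY → MEASURING → RESULT or ERROR, with the flip button cycling the
RESULT display through the three contents, the transmit button
emulating the radio link as an append to a JSON-lines sink file, and
ERROR/TRANSMITTED returning to READY on a tick. The hardware's timing
(the ~1 s welcome screen, ~2 s measurement) is modeled as zero-cost
`tick` events — timing is hardware-bound and not testable in software.
The transition table gives TRANSMITTED an explicit outgoing edge
(tick → READY), since a real device returns to the measurement prompt.
Illegal events are warning no-ops: a button press must never crash the
instrument. Randomized event fuzzing in the test suite asserts that
only the allowed edges are ever taken.

## Numerical choices and problem sizes

* Exact-recovery assertions use 10<sup>−6</sup> (coefficients) and
  10<sup>−8</sup> (PLSR/OLS equivalence); the HSV oracle comparison
  uses 10<sup>−9</sup>. CV checks against 3-decimal tabulated values
  compare rounded values exactly.
* Property sweeps use 10<sup>4</sup> random cases under fixed seeds;
  Monte-Carlo checks (RMSE → noise SD, coefficient coverage within 3
  SE) use n = 10<sup>4</sup> and 100 replications of n = 200
  respectively — large enough for stable statistics, small enough
  that the whole suite runs in well under a minute of compute.
* Tie-breaks: LOO component selection rounds CV-RMSE to 12 decimals
  before `which.min`, so numerically-tied counts resolve to the
  smaller one deterministically.
* Degenerate inputs: zero clear channel, negative channels, empty
  replicate lists, rank-deficient designs and zero-mean CV series all
  raise structured `leafchroma_*` conditions rather than propagating
  NaN.

## Known limitations

The shipped models are calibrated for wheat and maize leaves measured
with this sensor geometry; nothing here transfers them to other
species or instruments. The package does not model the sensor physics
(LED spectrum, photodiode response) and cannot correct for it; it
reproduces the computational contract of the device, not its optics.
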