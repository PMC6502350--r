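---
title: "Methods: synthetic BOLD-CVR cohorts and false-negative activation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic BOLD-CVR cohorts and false-negative activation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldcvr)
```

## The scientific problem

Task-evoked BOLD-fMRI infers neuronal eloquence from a vascular signal.
When the vascular bed has little vasodilatory reserve left — quantified by
BOLD cerebrovascular reactivity (CVR), the percent BOLD signal change per
mmHg change in end-tidal CO2 (PetCO2) — a working neural population may
fail to produce a super-threshold BOLD response. The activation map then
shows a *false negative*: a type II error that is clinically dangerous
when such maps guide surgery.

`boldcvr` implements the full analysis chain needed to study this effect
under controlled conditions: a generator of synthetic two-condition
studies (a normocapnic baseline and a hypercapnic baseline that halves
the effective CVR), voxel-wise CVR mapping, a mass-univariate task GLM,
and region-of-interest comparisons across conditions. Because every
synthetic voxel has a known ground truth, each stage is verifiable by
parameter recovery; no real MRI data are required.

## The generative model

Each subject is a digital phantom (default grid 24 x 24 x 12, 3 mm
voxels) containing the nine motor-network regions (bilateral pre- and
postcentral gyri, frontal opercula, cerebella, and the SMA) as
equal-sized blocks on a non-brain background. Per region the phantom
embeds four ground-truth values: CVR and task percent signal change, each
under the two CO2 baselines; defaults come from
`default_region_truth()`, literature-informed group means for healthy
adults in which the hypercapnic CVR column is roughly half the
normocapnic one (the vasodilatory saturation the elevated baseline
produces). A voxel's CVR-run signal is

S(t) = S0 [ 1 + CVR/100 ( PetCO2(t - lag) - baseline ) ] + S0 drift(t) + noise,

with per-voxel hemodynamic lags drawn uniformly from [0, 8] s and
quantized to the 1 s CO2 sampling grid (quantization makes *exact* lag
recovery a testable contract). The task-run signal replaces the CO2 term
with dpct/100 times the unit-peak HRF-convolved block regressor — the
same regressor the GLM fits, so the task coefficient reads directly in
percent. Noise is independent Gaussian per voxel and timepoint (sd in
percent of S0; default 1), chosen over an autocorrelated model so that
ordinary-least-squares standard errors stay exact and null calibration is
checkable against the t distribution. Drift is an order-2 Legendre
polynomial with coefficients uniform in +/- the configured amplitude
(default 0: the CVR regression deliberately carries no drift regressors,
matching its plain least-squares formulation, so the default conditions
do not embed a nuisance the model does not remove). What the generator
does *not* emulate: head motion, slice-timing offsets, spatial
correlation of noise, physiological (cardiac/respiratory) fluctuations,
and partial-volume anatomy. Passing recovery tests therefore demonstrates
the correctness of the estimators, not their robustness to artifacts of
real scanners.

The simulated stimulus follows the two-condition protocol: a 100 s
baseline clamp at the subject's resting PetCO2 (default 38 mmHg, a
conventional healthy value; the protocol is configurable), a pseudo-square
step of +10 mmHg held for 80 s with 6 s linear ramps (gas delivery cannot
switch instantaneously; the ramp time is a package choice as only the
plateau is standard), and a return to baseline, over 200 volumes at TR
2 s. The hypercapnic condition raises the clamp by 6 mmHg and uses the
hypercapnic truth columns. Task runs are 135 volumes: four 30 s
finger-tapping blocks alternating with 30 s rest, starting with rest, on
a constant CO2 clamp.

## CVR mapping

`compute_cvr_map()` performs, per masked voxel (mask: combined grey plus
white matter probability >= 0.8):

1. **Percent conversion** against the voxel's mean over the baseline
   clamp window (the protocol's initial clamp; 100 s by default). Voxels
   with zero baseline are excluded and flagged.
2. **Temporal smoothing**: a zero-phase order-4 Butterworth low-pass
   (default cutoff 0.1 Hz — far above the ~0.006 Hz stimulus fundamental,
   so the step passes while thermal noise is removed) followed by robust
   locally weighted regression (lowess, span 10% of the run, 2 bisquare
   iterations). Numerical care: the filter runs forward and backward over
   an odd-reflection-padded, demeaned series, which makes the whole
   smoother exactly affine-equivariant; and the robust lowess pass is
   skipped when the plain fit's residual scale is below 1e-6 of the
   series' own spread, because bisquare weights computed from a collapsed
   residual median are meaningless. Both choices are what make the
   noise-free recovery contracts exact rather than approximate.
3. **Lag estimation**: candidate lags on a 1 s grid within +/- 10 s; each
   candidate regressor is the CO2 trace interpolated at the volume
   midpoints shifted by the lag, then smoothed *identically* to the voxel
   signal. The lag maximizing the correlation wins; ties break toward the
   smallest |lag|, then toward the negative lag. Lags on the window
   boundary are flagged as saturated; zero-variance voxels are kept with
   lag 0 and flagged, so mask accounting stays explicit. Positive lag
   means the BOLD signal follows the CO2.
4. **OLS fit** of the smoothed percent signal on the lag-aligned smoothed
   regressor, with intercept. The slope is the voxel's CVR (%/mmHg); the
   t-value is slope over standard error, capped at 1e6 when the fit is
   numerically exact.

Smoothing the regressor with the same operator as the data is the one
place this pipeline departs from a naive reading of "smooth the BOLD
data": a linear smoother applied to only one side of an exactly linear
relation biases the slope by about a percent. Applying it to both sides
leaves the relation intact (the smoother is a linear operator with
scale-invariant robustness weights), removes the bias entirely, and is
what makes a zero-noise phantom recoverable to 1e-6.

Whether lag estimation should run on smoothed or raw series is left
configurable (`cvr_config(smooth = )`); the default smooths first, which
stabilizes the correlation under noise.

## Task GLM

The design matrix holds the unit-peak HRF-convolved task regressor
(double-gamma HRF: peak 6 s, undershoot 16 s, dispersions 1 s, ratio 1/6
— the canonical parameterization; the boxcar is convolved at 0.1 s
resolution and sampled at volume midpoints), optional nuisance columns
(the motion-covariate slot; synthetic runs have no motion), optional
polynomial drift terms, and an intercept. Rank deficiency is an error
naming the offending columns. Percent conversion uses the first rest
block. The task coefficient *is* the percent signal change (dpct) because
the regressor has unit peak — the normalization is stated rather than
inherited from any particular software convention, since conventions
differ (unit boxcar amplitude is the main alternative; unit peak was
chosen so that a sustained response of x percent yields a coefficient of
x). A caveat documented here because a spec-style idealization gets it
wrong: with a canonical undershoot, the convolved response to a long
block transiently overshoots its plateau, so after unit-peak
normalization the plateau sits near 0.93, not exactly 1.

Significance uses strict exceedance, t > 3.43 by default (the stated
average familywise-corrected p < 0.05 level for this design; the package
treats the value as a given threshold and implements no FWE machinery).
Cross-condition comparisons are made over the *combined* significant
voxel set — voxels significant in at least one of the two task runs — the
voxel set over which regional means are tabulated by default
(`roi_voxel_set = "combined_sig"`; whole-anatomical-ROI means are one
flag away, since which set a published table used is often ambiguous).
Note one consequence visible in recovery runs: selecting voxels by their
noisy t-values truncates the lower tail of the activation distribution,
so combined-significant regional dpct means sit a few hundredths above
the embedded truth. This is a property of the analysis definition, not an
estimator defect, and the same selection acts on real data.

## Region-level statistics

Per region and condition the package tabulates mean CVR, mean dpct, mean
t and significant-voxel counts; compares conditions with two-sided paired
t-tests (Bonferroni factor: 9 regions x 4 measures by default,
configurable and reported; over two conditions the repeated-measures
ANOVA is the same test, exposed as an alias); regresses ROI-mean
activation on ROI-mean CVR (with one predictor, stepwise selection
degenerates to simple OLS — implemented as such) per condition and
pooled, for both the (dpct, dpct) and (t, t) pairings; and identifies
false-negative voxels (significant under normocapnia, sub-threshold under
hypercapnia) plus the low-activation/preserved-CVR set (dpct < 1 and
CVR > 0.15 among activated voxels, strict on both sides).

Degenerate inputs are handled explicitly rather than left to chance:
empty regional voxel sets yield flagged NA rows; zero-variance paired
differences yield t = 0, p = 1 (all-zero) or a flagged p = 0 (constant
nonzero); zero predictor variance is a regression error.

## Cohort orchestration and reproducibility

`run_cohort()` drives the whole chain for n subjects (default 17) from
one master seed. Per-subject seeds follow
`(master_seed + 7919 * i + stage) mod (2^31 - 1)` with stage offsets 0-4
(phantom, CVR normo/hyper, task normo/hyper), so subjects are independent
and any cohort is reproducible bit for bit; identical configurations
produce byte-identical report CSVs. With an output directory set, all
intermediate volumes (NIfTI-1), tables (CSV), a structured plain-text log
and a JSON summary are written. There is no resume-from-intermediates
mode: reproducibility is guaranteed by determinism of the end-to-end run
instead.

## Problem sizes and expected runtimes

The defaults are desk-scale by design: a 24 x 24 x 12 grid gives 384
voxels per region (3456 brain voxels), enough for stable regional means
while a full 17-subject, two-condition cohort (34 CVR maps + 34 GLM
fits) completes in roughly two minutes on one core. Unit tests use a
12 x 12 x 6 grid and a shortened protocol. Null-calibration checks use
50 single-subject replicates on the small grid; the false-negative
direction check uses 10 independent master seeds.

## Known limitations

- Estimated lags under noise have a mean absolute error of 1-2 s
  (normocapnia) to ~3 s (hypercapnia, where the response is weaker);
  the induced slope attenuation is well under the reported tolerances
  but lag maps themselves should be read as noisy.
- The generator's condition-specific slopes encode vasodilatory
  saturation as two operating points rather than a sigmoidal
  dose-response; the package fits no sigmoid models.
- No BIDS ingestion, no spatial preprocessing (the phantom is generated
  aligned), no FreeSurfer integration, and no familywise-error
  calibration.
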