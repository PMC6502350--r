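# boldcvr

Voxel-wise BOLD cerebrovascular reactivity (CVR) mapping and analysis of
**false-negative task-fMRI activation** — with a fully synthetic study
generator so that every stage is verifiable by parameter recovery.

## The problem

Task-evoked BOLD-fMRI reads neuronal activity through a vascular proxy.
A voxel can only raise its BOLD signal if its vascular bed still has
vasodilatory reserve; that reserve is measured as BOLD-CVR, the percent
signal change per mmHg change in end-tidal CO2 (PetCO2):

    CVR = Δ%BOLD / ΔPetCO2   [%/mmHg]

When CVR is impaired — here provoked experimentally by raising the CO2
baseline ~6 mmHg, which roughly halves CVR — task t-values drop below
the significance threshold in tissue that is known to respond. Those
voxels are *false negatives* (type II errors), a direct hazard wherever
activation maps guide clinical decisions. `boldcvr` is for researchers
who want to study, teach, or validate this effect: it simulates
two-condition (normocapnic / hypercapnic baseline) CVR + finger-tapping
studies with known voxel-wise ground truth and runs the complete
analysis chain on them.

## What the package computes

| Stage | Function | Model |
|---|---|---|
| CO2 stimulus | `make_co2_trace()` | 100 s clamp, +10 mmHg pseudo-square step for 80 s, 6 s ramps |
| Phantom | `make_phantom()` | 9 motor-network regions, per-region CVR/activation truth, per-voxel lags in [0, 8] s |
| Simulated runs | `simulate_cvr_run()`, `simulate_task_run()` | S(t) = S0·[1 + CVR/100·(CO2(t−lag) − base)] + drift + noise |
| CVR map | `compute_cvr_map()` | percent-normalize → low-pass + robust lowess → voxel-wise lag by cross-correlation → OLS slope, t = slope/SE |
| Task GLM | `fit_task_glm()`, `threshold_tmap()` | mass-univariate OLS on a unit-peak double-gamma-HRF regressor; significant iff t > 3.43 |
| ROI comparison | `summarize_roi()`, `paired_condition_test()`, `regress_cvr_vs_dpct()` | regional means over combined-significant voxels, paired t + Bonferroni, activation ~ CVR regression |
| False negatives | `false_negative_voxels()`, `low_activation_high_cvr()` | sig(normo) \ sig(hyper); dpct < 1 & CVR > 0.15 |
| Cohort | `run_cohort()` | all of the above for n subjects from one master seed |

## Worked example

One subject, normocapnic condition, end to end:

```r
library(boldcvr)
proto   <- protocol_spec()                       # TR 2 s, 200/135 volumes
spec    <- subject_spec(subject_id = "sub-01", seed = 11)
phantom <- make_phantom(spec)                    # 24 x 24 x 12 grid
mask    <- make_analysis_mask(phantom$gm_prob, phantom$wm_prob, 0.8)

co2 <- make_co2_trace(proto, "normo", spec$resting_petco2_mmHg)
run <- simulate_cvr_run(phantom, co2, proto, "normo", seed = 12)
fit <- compute_cvr_map(run, co2, mask)
summary(fit)
#> BOLD-CVR map (normo)
#>   voxels in mask : 3456 (0 flagged)
#>   CVR            : 0.2604 +/- 0.0418 %/mmHg
#>   lag            : mean 3.94 s, range [-5, 9] s

tp   <- make_task_paradigm(proto, spec$resting_petco2_mmHg)
task <- simulate_task_run(phantom, tp$paradigm, proto, "normo", seed = 13)
reg  <- hrf_convolved_regressor(tp$paradigm, hrf_spec(),
                                proto$n_volumes_task, proto$tr_seconds)
act  <- threshold_tmap(fit_task_glm(task, build_design(reg), mask), 3.43)
act
#> Task activation map (normo): 3456 masked voxels, 1968 significant at t > 3.43

tab <- summarize_roi(fit, act, phantom, voxel_set = "all_masked")
head(tab[tab$modality == "cvr",
         c("region", "mean_dpct", "mean_tvalue", "n_sig_voxels")], 4)
#>              region mean_dpct mean_tvalue n_sig_voxels
#> 1  precentral right 0.2190718    50.33527          317
#> 3   precentral left 0.2096416    48.02733          310
#> 5 postcentral right 0.2363826    54.29042          335
#> 7  postcentral left 0.2572290    57.96119          317
```

Reading the numbers: the phantom embedded a ground-truth CVR of 0.22
%/mmHg in the right precentral region and a whole-mask mean of 0.2633;
under 1% noise the map recovers 0.219 and 0.260. With the embedded task
response (0.85% signal change in the precentral gyri) most motor-region
voxels clear t > 3.43 under normocapnia. Re-running the same pair of
fits under `condition = "hyper"` roughly halves every CVR estimate, and
`false_negative_voxels()` then counts the voxels that lose significance.

A full cohort is one call:

```r
report <- run_cohort(cohort_config(n_subjects = 17, master_seed = 1))
report          # whole-brain CVR per condition, false-negative summary
summary(report) # group mean +/- sd per region, condition and modality
plot(report)    # ROI-mean activation vs CVR scatter, both conditions
```

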