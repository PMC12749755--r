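# aortaflow

Quantification of chronic aortic regurgitation (AR) from 2D phase-contrast
cardiovascular magnetic resonance (PC-CMR) velocity image series, for
imaging scientists and CMR methodologists who need a fully testable,
scriptable version of the clinical workflow.

In PC-CMR a pixel's phase encodes through-plane velocity,
`v = VENC * phi / pi`, so integrating velocity over the vessel lumen gives
volumetric flow `Q(t)` (mL/s) across the cardiac cycle. From `Q(t)` the
regurgitant volume and fraction follow directly:

- **RVol** = diastolic backward flow volume, `|∫_diastole min(Q, 0) dt|` (mL)
- **RF** = `100 · RVol / ∫ max(Q, 0) dt` (% of the positive flow volume)
- **HFR** = holodiastolic flow reversal: `Q(t) ≤ −10 mL/s` throughout diastole
- **DFR velocity** = end-diastolic spatial-mean reversal velocity (cm/s),
  severe AR predicted when `> 19.5 cm/s`

Measuring in the ascending aorta is hampered by complex flow and vessel
dilation, so the package implements the transfer of the outcome-based
ascending-aorta severity cut-offs (RVol > 42 mL, RF > 33 %) to the
descending aorta: fit `y_DA = a·x_AAo + b` by ordinary least squares on a
paired cohort, evaluate the line at the reference cut-offs, and round —
with the published cohort relations this yields the descending-aorta
cut-offs **RVol > 17 mL** and **RF > 23 %**. Diagnostic performance of the
transferred cut-offs is summarized by confusion matrices, sensitivity and
specificity (Wilson CIs), likelihood ratios (log-method CIs), Bland–Altman
agreement and ROC/AUC.

Because no patient data ship with the package, a synthetic module generates
(a) velocity-encoded phantom image series — systolic/diastolic flow
waveforms with controllable RVol/RF/HFR, elliptical lumina under plane
angulation, VENC phase wrapping, planar eddy-current offsets, Gaussian
velocity noise — and (b) paired cohorts drawn from the published linear
relations, so every stage of the pipeline is exercised end to end.

## Worked example

```r
library(aortaflow)

## 1. Simulate a velocity-encoded phantom: 80 mL forward volume, 30 mL
##    holodiastolic regurgitation, 30 degrees of plane angulation, a
##    1.5 cm/s planar eddy-current offset and 1 cm/s velocity noise.
params  <- acquisition_params(venc = 180, noise_sd = 1,
                              offset_coeffs = c(1.5, 0.02, -0.01), seed = 7)
spec    <- waveform_spec(forward_volume = 80, rvol_true = 30,
                         reversal_shape = "holodiastolic")
phantom <- render_phantom(build_waveform(spec, params),
                          vessel_spec(radius = 12, angulation = 30), params)

## 2. Quantify: decode -> segment -> offset-correct -> integrate -> metrics
res <- quantify_phantom(phantom)
res$metrics
#> <regurg_metrics> site=descending RVol=29.2 mL RF=37.5% forward=77.8 mL sysBackward=0.0 mL HFR=TRUE
res$offset$residual_static_mean
#> [1] 0.012  # cm/s, well under the 0.6 cm/s acceptance limit
```

The recovered RVol (29.2 mL) agrees with the 30 mL ground truth within the
partial-volume error budget despite angulation, offset and noise, and the
holodiastolic reversal is detected.

```r
## 3. Threshold transfer + validation on a simulated derivation cohort
tab <- simulate_cohort(cohort_model(preset = "cohort1-rvol"), seed = 1)
fit_linear(tab)
#> <linear_fit> y = 0.571 x -5.301  R = 0.913 (0.842-0.953)  RMSE = 8.37  n = 41
bland_altman(tab)
#> <bland_altman> bias 32.80  LoA (1.12, 64.49)  n = 41

rep <- run_pipeline(pipeline_config(seed = 1))
c(rep$rvol$thresholds$derived, rep$rf$thresholds$derived)
#> [1] 19 22   # this seed's cohort; the published relations give 17 and 23
rep$rvol$auc
#> [1] 0.9886364
```

A single 41-patient draw recovers the generating relation (slope 0.59,
R 0.93, bias 32.3 mL in the population) within sampling error, and the
descending-aorta metric discriminates significant AR with high AUC. The
published relations themselves reproduce the printed cut-offs exactly:

```r
derive_threshold(list(slope = 0.59, intercept = -7.43), 42)$threshold  # 17
derive_threshold(list(slope = 1.01, intercept = -10.04), 33)$threshold # 23
```

## Command line

```sh
Rscript inst/scripts/aortaflow simulate --preset cohort1-rvol --seed 1 --out cohort.csv
Rscript inst/scripts/aortaflow fit      --in cohort.csv --reference 42 --out fit.json
Rscript inst/scripts/aortaflow evaluate --in cohort.csv --reference 42 --threshold 17 --out eval.json
Rscript inst/scripts/aortaflow run      --seed 1 --out report/
```

## Documentation

The methods vignette (`vignettes/aortaflow-methods.Rmd`) describes the flow
model, the phantom's error model (wrapping, offsets, noise, partial
volume), the metric definitions and boundary conventions, the threshold
transfer, and what the synthetic world does and does not establish.
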