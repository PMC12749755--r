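---
title: "Quantifying aortic regurgitation from PC-CMR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aortic regurgitation from PC-CMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortaflow)
```

## The problem

Chronic aortic regurgitation (AR) — diastolic backflow through an
incompetent aortic valve — is graded volumetrically with phase-contrast
cardiovascular magnetic resonance (PC-CMR): a velocity-encoded image plane
across the aorta yields a volumetric flow curve over the cardiac cycle,
from which the regurgitant volume (RVol) and regurgitant fraction (RF)
follow. The reference measurement site, the ascending aorta just above the
sinotubular junction, is unreliable when the vessel is dilated or the flow
is helical; the descending aorta offers a cleaner signal but its severity
cut-offs are not established. This package implements the full measurement
chain plus the transfer of ascending-aorta outcome-based cut-offs
(RVol > 42 mL, RF > 33 %) to the descending aorta via a linear
inter-site relation, and the machinery to validate the transferred
cut-offs.

## Velocity encoding and its error model

A phase pixel encodes through-plane velocity by

$$v = \mathrm{VENC} \cdot \varphi / \pi, \qquad \varphi \in (-\pi, \pi],$$

so velocities beyond ±VENC alias by $2\,\mathrm{VENC}$. The simulator and
decoder share this convention; the wrap is a strict no-op for in-range
values, so decoding a sub-VENC encoding returns the input to machine
precision.

The phantom renderer models the measurement errors the pipeline is meant to
correct:

* **Plane angulation** $\theta$ between the plane normal and the flow
  direction makes the lumen elliptical (semi-axes $r$ and $r/\cos\theta$)
  while reducing measured through-plane velocity by $\cos\theta$. The two
  effects cancel in the lumen-integrated flow, which is why clinical flow
  measurements tolerate angulated planes in large vessels; only
  partial-volume error remains (the tested bound is < 3 % at
  $\theta = 30^\circ$ for lumina at least 10 pixels across).
* **Eddy-current background offsets**: a first-order (planar) spurious
  velocity field, constant over the cycle, added to all tissue. This is
  the simplest surrogate consistent with the "adaptive filtering"
  correction whose residual must stay below 0.6 cm/s.
* **Noise**: Gaussian velocity noise inside tissue; uniform random phase in
  air (defined as pixels darker than 10 % of the lumen magnitude — here the
  2-pixel image border).
* **Partial volume**: boundary pixels carry area-weighted velocity and
  magnitude (coverage by 4×4 subsampling).
* **Aliasing**: when the peak lumen velocity reaches the VENC the series is
  rendered anyway and flagged, so the unwrapping stage is exercised.

### Waveform family

Clinical flow reports publish no analytic waveform, so the
generator uses an integrable family with explicit control of every metric:
a half-sine systolic ejection; for holodiastolic reversal a diastolic
plateau with a shallow mid-diastolic bump (never shallower than the
10 mL/s floor — requesting a holodiastolic shape whose RVol cannot sustain
the floor is an explicit infeasibility error); for early-only reversal a
negative half-sine returning to zero by mid-diastole; and an optional
pre-ejection notch carrying the systolic backward volume (a surrogate for
complex flow). The notch sits at the start of systole so the end-systole
zero crossing after the peak is untouched. After sampling on the phase
grid, each lobe is rescaled so the discrete rectangle-rule integrals equal
the specified volumes exactly — the same integration convention the metrics
use, closing the generator→metrics loop to within 0.5 %.

## Flow quantification

1. **Decoding**: $v = \mathrm{VENC}\,\varphi/\pi$.
2. **Unwrapping**: per phase, lumen pixels deviating from the lumen spatial
   median by more than the VENC are shifted by ±2 VENC toward the median.
   Only one wrap order is repaired; if more than 20 % of the lumen wraps,
   the series is declared unrecoverable — mirroring the clinical practice
   of excluding such acquisitions rather than attempting heroic repair.
   Note that under plug flow an aliased jet wraps coherently and is
   invisible to a median reference; the repair is exercised with a
   parabolic profile in which only the jet core (~10 % of pixels) wraps.
3. **Offset correction**: least-squares planar fit to the time-averaged
   velocity of static tissue, subtracted from every phase. The reported
   residual is the mean over phases of the absolute per-phase static-region
   mean — a temporal-stability figure that is not forced to zero by the
   fit's normal equations — and is warned about above 0.6 cm/s.
4. **Segmentation**: region growing on the magnitude image from a seed
   point, threshold 0.5 × the median of the seed's 3×3 neighborhood
   (configurable), 8-connected component containing the seed; subsequent
   phases re-grow from the previous centroid. An area jump of more than
   50 % between adjacent phases raises a tracking-lost error. Manual
   contour editing, an operator step in clinical software, is out of scope.
5. **Integration**: $Q(t) = \sum_{\text{mask}} v \cdot A_{\text{px}}$,
   with 1 cm/s over 1 mm² = 0.01 mL/s.

VENC selection implements the clinical optimization rule: the smallest
candidate strictly above the expected peak, warning when the 20 % headroom
bound cannot be met.

## Metrics and boundary conventions

With diastole starting at the first downward zero crossing after the peak
(fallbacks: first point below 10 % of peak, then 40 % of cycle, both with
warnings; indices are 1-based):

* RVol $= |\sum_{\text{diastole}} \min(Q,0)\,\Delta t|$;
  forward volume $= \sum \max(Q,0)\,\Delta t$; RF $= 100\,$RVol/forward.
  The identity RF·forward/100 = RVol holds to machine precision by
  construction.
* HFR is **boundary-inclusive**: reversal of exactly 10 mL/s at every
  diastolic phase counts, reading "a minimum flow of 10 mL/s" as the floor
  of the reversal magnitude.
* DFR velocity defaults to the magnitude of the end-diastolic spatial-mean
  reversal velocity, mirroring the end-diastolic Doppler measurement it
  imitates; a time-averaged diastolic alternative is selectable because
  the PC-CMR operationalization is not fixed by the source material. The
  19.5 cm/s cut-off is strict (`>`), so exactly 19.5 is negative.
* Severity cut-offs are strict `>` everywhere (42 mL ascending RVol is
  *not* significant); aortic dilation is `≥ 40 mm`.
* Reproducibility between repeat measurements is
  $100\,|m_1-m_2| / \bar m$; the formula is not stated in the source
  material, so this choice is tagged in outputs.
* Time units: `flow_curve()` takes a declared `time_unit` ("ms" or "s")
  and normalizes internally, making every metric invariant to the declared
  unit.

## Threshold transfer

OLS of the descending on the ascending metric (the source presents the
relation in that direction; Deming regression would treat errors in both
variables and is a stated limitation, not implemented). Pearson R carries a
Fisher-z 95 % CI; RMSE uses the $n-2$ denominator (the fit's residual SD —
the divisor is not stated in the source). The transferred cut-off is the
line evaluated at the reference, rounded to the nearest integer;
nearest-vs-floor is tagged because both conventions reproduce the published
17 mL / 23 % here but may disagree for other references.

## Diagnostic performance

Sensitivity/specificity use Wilson score CIs and likelihood ratios the log
method — the source does not state its CI methods, so standard choices are
used and degenerate cells (e.g. a perfect classifier's PLR) are flagged
`undefined` rather than silently continuity-corrected (Haldane's 0.5 is
opt-in). Bland–Altman differences are fixed as ascending − descending,
matching the positive published biases. The ROC sweeps all observed
thresholds with strict `>` classification; the trapezoid AUC is verified
against the exhaustive pairwise Mann–Whitney count (ties one half) on every
small instance.

## What the synthetic world establishes — and what it does not

The cohort generator draws the ascending metric from the published
derivation-cohort moments (RVol: mean 61, SD 37 mL; RF: mean 38, SD 16 %)
untruncated — negative draws are retained as abstract metric values so the
printed fit parameters imply the printed correlation — and the descending
metric from the published lines plus Gaussian residuals (SD 9). Under that
model the simulated mean Pearson R is ≈ 0.92 (RVol) and ≈ 0.87 (RF), and
the mean Bland–Altman bias ≈ 32.4 mL; the RF population correlation
implied by the published parameters (0.874) sits slightly below the
published 0.89, a small internal inconsistency of the printed values that
the generator reproduces faithfully rather than recalibrating away.

Green tests therefore establish that the pipeline implements the stated
definitions and recovers known ground truth under the stated error model.
They do **not** establish clinical diagnostic performance: the phantom has
no k-space physics, coils, gating artifacts or real vessel motion, the
cohort model has no outcome data, and the published patient-level confusion
matrices and CIs cannot be re-derived without the unavailable data.
Repeat-measurement noise (reproducibility) has no published generating
parameters; its SD is a free parameter defaulting to 6 metric units.

## Numerical choices

* Rectangle-rule integration with uniform phase spacing (equal to the
  trapezoid rule on a periodic uniform grid); non-uniform spacing warns and
  uses the mean interval.
* Lobe rescaling in the generator guarantees discrete-integral closure at
  any `n_phases ≥ 8`.
* Segmentation and mask propagation are fully deterministic given the
  series and seed point; all stochastic stages consume explicit integer
  seeds and restore the caller's RNG state.
* Reports serialize with fixed digits so identical seeds give byte-identical
  JSON.

## Known limitations

Single 2D slice only (no 4D flow); no DICOM ingestion; OLS rather than
errors-in-variables transfer; the unwrapper repairs one wrap order; the
DFR-velocity definition is one of several defensible readings; phantom
magnitudes are schematic (bright lumen / mid tissue / dark air), not
SSFP-realistic.
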