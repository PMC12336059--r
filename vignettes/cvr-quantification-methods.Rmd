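---
title: "Methods: CVR quantification from CO2-challenge MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CVR quantification from CO2-challenge MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrquant)
```

## What this package computes

Cerebrovascular reactivity (CVR) is the fractional hemodynamic response of
the brain per mmHg of arterial CO2 change, measured here with a 5% CO2
inhalation challenge and two complementary MRI readouts:

* **CBF-CVR** — global, from phase-contrast (PC) flow through the superior
  sagittal sinus (SSS) during room air and hypercapnia;
* **BOLD-CVR** — voxelwise, from a gradient-echo EPI time series regressed
  on the end-tidal CO2 (EtCO2) curve.

Alongside these, venous oxygenation (Yv) is estimated with
T2-relaxation-under-spin-tagging (TRUST), a Davis-type forward model links
the two CVR readouts mechanistically, and a statistics layer reproduces the
two-group (caffeine-naive / caffeine-habituated) pre/post-caffeine crossover
analysis.  A synthetic-data generator renders every raw input from explicit
ground truth, so the entire image-to-number chain is validated by recovery.

## End-tidal CO2 extraction

The capnograph records CO2 partial pressure at 20 Hz.  End-tidal values are
the per-breath maxima: `detect_envelope()` finds prominence-filtered local
maxima separated by at least `min_breath_interval` (default 2 s, i.e. a
breathing rate of at most 30 breaths/min; prominence floor 1 mmHg rejects
ripple).  The breath-wise envelope is linearly interpolated onto the scan
grid and constant-extrapolated at the edges.  Fewer than three detected
breaths is treated as a signal-quality failure.

Scalar summaries follow the analysis conventions: `mean_etco2` is the
arithmetic mean of the resampled curve, and `baseline_etco2` is the mean of
the **bottom 25% of resampled (time-uniform) samples** — a duration-weighted
statistic, deliberately not a per-breath quantile, so long room-air phases
dominate the baseline.  With a protocol attached, `delta_etco2` is instead
the hypercapnic-block minus room-air-block mean.  The baseline is computed
*after* time-shift alignment, on the scan-overlapping segment.

## CBF-CVR from phase contrast

The session acquires three 1-minute PC scans: room air, then two after the
switch to hypercapnic gas.  Scans 1 and 3 enter the CVR computation; scan 2
falls in the physiological transient and is parsed but excluded.  Each
scan's EtCO2 is the breath-wise mean inside its acquisition window.

Stored PC velocities live in `(-venc, venc]`; true velocities beyond the
venc wrap by multiples of `2*venc`.  `unwrap_velocity()` corrects ROI
voxels whose sign opposes the ROI-median flow direction and whose value
lies within `0.5*venc` of the opposite rail — a documented, configurable
heuristic that handles single wraps, is idempotent, and only ever moves a
voxel by exactly `2*venc`.

Flux is the ROI sum of velocity times voxel area (`cm/s * mm^2 * 0.01 * 60`,
giving ml/min), and unit-mass CBF is

    CBF = BF * 100 / (0.46 * Bvol * 1.06)    [ml/100 g/min]

with 0.46 the SSS fraction of whole-brain flow, 1.06 g/ml the tissue
density, and Bvol the brain volume, a metadata input (on real data it comes
from structural segmentation, which is out of scope here).  CBF-CVR is the
percent CBF change per mmHg EtCO2 change; the Bvol factor cancels, and the
implementation verifies flux-based and CBF-based CVR agree to 1e-12.

## BOLD-CVR mapping

The block protocol is 15 s room air, then two 55 s hypercapnic phases
interleaved with 75 s room-air phases, the last room-air phase running to
the end of the 300 s scan (TR 1.5 s, 200 dynamics).  Preprocessing is
Gaussian smoothing (separable, edge-renormalized kernel; default FWHM 0 on
synthetic data) and intensity-threshold masking; motion correction is an
identity hook because generated data are motion-free.

The EtCO2 curve is time-shifted to the global (mask-mean) BOLD signal by
maximizing Pearson correlation over a discrete shift grid (default ±30 s in
0.1 s steps; ties break toward the smallest |shift|).  Both signals are
linearly detrended before correlation — the GLM models drift separately,
and symmetric detrending keeps the zero-shift correlation exact on
trend-free data.  One global shift is used per scan; voxelwise delay
mapping is out of scope.  If the best correlation is below 0.2 the delay is
unidentifiable; the caller chooses an error or a shift of 0 with a warning.

Each voxel is then fit by ordinary least squares on
`[1, zero-mean shifted EtCO2, linear trend]`, where the trend is the
unit-step sequence centred on zero, `-(N-1)/2, ..., (N-1)/2`.  The CVR map
references the percent signal change to the *room-air state* rather than
the scan mean:

    CVR = beta1 / (beta0 - beta1 * (mean_etco2 - baseline_etco2)) * 100

Voxels with a non-positive denominator are flagged invalid and excluded
from ROI means (never clipped).  This referencing makes recovery exact when
the generator uses the same room-air baseline convention, and the map is
invariant to multiplicative rescaling of the raw series.

Before group statistics, CVR values can be normalized for baseline EtCO2
and EtCO2 change with `adjust_cvr()`.  The upstream literature gives the
sensitivity of CVR to these factors (≈2% per mmHg of baseline EtCO2, ≈4%
per mmHg of ΔEtCO2, population mean baseline 38.1 mmHg) but not a closed
functional form; we implement a multiplicative linear adjustment with all
coefficients exposed, defaulting to those slopes and to an 8 mmHg reference
step.  Atlas parcellation is replaced by user-supplied native-space ROI
masks.

## TRUST venous oximetry

Label/control pairs at effective TEs 0/40/80/160 ms are subtracted pairwise
(static tissue cancels), the **top-4 highest-intensity voxels** inside the
sinus ROI of the shortest-eTE difference image are selected (deterministic
index-order tie-break; which eTE ranks voxels is unspecified upstream, and
eTE = 0 has the best SNR), their signals are spatially averaged per eTE and
fit with `S(eTE) = S0 * exp(-eTE/T2)` by nonlinear least squares
(Levenberg–Marquardt, log-linear initialization).  No T1 correction across
eTEs is applied.  Blood T2 converts to Yv through a strictly monotone
quadratic-relaxivity calibration `R2 = a + b*(1-Yv) + c*(1-Yv)^2` with
Hct-linear coefficients, using Hct 0.40 (female) / 0.42 (male).  Validated
calibration coefficients are instrument/literature-specific and not shipped;
the default file is a clearly labelled synthetic stand-in with plausible
venous T2 values, and every test relies on round-trip consistency rather
than specific coefficients.

## The Davis-type link between the two CVR readouts

The hypercapnic BOLD response is modelled as

    dBOLD/BOLD0 = k * CBV0 * dHb0^beta * (1 - (CBF_HC/CBF_0)^(alpha-beta))

with `dHb0 = 1 - Yv0`.  Defaults `alpha = 0.38`, `beta = 1.5` are the
conventional 3 T values — conventions, not study-derived estimates — and
`k` is unidentifiable from CVR data, fixed at 1 unless calibrated.
Whether dHb0 should additionally scale with hematocrit is left open
upstream; we use `1 - Yv0` alone.  `attenuation_analysis()` compares the
percent change of CBF-CVR and of predicted BOLD-CVR between two states.
When caffeine weakens the flow response *and* lowers basal Yv, the rise in
dHb0 counteracts the flow-driven loss, so the signed BOLD-CVR reduction is
strictly smaller than the CBF-CVR reduction across the whole
`alpha ∈ [0.2, 0.5] × beta ∈ [1, 2]` grid.  For the observed oxygenation
shift (0.608 → 0.469) and beta ≳ 1 the offset is strong enough that the
model can even predict a BOLD-CVR *increase*; the robust, tested property
is the directional attenuation, not a specific percentage.

## Statistics layer

Percent change uses the reduction-positive convention
`(pre - post)/pre * 100`.  Within-group comparisons are two-sided paired
t-tests with Shapiro–Wilk checks on the differences; between-group
comparisons default to Welch (the pooled test is an option; the upstream
choice is unstated).  The crossover model is

    outcome ~ caffeine * group + sex + age + (1 | subject)

fit by REML with caffeine coded pre = 0 / post = 1 and the naive group as
reference; p-values use the Satterthwaite approximation and CIs are Wald by
default (profile optional) — the upstream software and df method are
unstated, so coefficients, not p-values, are the recovery surface.
Degenerate cases are conventions, not errors: identical paired vectors give
t = 0, p = 1; a singular (zero random-intercept variance) fit is flagged
and its fixed effects coincide with OLS.

## The synthetic-data generator

The generator defines the study conditions; every downstream stage is
tested by recovering its configured truth.

* **Capnograph**: raised-cosine breaths (4 s period, trough 2 mmHg) whose
  per-breath maxima equal the condition level at the peak time, so the
  envelope follows the block schedule within one breath.  Only the maxima
  matter downstream; the intra-breath shape is unconstrained.
* **BOLD**: the forward model *is* the analysis GLM — baseline times
  `(1 + cvr/100 * (EtCO2(t - delay) - EtCO2_ra))` plus linear drift and
  white noise, with a pure 6 s shift (no HRF convolution, matching the
  shifted-regressor analysis).  Default grid 16×16×8, beta0 1000, noise SD
  10 (1%), drift 0.02/dynamic.
* **PC**: truncated-parabolic velocity profile over an elliptical sinus
  (~48 mm² at 0.16 mm² voxels), scaled so the ROI-integrated flux equals
  the configured value exactly before noise (velocity noise SD 0.5 cm/s);
  venc 40 (room air) / 60 (hypercapnia) cm/s, with values beyond venc
  stored wrapped; fluxes implying velocities beyond 2*venc are refused as
  irrecoverable.
* **TRUST**: four bright sinus voxels (matching the top-4 selection) over
  cancelling static tissue, venous signal `S0 * exp(-eTE/T2)` with T2 from
  the calibration at the subject's Hct; image noise SD 2 (S0 = 100).
* **Cohort**: per-subject (pre, post) truths drawn from bivariate normals
  with the configured group means/SDs and within-subject correlation 0.7
  (per-state SDs are reported upstream but not correlations; 0.7 gives
  paired-test power comparable to the reported significances).  Group
  compositions 3M/5F and 5M/3F, ages 28.6 ± 5.2 / 29.1 ± 2.7, brain volume
  1200 ± 100 ml.

Generator values not fixed by the study report, chosen once as field-typical
and documented here: absolute basal CBF means (60 naive / 55 habituated
ml/100 g/min, with the reported SDs 15.4 / 5.9 and the reported percent
reductions fixing the post-caffeine means), the 8 mmHg hypercapnic EtCO2
step (typical for 5% CO2; per-subject SD 1 mmHg), baseline EtCO2
38.1 ± 4.5 / 3.2 mmHg, and all image SNRs above.  Per-group BOLD-CVR
configurations reuse the pooled 0.17 ± 0.04 → 0.15 ± 0.05 values, the only
ones reported.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify on real data: subject motion, cardiac/respiratory
nuisance cycles, partial-volume effects, multi-vessel PC anatomy,
background phase offsets, HRF dispersion, and scanner drift beyond a linear
trend.

## Numerical choices and degenerate inputs

* GLM: 3-column normal equations (centred regressors keep the design well
  conditioned); verified against an explicit least-squares oracle at 1e-8.
* T2 fit: Levenberg–Marquardt with log-linear start; non-positive signals
  fall back to a configurable T2 start (60 ms); verified against a T2 grid
  search with profiled-out S0.
* Calibration inverse: closed-form quadratic root on the monotone branch;
  domain violations produce errors stating the admissible range.
* Smoothing: separable Gaussian, per-axis kernels normalized and edge rows
  renormalized, so constants are fixed points and interior mass is
  conserved.
* Alignment ties break toward the smallest |shift|; the correlation floor
  (0.2) marks unidentifiable delays.
* Wrap detection: only voxels within `0.5*venc` of the opposite rail are
  corrected — a single-wrap assumption; double wraps are refused at
  generation and out of scope in analysis.

## Problem sizes used in validation

Recovery runs simulate 200 replicate cohorts per target (8 subjects/group,
the study size) at the default grids: 16×16×8 × 200 dynamics for BOLD with
alignment search ±15 s in 0.5 s steps (the true 6 s delay is on-grid;
package defaults remain ±30 s / 0.1 s), 64×64 PC images and 32×32 TRUST
slices.  Grand means are required to sit within 3 Monte-Carlo standard
errors of the configured means — an unbiasedness statement about the full
image-to-number chain, with ~1600–6400 rendered scans per quantity.

## Known limitations

* The alignment assumes a positive global CO2 response; subjects with a
  truly absent/inverted response (possible in the Gaussian tails of the
  simulated cohorts) fall back to shift 0 with a warning.
* The EtCO2 adjustment's functional form is a documented assumption
  (multiplicative linear), not an upstream-published equation.
* The shipped TRUST calibration coefficients are synthetic placeholders;
  real-data use requires a validated coefficient file.
* ROI masks are supplied (or synthesized) in native space; no spatial
  normalization or atlas machinery is included.
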