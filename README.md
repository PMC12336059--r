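# cvrquant

Quantification of cerebrovascular reactivity (CVR) from CO2-challenge MRI,
built around a caffeine crossover study design: two groups (caffeine-naive
and caffeine-habituated, n = 8 each) measured before and after a 200 mg
caffeine dose.

CVR — the hemodynamic response per mmHg of CO2 — is a marker of
cerebrovascular health, but it varies substantially across individuals for
physiological rather than instrumental reasons. This package implements the
full image-to-number chain needed to quantify that variation with two
complementary MRI readouts, and a synthetic-data generator that renders
every raw input from known ground truth so the whole chain is testable by
recovery:

* **EtCO2 extraction** — breath-wise end-tidal envelope of a 20 Hz
  capnograph trace (prominence-based peak detection, resampling to the scan
  grid, mean / bottom-25% baseline summaries).
* **CBF-CVR** (global) — phase-contrast flux through the superior sagittal
  sinus with venc unwrapping:
  `CBF = BF · 100 / (0.46 · Bvol · 1.06)` and
  `CVR = (ΔCBF/CBF_RA · 100) / ΔEtCO2` in %/mmHg.
* **BOLD-CVR** (voxelwise) — time-shifted EtCO2 regressor in a GLM,
  `BOLD(t) = β0 + β1·EtCO2(t, s) + β2·l`, mapped with the
  room-air-referenced formula
  `CVR = β1 / (β0 − β1·(mean(EtCO2) − baseline(EtCO2))) · 100`,
  plus EtCO2-based adjustment and ROI summaries.
* **TRUST oximetry** — label/control subtraction, top-4 voxel selection,
  mono-exponential T2 fit over eTEs 0/40/80/160 ms, and a monotone
  T2 ↔ Yv calibration with sex-based hematocrit.
* **Davis-type forward model** —
  `ΔBOLD/BOLD0 = k·CBV0·dHb0^β·(1 − (CBF_HC/CBF_0)^(α−β))`, explaining why
  a ~30% CBF-CVR reduction appears as a much smaller BOLD-CVR reduction
  when basal venous oxygenation drops too.
* **Group statistics** — percent changes, Shapiro–Wilk, paired and Welch
  t-tests, and the crossover mixed model
  `outcome ~ caffeine * group + sex + age + (1 | subject)`.

## Worked example

Simulate one subject, render the raw phase-contrast session, and quantify
CBF-CVR from the rendered data alone:

```r
library(cvrquant)

cohort <- generate_cohort(cohort_spec(), seed = 7)
subj   <- cohort[1, ]
inp    <- render_pc_inputs(subj, "pre", seed = 3)
est    <- estimate_cbf_cvr(inp$trace, inp$pair$ra, inp$pair$hc,
                           inp$pair$roi, subj$bvol)
c(true = inp$truth$cvr, estimated = est$cvr)
#>      true estimated
#>  5.596695  5.599036
c(cbf_ra = est$cbf_ra, etco2_ra = est$etco2_ra, etco2_hc = est$etco2_hc)
#>    cbf_ra  etco2_ra  etco2_hc
#>  62.29454  39.64163  45.85574
```

`est$cvr` is the percent CBF change per mmHg EtCO2 (%/mmHg): this subject's
sinus flux rose ~5.6% per mmHg of CO2, recovering the configured truth to
0.04% despite velocity noise, because flux integration is exactly
conservative and the EtCO2 block levels are recovered breath-exactly.

The full study-scale analysis lives in `analysis/` as numbered drivers:

```sh
Rscript analysis/01_simulate_cohort.R   # render the 16-subject cohort
Rscript analysis/02_cbf_cvr.R           # PC chain  -> results/cbf_cvr_estimates.csv
Rscript analysis/03_bold_cvr.R          # BOLD chain -> results/bold_cvr_estimates.csv
Rscript analysis/04_trust_yv.R          # TRUST chain -> results/yv_estimates.csv
Rscript analysis/05_group_stats.R       # t-tests + mixed model -> results/*.csv
Rscript analysis/06_davis_mechanism.R   # attenuation grid -> results/davis_attenuation.csv
```

On the default seed, step 3 reports whole-brain BOLD-CVR pooled over groups
falling from 0.167 to 0.151 %/mmHg (matching the configured truth) with the 6 s
hemodynamic delay recovered for every subject, and step 5's mixed model
gives a caffeine effect of −1.40 %/mmHg on CBF-CVR and a positive
caffeine × group interaction on venous oxygenation — the habituated group's
smaller drop.

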