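# crossmark

Cross-platform quantitation and harmonisation of a three-protein plasma
biomarker panel (APOA4, CD5L, IGFBP3) measured both by immunoaffinity
mass spectrometry (IAMS, targeted MRM with stable-isotope dilution) and by
sandwich ELISA. The panel, combined with age, HDL-cholesterol and eGFR in a
logistic risk model, yields a 0–100 risk score for progression of diabetic
kidney disease; the package's purpose is to show that the score is
concordant across the two measurement platforms once the systematic
inter-platform bias is removed.

It is written for assay developers and clinical-proteomics analysts who need
the whole chain as reproducible code: transition-level MRM reports in,
harmonised concentrations, QC verdicts and score concordance out.

## What it does

- **IAMS quantitation** — from Skyline-style transition reports
  (Total Area / Total Background per light/heavy peptide): peaks must have
  S/N > 5 on both labels; the unlabelled:labelled area ratio is averaged over
  4 calibrator replicates whose effective plasma concentration is
  `c_cal × V_cal / V_plasma` (e.g. 18.3 µg/mL × 50 µL / 10 µL = 91.5 µg/mL),
  and sample concentrations follow as
  `c = c_eff × r_sample / r̄_calibrator`, flagged against the plasma working
  range.
- **ELISA quantitation** — 7-point 4PL standard curves
  `OD = d + (a − d) / (1 + (x/c)^b)` fitted per plate
  (Levenberg–Marquardt), closed-form inversion, low/high QC recovery gates
  (±20%), and per-analyte plasma dilution factors (×400, ×1600, ×200).
- **Assay validation** — linearity (OLS, R²), LOD/LOQ rules, intra/inter-assay
  precision ("average % CV"), and stability verdicts under the FDA
  ligand-binding 20%/20% accuracy/precision criteria.
- **Batch QC gating** — each batch's reference-plasma means must sit within
  the rolling mean ± 2 SD of all previously accepted batches
  (Levey–Jennings style; provisional acceptance until 5 batches of history).
- **Harmonisation & concordance** — Bland–Altman bias per analyte (additive,
  or multiplicative on the log scale), a one-sample t-test of zero bias,
  adjustment of the ELISA values onto the IAMS scale, logistic risk scores
  on both platforms, and a pass/fail concordance rule: > 90% of subjects
  within 5 score points.
- **Synthetic cohort** — a generator for a paired 100-subject cohort with
  known truth (log-normal analyte distributions, per-platform noise,
  injected inter-platform biases), simulated 96-well IAMS batches and ELISA
  plates, so every stage is testable end to end without clinical data.

## Worked example

```r
library(crossmark)
run <- run_pipeline(default_config(seed = 1))
print(run)
#> crossmark pipeline run (seed 1 )
#>   cohort: 100 subjects
#>   QC B01: provisional
#>   QC B02: provisional
#>   APOA4: additive bias +45.965 ug/mL (p = 1.6e-83)
#>   CD5L: additive bias +0.433 ug/mL (p = 2.48e-27)
#>   IBP3: bias factor 9.385 (p = 3.87e-138)
#> Score concordance (n = 100): R = 0.972
#>   98.0% of subjects within 5 points (need > 90%): PASS
```

The synthetic cohort injects an ELISA scale offset of −47.93 µg/mL (APOA4),
−0.53 µg/mL (CD5L) and ×9.52 (IGFBP3); the Bland–Altman stage recovers
these as the printed adjustments (+45.97, +0.43, ÷9.39 at this seed — each
within sampling error of the injected value at n = 100 and 5% analytical
CV). The two provisional QC lines show the rolling-2SD gate in bootstrap
mode: with fewer than 5 historical batches the SD is too unstable for a
hard gate. After adjustment, 98% of subjects score within 5 points across
platforms and the score correlation is 0.97, so the run passes the
concordance rule.

Individual stages are plain functions with classed results:

```r
print(run$bland_altman$APOA4)
#> Bland-Altman [APOA4], additive mode, n = 100
#>   bias (add to comparator): +45.96; LoA [32.27, 59.66]
#>   t = 65.8, p = 1.6e-83 (H0: zero mean difference)

print(run$plates$CD5L$curve)
#> 4PL standard curve [CD5L]
#>   a=0.06084  b=1.105  c=1.313 ng/mL  d=1.877   R^2=0.99981
#>   working range: 0.1562-10 ng/mL (7 standards)
```

`write_run(run, "out/")` writes the concentration tables, QC ledger, paired
adjusted values, risk scores and a text report as delimited text.

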