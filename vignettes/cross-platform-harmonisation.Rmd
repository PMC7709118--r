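---
title: "Methods: cross-platform quantitation, QC and harmonisation of a plasma biomarker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform quantitation, QC and harmonisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmark)
```

crossmark implements the full measurement chain for a three-protein plasma
panel (APOA4, CD5L, IGFBP3) run on two platforms — immunoaffinity MRM mass
spectrometry (IAMS) and sandwich ELISA — and the statistics needed to show
that a composite risk score computed from either platform agrees. This
vignette is the package's account of the models, the tunable parameters,
the synthetic-data design, and the choices made where the design was open.

## 1. IAMS quantitation model

Each analyte is read out through one proteotypic peptide monitored light
(endogenous) and heavy (spiked ¹³C/¹⁵N standard, 400 fmol per well). The
quantitation model is single-point stable-isotope-dilution calibration:

- **S/N filter.** Every integrated peak must satisfy
  S/N = Total Area / Total Background > 5 on *both* labels before a ratio
  is formed. The threshold is strict (`> 5`): a peak at exactly 5 fails. A
  zero background with positive area is treated as infinite S/N (it cannot
  fail a noise criterion it exceeds by construction); zero area over zero
  background is a missing peak. A missing light or heavy record yields a
  flagged row, never an exception, so one dropped peak does not abort a
  96-well batch.
- **Transition aggregation.** When several transitions are monitored per
  peptide, areas and backgrounds are summed per label before ratioing.
  This is standard practice and is robust to individually weak
  transitions; the alternative (per-transition ratios averaged) weights
  noisy transitions equally and was rejected.
- **Calibration.** The calibrator is processed at 50 µL against 10 µL of
  plasma, so a solution at concentration $c$ represents an effective plasma
  concentration $c \cdot 50/10$. The four calibrator replicate ratios are
  averaged; a replicate CV ≥ 20% or fewer than two S/N-passing replicates
  is a calibration failure that aborts the batch (the 20% figure is the
  FDA ligand-binding precision criterion). Note the arithmetic for the two
  lower calibrators (0.686 and 0.178 µg/mL × 5 = 3.43 and 0.890 µg/mL)
  differs in the third digit from some printed reference values (3.45,
  0.892); the package always computes the formula.
- **Sample concentration.** $c_s = c_{\mathrm{eff}} \cdot r_s / \bar r_{\mathrm{cal}}$.
  Values outside the plasma working range (APOA4 37.5–200, CD5L 0.104–10,
  IGFBP3 0.0104–1.00 µg/mL) are *flagged* (`below_lod`, `above_range`) but
  reported: the downstream Bland–Altman analysis needs the values, and the
  flags carry the uncertainty. Blank wells are quantified like samples and
  a warning is raised when a blank's apparent concentration exceeds the
  analyte LOD; no numeric blank-subtraction rule is applied.

Two invariances characterise this model and are enforced as property
tests: rescaling every area in a batch by a constant changes no
concentration, and rescaling one sample's light *and* heavy areas together
changes nothing while rescaling only its light area scales its
concentration proportionally.

## 2. ELISA quantitation model

Each analyte runs on its own plate at its own plasma dilution (1 in 400 /
1600 / 200 for APOA4 / CD5L / IGFBP3), with a 7-point two-fold standard
series spanning the assay range and low/high QC wells.

- **Curve.** $OD = d + (a-d)/(1+(x/c)^b)$, fitted by unweighted
  least squares with Levenberg–Marquardt (`minpack.lm::nlsLM`), starting at
  $a=\min OD$, $d=\max OD$, $c=$ geometric mean of the standards, $b=1$.
  The fit is unweighted because no weighting scheme is specified for these
  assays and the OD noise is modelled (and simulated) as additive; on
  well-behaved sigmoid data the heuristic start converges reliably. At
  least 5 distinct levels are required.
- **Inversion.** Closed form, $x = c((a-d)/(OD-d)-1)^{1/b}$, valid only for
  OD strictly between the asymptotes; out-of-curve wells are flagged, not
  errored. Round-trip identity holds to well below 10⁻⁹ in OD.
- **Plate QC.** Every QC well must back-calculate within ±20% of nominal
  (the FDA ligand-binding accuracy criterion; the assays' own limits are
  not published) and the curve must reach R² ≥ 0.99 for the plate to pass.
- **Units.** Plasma µg/mL everywhere; ng/mL only at the assay level:
  plasma = assay × dilution / 1000. Blank OD is not subtracted by default —
  the 4PL lower asymptote absorbs it.

## 3. Validation statistics

- *Linearity*: OLS of measured on nominal over a ≥ 5-level dilution series,
  with per-level accuracy and CV.
- *LOD/LOQ*: the reference tables report LODs without a formula, so the
  rules here are explicit and returned with the estimate. LOD = lowest
  level with all replicates detected (S/N rule for MRM, mean blank + 3 SD
  for OD-based detection); LOQ = lowest level within 20% accuracy and
  < 20% CV.
- *Precision*: intra-assay CV is the *average* of within-batch CVs (the
  "average % CV" convention of the reference tables); inter-assay CV is the
  CV of batch means. Per-batch CV averaging was chosen over a pooled
  variance because it matches how such panels are conventionally reported.
- *Stability*: paired stressed/baseline arms (4 °C and room temperature at
  1 h vs 24 h; 1–3 freeze-thaw cycles) pass when |%difference| ≤ 20 and
  both arms' CV < 20%; a freeze-thaw summary as the average CV across the
  0–3× cycle arms is also provided.

## 4. Batch QC gate

A reference plasma (4 replicates) runs in every batch. The batch is
accepted when each analyte's reference mean lies within the rolling
mean ± 2 SD of **all previously accepted** batches. Three choices were
open:

- *Window*: all prior batches, no forgetting factor — the rolling-average
  description is cumulative.
- *Start-up*: with < 5 prior batches the SD estimate is too unstable for a
  hard gate, so decisions are "provisional" (accepted with a warning). The
  threshold of 5 is a pragmatic floor on SD stability.
- *Failed batches* are excluded from the rolling statistics, the standard
  QC practice that prevents a drifting process from widening its own
  acceptance band.

Under in-control simulation the long-run rejection rate per analyte is the
two-sided 2 SD tail (≈ 4.6%) when the current statistic has the same
variance as the history — with a 4-replicate mean it is accordingly
smaller; both regimes are checked empirically in the suite.

## 5. Harmonisation and concordance

Bland–Altman agreement is computed per analyte in a configured mode:
**additive** (differences IAMS − ELISA; bias = mean difference; limits of
agreement ± 1.96 SD) or **multiplicative** (log-scale differences; the bias
is the geometric mean ELISA/IAMS factor, limits back-transformed). Defaults
are additive for APOA4 and CD5L and multiplicative for IGFBP3, matching the
structure of their observed disagreement (constant offsets vs a ~9.5× scale
factor). A diagnostic correlation of difference vs pair mean supports the
choice, but the mode never auto-switches — silent switching would make runs
incomparable.

The attached test is a two-sided one-sample t of zero mean difference on
the analysis scale ($t = \bar d/(s_d/\sqrt n)$, df $= n-1$); degenerate
zero-variance differences are defined as $t=0, p=1$ when the mean is also
zero (identical pairs) and $|t|=\infty, p=0$ otherwise. Adjustment adds the
bias to (or divides the factor out of) the ELISA values, after which the
mean (log-)difference is zero by construction — to 10⁻¹⁰ in the property
tests. The adjustment is estimated in-sample on the same cohort, as a
method-comparison study does; a split-sample design would halve the cohort
for no inferential gain at this n.

**Risk score.** score $= 100 \cdot \mathrm{logit}^{-1}(\beta_0 + \beta^\top x)$
with $x =$ (APOA4, CD5L, IGFBP3, age, HDL, eGFR). The production
coefficients of the published score are proprietary; the packaged default
is a synthetic, documented placeholder with clinically sensible directions
(risk increases with age, CD5L, IGFBP3; decreases with APOA4, HDL, eGFR)
and a realistic score spread (~3–45 for the default cohort). Every
coefficient is overridable via `risk_model()` or the YAML config; all
concordance machinery is agnostic to the coefficient values.

**Concordance rule.** Pearson correlation of the paired scores plus the
fraction of subjects whose absolute score difference is ≤ 5 points; pass
requires that fraction to *strictly* exceed 90%. "Within 5%" is read as 5
absolute percentage points on the 0–100 score scale: scores are themselves
percentages, and a relative rule is unstable near zero. Both the allowable
difference and the threshold are configurable.

## 6. The synthetic cohort: what it emulates, and what it does not

The generator stands in for a paired 100-subject plasma cohort; its
defaults are fixed study conditions, not tuning knobs.

- **Truth**: per-analyte log-normal concentrations — strictly positive and
  right-skewed like plasma proteins — with medians 110 / 3.0 / 0.45 µg/mL
  and geometric CVs 0.30 / 0.40 / 0.40. The medians sit near the middle of
  the platforms' plasma working ranges (APOA4 is placed high enough that
  the −47.93 µg/mL ELISA offset leaves apparent concentrations positive
  for essentially all subjects); the reference data report working ranges
  but not cohort distributions, so these are stated assumptions.
  Covariates: age ~ N(65, 10) (truncated 30–95), HDL log-normal
  (median 1.3 mmol/L, GCV 0.25), eGFR ~ N(75, 20) (truncated 10–140).
- **Inter-platform bias**: ELISA-apparent = truth − 47.93 (APOA4),
  truth − 0.53 (CD5L), truth × 9.52 (IGFBP3) — the additive/multiplicative
  magnitudes the harmonisation stage is designed around.
- **IAMS response**: ratio linear through the origin in concentration
  (single-point calibrator normalisation presumes exactly this
  proportionality), slope defaulting to 1/calibrator-effective-concentration
  so calibrator ratios sit near 1. Noise is multiplicative log-normal on
  the ratio (CV 5%) — the dominant error mode of area ratios — heavy areas
  log-normal around 10⁶ (CV 10%), and backgrounds drawn about an absolute
  noise floor giving typical S/N ≈ 50. Blank wells carry only background
  in the light channel.
- **ELISA response**: OD = 4PL(assay concentration) + additive Gaussian
  noise (SD 0.01 absorbance units over a ~1.8-unit curve), floored at 0.
- **Seeding**: one master seed; every sub-generator (cohort, each batch,
  each plate, each noise stream) draws from an integer substream derived
  from it, so arms are independent yet byte-reproducible.

Problem sizes used throughout the suite: cohorts of 100 subjects (split
into two 96-well IAMS batches of ≤ 85 samples plus 4 calibrators, 4
reference-plasma wells, 2 blanks and a double blank), one ELISA plate set
per analyte, and 20 replicate cohorts for the bias-recovery study — sizes
chosen to match the emulated study design while keeping a full run in
seconds.

What the simulation does **not** contain — and therefore what passing
tests cannot show about real data: chromatographic peak-shape or
integration artefacts (areas are simulated post-integration),
plate-position (edge) effects, antibody cross-reactivity or matrix
interferences, between-day drift beyond independent batch calibrations,
and non-constant (concentration-dependent) inter-platform bias. Parameter
recovery here validates the statistical machinery, not the assays'
chemistry.

## 7. Numerical choices and degenerate inputs

- 4PL inversion refuses ODs at or beyond the asymptotes (flag, not error);
  fitted-curve round-trips are exact to < 10⁻⁹ OD.
- Zero-variance Bland–Altman differences and zero-variance score lists are
  handled with defined degenerate values (see above) rather than NA
  propagation or errors, because simulated noiseless fixtures hit these
  paths routinely.
- S/N at exactly the threshold fails (strict inequality, as "greater
  than 5" states).
- Working-range flags use closed intervals; a value exactly at a bound is
  in range.
- All tabular I/O is header-named delimited text; column order is never
  significant, and vendor-style headers ("Total Area") are normalised on
  read.

## 8. Known limitations

- The default risk coefficients are placeholders; absolute score levels
  are meaningful only relative to a supplied coefficient set.
- LOD/LOQ rules are package-defined (the reference values' derivation is
  unpublished); reported LODs from other sources cannot be reproduced
  exactly and are not forced.
- The QC gate implements only the 2 SD rule — no multi-rule Westgard
  schemes.
- Deming or Passing–Bablok regression is deliberately out of scope; the
  harmonisation is the Bland–Altman mean-bias adjustment only.
- ELISA intra/inter precision uses the same averaging conventions as the
  IAMS assay; variance-component models (CLSI EP05) are not implemented.
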