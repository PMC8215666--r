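# periomr

Bidirectional two-sample Mendelian randomization (MR) between chronic
periodontitis (CP) and kidney-function biomarkers — estimated glomerular
filtration rate (eGFR) and blood urea nitrogen (BUN) — from GWAS summary
statistics, packaged as a reusable MR toolkit.

Observational studies repeatedly associate periodontitis with chronic kidney
disease, but confounding (smoking, diabetes, socioeconomic status) and
reverse causation make the direction and existence of a causal link
uncertain. MR sidesteps these by using germline genetic variants as
instrumental variables: allele assignment at conception precedes disease and
is essentially randomized, so a variant that raises the exposure can probe
the exposure's downstream causal effect. `periomr` implements the full
two-sample workflow for both causal directions, with the CP instruments from
the GLIDE consortium GWAS (12,289 cases / 22,326 controls) and the eGFR/BUN
instruments from the CKDGen consortium GWAS (439,303 participants) built in
as fixtures.

## Methods

For instrument *j* with exposure association β<sub>Xj</sub> (SE
σ<sub>Xj</sub>) and outcome association β<sub>Yj</sub> (SE σ<sub>Yj</sub>),
both expressed on the same effect allele:

- **Wald ratio**: θ̂<sub>j</sub> = β<sub>Yj</sub>/β<sub>Xj</sub>, SE
  σ<sub>Yj</sub>/|β<sub>Xj</sub>| (first order).
- **IVW**: θ̂ = Σ β<sub>Xj</sub>β<sub>Yj</sub>σ<sub>Yj</sub>⁻² / Σ
  β<sub>Xj</sub>²σ<sub>Yj</sub>⁻², the inverse-variance-weighted mean of the
  ratios (equivalently weighted through-origin regression). Under the
  multiplicative random-effects model the fixed-effects SE is inflated by
  φ = max(1, √(Q/(J−1))), Q being Cochran's heterogeneity statistic.
- **Weighted median**: the ratio at cumulative weight ½; consistent when
  valid instruments carry ≥ 50% of the weight. Parametric-bootstrap SE.
- **MR-Egger**: weighted regression of β<sub>Yj</sub> on β<sub>Xj</sub> with
  a free intercept after orienting β<sub>Xj</sub> ≥ 0; the slope estimates
  the causal effect under InSIDE, the intercept the average directional
  pleiotropy, its test being the standard pleiotropy diagnostic.

Instrument selection applies the three IV assumptions as successive filters:
association-strength threshold → confounder/outcome blocklist → greedy LD
clumping → Steiger directionality filtering (drop variants explaining more
variance in the outcome than the exposure, r² = z²/(z² + n)). A
synthetic-data module generates paired summary statistics under a known
causal effect and pleiotropy model so every estimator's calibration (bias,
coverage, type-I error) is testable against ground truth.

## Worked example

Does blood urea nitrogen causally affect periodontitis risk?

```r
library(periomr)
tabs  <- cpkd_tables()   # built-in instrument tables
metas <- cpkd_metas()    # study sample sizes

rep <- run_direction(tabs$bun_exposure, tabs$cp_outcome,
                     metas$bun, metas$cp,
                     mr_config(p_threshold_exposure = 5e-8, seed = 1))
print(rep)
```

```
<direction_report> BUN -> CP: J = 9, power = 0.956 at effect 1
          method estimate    se ci_low ci_high     p n_snps q_statistic
             ivw   -0.021 0.728 -1.447   1.405 0.977      9       0.934
              wm    0.351 0.891 -1.395   2.098 0.693      9          NA
     egger-slope   -1.013 2.332 -5.584   3.558 0.664      9          NA
 egger-intercept    0.009 0.021 -0.032   0.051 0.654      9          NA
```

All nine genome-wide-significant BUN instruments survive harmonization and
Steiger filtering. The IVW estimate of the effect of BUN on CP log-odds is
−0.021 (95% CI −1.447 to 1.405, p = 0.977): no evidence of a causal effect,
and the weighted-median and Egger sensitivity analyses agree. The
nonsignificant Egger intercept (0.009, p = 0.65) shows no detectable
directional pleiotropy in this direction. `run_bidirectional()` runs all
four directions (CP→eGFR, CP→BUN, eGFR→CP, BUN→CP) at once;
`forest_data()`, `scatter_data()` and `write_direction_report()` export
plot-ready tables.

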