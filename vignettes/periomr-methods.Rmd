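---
title: "Methods: bidirectional two-sample MR for periodontitis and kidney function"
author: "periomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR for periodontitis and kidney function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periomr)
```

## The model

Two-sample Mendelian randomization estimates the causal effect $\theta$ of
an exposure $X$ on an outcome $Y$ from two independent GWAS. For each
instrument $j$ the exposure study reports $\hat\beta_{Xj}$ with standard
error $\sigma_{Xj}$, the outcome study $\hat\beta_{Yj}$ with
$\sigma_{Yj}$. The working model is

$$\beta_{Yj} = \theta\,\beta_{Xj} + \alpha_j,$$

where $\alpha_j$ is the direct (pleiotropic) effect of variant $j$ on the
outcome. A variant is a valid instrument when it is (i) associated with the
exposure, (ii) independent of exposure–outcome confounders, and (iii)
affects the outcome only through the exposure ($\alpha_j = 0$). The package
encodes these assumptions as a selection chain and offers estimators whose
validity degrades gracefully as assumption (iii) fails: IVW (all
instruments valid), weighted median (≥ 50% of weight valid), MR-Egger
(valid under the weaker InSIDE condition that $\alpha_j$ is independent of
instrument strength).

Here the exposure/outcome pairs are chronic periodontitis (CP; GLIDE
consortium, 12,289 cases / 22,326 controls, so $n = 34{,}615$ and case
fraction $0.355$) against two continuous kidney-function biomarkers from
the CKDGen consortium ($n = 439{,}303$): estimated glomerular filtration
rate (eGFR, the primary biomarker) and blood urea nitrogen (BUN). The
analysis is bidirectional: four direction reports, CP→eGFR, CP→BUN,
eGFR→CP, BUN→CP, each with its own instrument set. CP effects are on the
log-odds scale; eGFR and BUN effects on the source GWAS's (log-transformed,
standardized) trait scales.

## Instrument selection

`run_direction()` applies four stages, each of which partitions its input
into retained and dropped records with logged reasons:

1. **Relevance** (`filter_by_pvalue`): keep associations with $p$ strictly
   below the threshold. Default $5\times10^{-6}$ — the suggestive level
   used for the CP exposure, whose GWAS yields few genome-wide-significant
   hits; the kidney-function exposures use the conventional
   $5\times10^{-8}$.
2. **Independence** (`exclude_blocklisted`): drop variants reported as
   associated with the outcome or a named confounder. The blocklist is a
   local table (`SNP TRAIT SOURCE`) standing in for an online trait-catalog
   query, so the stage is reproducible offline.
3. **LD clumping** (`ld_clump`): greedy thinning — rank by ascending $p$
   (ties broken by the lexicographically smallest identifier, for
   determinism), accept the best, drop same-chromosome variants with
   $r^2 > 0.001$ to an accepted variant within 10,000 kb. These defaults
   are the conventional two-sample MR settings; both are configurable. The
   distance window needs base-pair positions (optional `POS` column) and is
   ignored without them; variants absent from the LD matrix pass with a
   warning, since published instrument tables rarely carry LD information.
4. **Directionality** (`steiger_filter`): per variant, compare the variance
   explained in exposure and outcome, $r^2 = z^2/(z^2+n)$ with
   $z = \beta/\sigma$ and the trait's total sample size; drop variants
   explaining at least as much outcome as exposure variance, which act
   against reverse causation. This $z$-based approximation needs only the
   printed summary statistics and applies to both continuous and
   case-control traits; exact ties are retained (a tie carries no
   directional evidence).

Harmonization (`harmonize`) sits between stages 3 and 4: the outcome
association is re-expressed on the exposure's effect allele, negating the
beta and complementing the frequency when the allele labels are swapped.
Allele sets that disagree even after swapping are dropped — no strand
inference is attempted, because inferring strand from labels alone invites
silent sign errors. Palindromic variants (A/T, C/G) are flagged and dropped
only when an available allele frequency falls within 0.08 of 0.5 (window
configurable, boundary inclusive): away from 0.5 the frequencies still
identify the shared allele, at 0.5 they cannot. None of the built-in
instruments is affected — the published tables are already harmonized — so
this policy is exercised only by the synthetic tests.

## Estimators

With weights $w_j = (\beta_{Xj}/\sigma_{Yj})^2$ and ratio estimates
$\hat\theta_j = \beta_{Yj}/\beta_{Xj}$:

- **Wald ratio** (single SNP): $\hat\theta_j$ with first-order SE
  $\sigma_{Yj}/|\beta_{Xj}|$. First-order weights ignore exposure
  uncertainty throughout; with the strong instruments the selection chain
  enforces, the neglected term is second-order, and it keeps the estimator
  an exact function of the published columns.
- **IVW**: $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$, the weighted
  through-origin regression of $\beta_Y$ on $\beta_X$. Fixed-effects SE
  $(\sum_j w_j)^{-1/2}$; the multiplicative random-effects model inflates
  it by $\phi = \max(1, \sqrt{Q/(J-1)})$ with Cochran's
  $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$, so heterogeneity widens
  but never narrows the interval. The default `"auto"` model uses fixed
  effects for $J \le 3$ (too few instruments to estimate heterogeneity
  usefully) and random effects otherwise.
- **Weighted median**: order the $\hat\theta_j$, normalize weights, take
  the value at cumulative weight $\tfrac12$ using the half-weight-shifted
  cumulative sums with linear interpolation between bracketing order
  statistics. SE by parametric bootstrap: redraw
  $\beta_{Xj} \sim N(\hat\beta_{Xj}, \sigma_{Xj}^2)$,
  $\beta_{Yj} \sim N(\hat\beta_{Yj}, \sigma_{Yj}^2)$, recompute; default
  10,000 draws, seed mandatory so results are reproducible by
  construction.
- **MR-Egger**: orient every instrument to $\beta_{Xj} \ge 0$ (negate both
  betas otherwise — required for the intercept to mean "average directional
  pleiotropy"), then weighted least squares of $\beta_Y$ on $\beta_X$ with
  weights $\sigma_{Yj}^{-2}$ and a free intercept. Both SEs are scaled by
  $\max(1, \sqrt{RSS_w/(J-2)})$, the residual scale floored at 1,
  mirroring the IVW convention.

All confidence intervals and $p$-values use the normal reference
($z_{0.975} = 1.959964$), not $t$: with the small instrument counts here
the choice is material, and the normal reference reproduces the published
intervals and $p$-values from the fixture tables, which a $t$ reference
does not.

## Power

`power_estimate()` implements the standard normal-approximation power for
summary-data MR. Continuous outcome: noncentrality
$|\theta|\sqrt{n\,r^2}$, with $r^2$ the exposure variance explained by the
instruments, and
$\mathrm{power} = 1 - \Phi(z_{1-\alpha/2} - \mathrm{ncp}) +
\Phi(-z_{1-\alpha/2} - \mathrm{ncp})$. Binary outcome: the same with the
noncentrality scaled by $\sqrt{cf(1-cf)}$ for case fraction $cf$, the
effect then a log odds ratio. Direction reports evaluate power at the
configurable reference effect `power_effect` (default 1 outcome unit per
exposure unit) using the per-direction $r^2 = \sum_j z_j^2/(z_j^2+n)$
stored by the Steiger stage. Against the large continuous eGFR/BUN outcome
GWAS the forward directions have essentially complete power for even
modest effects (> 99% at an effect of 0.1); the reverse directions, limited
by the binary CP outcome's size, reach ~95% at a unit log-odds effect. The
exact instrument-$r^2$ inputs behind any published power claim are rarely
printed, so power here is always re-derived from the stated formula and
the report's own $r^2$.

## The synthetic-data generator

`simulate_pair()` instantiates exactly the working model above: true
$\beta_{Xj}$ uniform in magnitude on `beta_range` (default 0.05–0.2) with
random sign, $\alpha_j$ per the pleiotropy mode, true
$\beta_{Yj} = \theta\beta_{Xj} + \alpha_j$, standard errors from the
standardized-trait model $se = 1/\sqrt{2n\,maf(1-maf)}$ at each study's
sample size (magnitudes matching the kidney-GWAS fixtures at
$n \approx 4\times10^5$), observed betas with normal noise at those SEs,
and $p$-values from the implied $z$. Defaults (two studies of 50,000,
minor-allele frequencies 0.1–0.5) give instrument $z$-scores around 10–25:
the strong-instrument regime the estimators assume. Directional
pleiotropic effects are aligned with the sign of $\beta_{Xj}$, i.e. their
mean is defined relative to the exposure-increasing allele — the
orientation under which the Egger intercept estimates it; with arbitrary
allele coding a "directional" effect would cancel in the ratios and bias
nothing. `pleiotropy_frac` controls how many instruments carry the direct
effect (the weighted median's robustness is specifically about a minority
of invalid instruments). The generating truth is always returned (and
serialized by `write_simulated_pair()`), making every calibration test
self-checking. Replicate studies use the seed schedule
`base_seed + replicate_index`.

What the generator does **not** emulate: LD between instruments (the LD
module generates correlation matrices separately, and only for the
clumping stage), sample overlap between the two GWAS, winner's-curse
inflation of selected instruments, allele-frequency differences between
studies, population stratification, and case-control ascertainment in the
exposure GWAS. Passing calibration tests therefore demonstrates the
estimators' statistical correctness under the stated model, not robustness
to those additional real-data complications.

The test suite's calibration runs use $J = 50$ instruments, studies of
50,000, and 1000 replicates — sizes chosen so Monte-Carlo error on a
coverage proportion is ~0.7%, well inside the asserted bands (coverage
0.93–0.97, Egger intercept type-I error 0.03–0.07 at $\alpha = 0.05$).

## Numerical and design notes

- Numbers are parsed and stored at full precision; files are written with
  the fewest digits that reproduce the stored double exactly, so
  read–write round-trips are identities; 3-decimal rounding happens only
  in printed reports and serialized summary tables.
- The published instrument tables carry betas at 4 decimals. Re-deriving
  headline estimates from them can differ from full-precision results in
  the third decimal: the CP→eGFR IVW reconstructs to ~0.0024 against a
  published 0.003, and the eGFR→CP IVW to −0.3335 against −0.333. Tests
  assert agreement to one unit in the last published digit and, for
  $p$-values, qualitative agreement of the inferential conclusion.
- The record validator cross-checks $|\beta/\sigma|$ against the normal
  quantile implied by the published $p$ (10% relative tolerance, with a
  0.05 absolute floor for near-zero $z$ and an exemption where $p$
  underflows past $|z| \approx 37$); disagreement warns rather than
  errors, since published tables legitimately round. One fixture row
  (rs2976950's eGFR association) sits just outside the tolerance — a
  genuine 4-decimal rounding artifact, left visible by design.
- Degenerate inputs: a single instrument under the random-effects IVW
  falls back to fixed effects with a warning; MR-Egger refuses designs
  with no variation in $|\beta_X|$; a zero exposure beta is an error
  (undefined ratio); an all-identical-ratio set yields bootstrap SE 0,
  floored at machine epsilon.
- Directions in `run_bidirectional()` are isolated: one direction's
  failure is recorded in its report and leaves the others untouched,
  matching the symmetric bidirectional design.
- The four-direction analysis on the built-in tables retains all 7 CP, 6
  eGFR and 9 BUN instruments: the published tables are pre-filtered, so
  the blocklist, clumping and palindrome policies are exercised by
  synthetic tests rather than the fixtures. Which candidate CP variant the
  original eight-SNP suggestive set lost, and at which stage, is not
  derivable from the published tables; the blocklist stage reproduces that
  8→7 behaviour only on constructed examples.

## Limitations

Estimates inherit every limitation of the source GWAS (European-ancestry
populations, case-control CP phenotyping). Weak instruments — the CP set
sits at the suggestive threshold — bias two-sample estimates toward the
null, so null findings are not proof of no effect; the Steiger and Egger
diagnostics are themselves approximations at published-summary resolution.
The package deliberately excludes mode-based estimators, MR-PRESSO-style
outlier removal, multivariable MR and correlated-instrument IVW.
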