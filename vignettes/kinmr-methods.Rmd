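---
title: "Intergenerational IV estimation: models, simulator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intergenerational IV estimation: models, simulator design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kinmr)
```

## The estimation problem

We want the average causal effect of body mass index (BMI, kg/m²) on
all-cause mortality in a parental generation for which we observe only
survival (age at assessment or at death, reported by the offspring) — no
parental BMI, no parental genotype. Two instruments measured in the
offspring stand in for the unobservable parental exposure:

* **Offspring BMI (OAI).** Parent and offspring BMI correlate because they
  share genetic causes and a family environment. Offspring BMI is a valid
  instrument only if that shared environment (`E1`) is independent of the
  environmental causes of parental mortality (`E2`). This independence is
  untestable in real data and is precisely the assumption the simulator can
  break on demand.
* **Offspring genotype (PGMR).** Offspring alleles are transmitted from the
  parents, so an offspring risk score is a proxy for the parental score with
  a predictable attenuation of exactly one half per generation (each parent
  transmits one of two alleles per locus). Genotype is plausibly independent
  of `E2`, which is why the proxy-genotype route is robust where OAI is not.

Both estimators are IV ratios on the log hazard scale:
`log HR per kg/m² = numerator / denominator`, where the numerator is the
instrument–mortality log hazard ratio and the denominator is the
instrument–exposure slope in kg/m² per instrument unit.

### Numerators

All numerators are Cox proportional-hazards coefficients with **parental
age** as the time axis. A parent enters the risk set at their age when the
offspring was born (they must have been alive then — left truncation
prevents immortal-time bias) and exits at death or at their age when the
offspring was assessed (right censoring). Ties are handled by the Efron
approximation by default because whole-year death ages make ties certain;
Breslow is available for cross-checking. The offspring's date of birth
always enters as a linear term to absorb secular trends; genetic instruments
are additionally adjusted for principal-component columns; the "adjusted"
convention adds the behavioural/socio-economic covariates. Model fitting is
delegated to `survival::coxph()` (Newton–Raphson with step-halving); the
test suite verifies the fitted coefficients against brute-force
maximization of the explicit partial likelihood, including delayed-entry
risk-set membership, on small data.

A parent's entry age is only observable if the parent is alive at
assessment. `impute_entry_age()` fills deceased parents' entry ages with the
mean (or a chosen percentile, for sensitivity) of observed entry ages among
living parents of the same sex. Because parenthood occurs decades before
almost all deaths, risk sets are insensitive to this choice; a test verifies
that the 5th vs 95th percentile rules move the log HR by less than 0.005.

### Denominators

* **OAI**: the regression of *parental* BMI on *offspring* BMI, estimated in
  an external cohort where both are measured. Published associations usually
  run the other way (offspring on parent); `invert_iga()` reverses them by
  covariance algebra, `b · (sd_parent / sd_offspring)²`. On simulated data
  the role of the external cohort is played by an independently seeded
  auxiliary cohort, keeping the two-sample structure.
* **GRS-PGMR**: the slope of sex-specific BMI Z-scores on the GRS, times 0.5
  for the generation gap, times the BMI SD of the sex matching the parent.
* **summary-PGMR**: per SNP, the per-allele SD-unit weight times 0.5 times
  the parent-sex BMI SD (two-sample, external weights), or the same slope
  refit in-cohort (one-sample), computed efficiently by residualizing on the
  adjustment set once (Frisch–Waugh–Lovell) before the per-SNP regressions.

A weak-instrument guard refuses any denominator with |estimate|/SE below 2
(configurable, overridable) rather than silently producing an exploding
ratio; per-SNP ratios override it by design since single SNPs are
individually weak and the combiners handle that.

### Ratio standard errors and combiners

The default ratio SE is the first-order two-sample delta method
(`se² = num_se²/d² + num²·den_se²/d⁴`, zero cross-term, appropriate when
numerator and denominator come from independent samples). A numerator-only
convention is provided because the classical identity "IVW equals weighted
least squares of numerators on denominators through the origin" holds under
it; a test asserts that identity. MR-Egger is the weighted regression with a
free intercept (denominators oriented positive), its intercept estimating
directional pleiotropy; the weighted median interpolates the
inverse-variance-weighted cumulative distribution of per-SNP ratios at 0.5;
the weighted mode maximizes a weighted Gaussian-kernel density with
normal-reference bandwidth `0.9·min(sd, mad)·n^(−1/5)` scaled by a
configurable factor (as the factor grows the mode tends to the weighted
mean, another tested identity). Median and mode SEs come from a seeded
parametric bootstrap (2 000 draws by default): analytic forms exist only for
the median and are approximation-sensitive, and a seeded bootstrap keeps
determinism. Son/daughter OAI estimates are pooled by fixed-effect
inverse-variance meta-analysis with Cochran's Q, I² and a heterogeneity
p-value; DerSimonian–Laird random effects is available as a sensitivity
option. Fixed effect is the default because the pooled estimates it produces
match the corresponding published pooled values more closely under the
printed SEs.

### Diagnostics

`ph_diagnostics()` quantifies proportional-hazards violations two ways: the
correlation of the instrument's Schoenfeld residuals with log analysis time
(with its two-sided p), and an episode-split fit cutting the age axis at 70
(each parent contributing person-time to every segment it traverses). The
correlation form is reported because it is the form used in this literature;
the split fit quantifies the departure. `instrument_strength()` reports the
partial R² and partial F of the instrument beyond the adjustment covariates
from nested OLS fits. `bias_components()` compares, covariate by covariate,
the relative confounding of the two instruments: the raw component is
(covariate per instrument unit)/(exposure per instrument unit), each
covariate's OAI/GRS pair is scaled by its larger absolute member (so the
scaled pair always contains ±1), CIs come from a seeded nonparametric
bootstrap over individuals (1 000 resamples, percentile intervals), and rows
are ordered by absolute relative bias. These components are comparable
between methods within a covariate, not between covariates, and cannot
estimate the absolute magnitude of bias — only which instrument a measured
covariate loads more heavily.

## The trio simulator

No public generative model exists for this design, so the simulator adopts
the minimal structure that realizes every causal arrow — and every *absent*
arrow — of the design's assumed graph:

1. **Genotypes.** Independent biallelic loci; parental genotypes from
   Hardy–Weinberg proportions at panel frequencies; offspring dosages by
   Mendelian transmission (one allele from each parent, transmission
   probability dosage/2). Linkage disequilibrium is deliberately absent: the
   panel emulates index SNPs. Panel weights are scaled so that
   `Σ 2p(1−p)w²` equals the target variance explained exactly.
2. **Phenotypes.** Standardized BMI is linear-Gaussian:
   genetic value + `√var_e1 · E1` + covariate loadings + residual, scaled to
   sex-specific means/SDs. One scalar `E1` per family loads mother, father
   and offspring; there is **no** direct parental-BMI → offspring-BMI arrow,
   so the parent–offspring BMI correlation arises only from shared causes —
   the identifying assumption of OAI.
3. **Assortative mating.** Spouses are paired by rank-matching on the
   parent-specific BMI component with Gaussian noise. Sorting both sexes on
   noisy scores makes the scores comonotone, so the achieved component
   correlation equals the attenuation `σ²/(σ² + τ²)`; solving for `τ` gives
   the target total spousal correlation analytically, with family-shared
   components (`E1`, covariates) contributing their variance share as a
   floor. Genotypic spousal correlation emerges from the phenotypic
   matching, as in real populations; genotypes are never matched directly.
4. **Survival.** Each parent's death age is drawn from a Weibull
   proportional-hazards model, log hazard
   `γ·(BMI − sex mean) + δ·E2 + covariate terms`, *conditional on surviving
   to the entry age*, by exact inverse-transform sampling from the truncated
   distribution (cost independent of the entry age; a KS test checks the
   sampler against the analytic conditional CDF and the memoryless
   exponential special case). `E2` is drawn per parent with correlation
   `rho_e1e2` to `E1`. With `rho_e1e2 = 0` both designs are valid and every
   estimator recovers `γ`; with `rho_e1e2 > 0` and `δ > 0` the OAI numerator
   absorbs the `E1→E2→mortality` path and OAI is biased in the direction of
   `sign(δ)` while PGMR is untouched — the mechanism behind the expectation
   that OAI estimates exceed PGMR estimates when family environments carry
   mortality risk.
5. **Observation model.** The offspring's age at assessment (truncated
   normal, 40–70) censors the parent; the parent's entry age is reported
   only if the parent is alive at assessment, mirroring questionnaire data;
   `true_*` columns carry the generator's ground truth and are never read by
   estimators (the auxiliary-IGA fit reads `true_parent_bmi` only in its
   role as an *external* study in which parental BMI is genuinely measured).

### Default study conditions

Chosen once to emulate a UK-style middle-aged cohort reporting parental
longevity, and fixed:

| parameter | default | rationale |
|---|---|---|
| `gamma` | log(1.05) | a plausible harmful BMI effect, 5%/kg/m² |
| `h2_snp` | 0.02 | a ~100-SNP BMI panel explains ≈2% of variance |
| BMI mean (SD) | 26.7 (5.0) female, 27.6 (4.1) male | published descriptive values for such cohorts |
| `var_e1` | 0.15 | gives parent–offspring BMI correlations ≈0.16–0.19, matching 1958-birth-cohort associations |
| `rho_mate` | 0.2 | typical spousal BMI correlation |
| Weibull shape, scale | 9, 85 | ≈55–60% of mothers and ≈70% of fathers deceased at assessment ages |
| entry age | N(27, 4) mothers, N(30, 4) fathers | sex-specific ages at parenthood (exposed separately so either convention is testable) |
| assessment age | N(56, 8) on [40, 70] | middle-aged volunteer cohort |
| covariates | two standard normals, BMI loadings 0.15/0.15 and 0.10/0.10 (offspring/parent), hazard loadings 0.05/0.10 | measured confounders that bias unadjusted OAI but not genetic instruments |
| PCs | 10 pure-noise columns | generic ancestry-adjustment covariates |
| `rho_e1e2`, `delta_e2` | 0, 0 | valid instruments unless deliberately broken |

Covariates are kept as continuous standard normals rather than
discretized categories: the scan conventions treat ordered categories as
numeric anyway, and marginal fidelity to any particular cohort is a
non-goal. Calendar time exists only as `offspring_dob`, an adjustment
covariate; parental age is the analysis time axis.

### What the simulator does *not* emulate

Linkage disequilibrium, dynastic effects (parental genotype shaping the
offspring's environment), time-varying BMI trajectories, non-linear BMI
effects, competing risks, and reporting error in parental ages. Passing
recovery tests on this generator therefore shows that the estimators
implement their estimands correctly under the stated causal structure — not
that real-data estimates are unbiased, where these omitted features operate.

## Numerical and design choices

* **Seeds.** Every stochastic function requires an explicit seed and
  refuses to run without one; sub-streams derive deterministically from a
  master seed (`derive_seed()`), so any table is bit-reproducible and two
  pipeline runs with the same config are identical.
* **Recovery summaries.** Parameter-recovery checks pool the per-parent-sex
  estimates (fixed-effect) for OAI and GRS-PGMR — the pooled estimate is the
  design's headline quantity and halves Monte-Carlo error; the one-sample
  summary-IVW check runs on mothers to bound the per-SNP Cox cost (one fit
  per SNP). Per-SNP numerators in recovery runs use the unadjusted set:
  genotypes are independent of the measured covariates by construction, so
  adjustment costs time without removing bias.
* **Problem sizes.** Validation runs use 50 000 trios (recovery), 50
  replicates of 10 000 trios (bias separation), and 100 000 trios
  (transmission) — large enough that Monte-Carlo error is small against the
  effects tested, small enough to run on a laptop in minutes.
* **Degenerate inputs.** Zero-weight panels give a well-defined zero-signal
  path: the score is refused (undefined weighted average), denominators are
  0, and the ratio refuses rather than dividing by zero. Constant
  adjustment columns are dropped from Cox fits instead of producing singular
  model matrices. Harmonization resolves the eight allele-pair
  configurations explicitly, drops palindromic SNPs with frequency in
  0.42–0.58 (configurable) as strand-ambiguous, uses frequency concordance
  outside that window, and reports every action.
* **Egger intercept testing** uses the weighted-OLS standard errors from the
  fit (the `lm` convention); calibration under no pleiotropy is verified by
  simulation in the test suite.
* **Known limitations.** The OAI/PGMR contrast here is qualitative; the
  bias-component scale is relative by construction. The delta-method ratio
  SE ignores numerator–denominator dependence in the one-sample GRS-PGMR
  variant (the two-sample summary route exists precisely to avoid that).
  Cox non-collapsibility attenuates marginal numerators slightly relative
  to `γ` at these effect sizes (≲5% of the effect, well inside Monte-Carlo
  error at the validation sizes).
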