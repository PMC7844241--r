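---
title: "Multi-PGS analysis of psychosis-spectrum symptoms: models and design choices"
author: "pgspectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-PGS analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic cohort does and
does not emulate, and the choices made where the design was genuinely open.

## The analysis

The question the pipeline addresses is whether common-variant liability
for a battery of psychiatric and brain-related traits can classify, or is
associated with, psychosis-spectrum (PS) status in a community youth
cohort with two ancestry groups. The pipeline has five stages:

1. **Inputs.** GWAS summary statistics per trait (effect allele, log-odds
   or linear effect, standard error, p, N), target genotypes as dosages,
   and a per-subject phenotype table. GWAS are admitted when their
   LD-score heritability z exceeds 5 — strictly; a boundary z of exactly 5
   is excluded, since admission is meant to guarantee *more* than
   borderline power.
2. **Polygenic scoring** (`harmonize`, `ld_clump`, `p_threshold`,
   `pgs_score`, or `ldpred_inf`): weights aligned to the target's effect
   allele, greedily clumped on LD and thresholded on p, summed over
   dosages; or shrunk jointly under an infinitesimal model.
3. **Score correction** (`compute_pcs`, `residualize_standardize`): raw
   scores are residualized on ancestry-specific genotype PCs and
   standardized within ancestry, so each corrected score has mean 0 / SD 1
   in the group it is analysed in and zero correlation with the PCs.
4. **Multi-PGS classification** (`tune_fit`, `split_eval`,
   `repeat_and_permute`): elastic net over all corrected scores, repeated
   70/30 evaluation, permutation null, and a rank-sum comparison against
   the best single score.
5. **Univariate battery and overlap** (`fit_univariate`,
   `test_interaction`, `decile_contrast`, `sensitivity_refit`,
   `contingency`, `rank_sum`, `rank_correlation`).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| clumping `r2_max` | 0.1 | r² | conventional stringency for index-variant independence |
| clumping `window_kb` | 500 | kb | standard clumping window |
| `p_max` | 0.05 | p | single liberal threshold; strict `<` (a p exactly at the threshold is excluded), configurable |
| `radius` | 500 | variants | LD band half-width for both clumping lookups and the infinitesimal solve |
| `h2` for `ldpred_inf` | required input | liability h² | deliberately not estimated here; the shrinkage target is a modelling assumption the caller owns |
| PCs per ancestry | 10 | — | common default for within-continental-group stratification |
| elastic-net `alpha_grid` | 0, 0.1, …, 1 | mixing | full ridge-to-lasso sweep |
| CV | 10-fold, stratified | — | stratification by outcome (and ancestry) prevents class-empty folds |
| `lambda_rule` | `"cv_min"` | — | "the CV-optimal λ"; `"path_min"` (smallest λ on the path) is available because the phrase "minimal lambda" is genuinely ambiguous |
| repetitions / permutations | 1000 / 1000 | — | full-study loop sizes; every function takes smaller values, and the package's own tests run scaled down |
| covariates | age, age², sex | — | age is centred before squaring to reduce collinearity; score estimates are unchanged by this reparameterization |
| age bins | [8,12), [12,16), [16,22] | years | the bin labels overlap at 12 and 16 in common usage; half-open intervals (upper bin closed) are a convention this package fixes |

## The synthetic cohort: what it emulates

`sim_config()` defaults encode the study conditions the package is
exercised under:

* 4852 + 1802 subjects in two ancestry groups ("EA", "AA"), ages uniform
  on 8–22, sex balanced;
* allele frequencies diverging under a Balding–Nichols model with
  Fst = 0.1; 2000 variants in 40 blocks of 50 with latent AR(1)
  correlation 0.8^|i−j| within a block (zero across blocks);
* 13 GWAS traits at realistic sample sizes; only the ADHD-like trait is
  genetically correlated with the latent PS liability (rg = 0.85);
* PS prevalence 15% (EA) and 29% (AA); ADHD 5%; symptom endorsement 50%;
* an ADHD-score effect on PS of OR 1.23 per SD in EA, absent (OR 1.0) in
  AA, declining linearly with age (−0.02 per year on the log-OR scale);
* comorbid flags (ADHD, symptom endorsement, depression, mania, anxiety,
  trauma, substance use) drawn conditional on PS with log-ORs around
  ln 3–ln 4.7, substance items 57% missing; PRIME and SOPS severity scales
  sharing a latent component so they are mutually rank-correlated and
  elevated under PS.

Three generator choices deserve explanation.

**Liability noise is logistic, not Gaussian.** The binary PS outcome is a
liability threshold: genetic term + age-modulated effects + residual,
thresholded per ancestry so realized prevalence matches the target (the
threshold is solved numerically from the linear predictor distribution).
With a *logistic* residual, P(PS | score) is exactly a logistic regression
with the configured coefficient, so "OR 1.23 per SD" is a statement the
downstream logistic fit can recover without approximation. A Gaussian
residual would make the configured OR only approximately true and
age-dependent in an uncontrolled way.

**The configured OR binds the true genetic score.** `target_or_per_sd`
applies to the generator's latent standardized genetic score (emitted in
the cohort table as `g_<trait>`), which is what parameter-recovery checks
fit. The *estimated* PGS — clumped and thresholded from noisy summary
statistics — is an imperfect proxy, so its odds ratio is attenuated
(typically 1.10–1.16 under the defaults), exactly as measurement error
predicts. The acceptance script reports both.

**Age anchoring.** The age interaction enters linearly in (age − 8), but
the baseline log-OR at age 8 is back-computed so the configured OR holds
at the cohort mean age. Otherwise a nonzero default slope would silently
contradict the configured marginal OR.

What the generator does **not** emulate: real human LD maps and minor
allele frequency spectra, admixture (ancestry is a hard label),
relatedness, genotyping error and imputation uncertainty, item-level
clinical instruments (the PS flag is generated directly), and any
environment–genotype correlation. Passing tests therefore demonstrate the
statistical machinery is correct under the stated model — not that the
model captures every property of real cohort data.

## The permutation null and "mean-equivalent" AUCs

The classification significance compares the *mean* test AUC over R
repetitions with a permutation distribution. A subtlety: a single
split-evaluation per permuted outcome carries both outcome-level noise and
split-level noise, while the observed mean has averaged most split noise
away. Comparing a tight statistic with an overdispersed null is badly
conservative — in the package's own calibration experiments the naive
comparison essentially never rejected under the null.

`repeat_and_permute` therefore produces *mean-equivalent* permutation
AUCs: each permutation is evaluated over `perm_repetitions` splits and
averaged, and the permutation deviations are rescaled so their variance
matches that of a mean of R splits (the split-level variance is estimated
from the observed repetitions, which share one outcome vector). With
`perm_repetitions = 3` this test rejects at the nominal 5% rate under the
null in the package's calibration suite (200 replicates of 50 repetitions
vs 99 permutations). `perm_repetitions = 1` reproduces the common
one-fit-per-permutation practice and is the default. The empirical p is
(r+1)/(n+1) and can never be zero.

## Numerical choices

* **Clumping tie-breaks:** ties on p are broken by ascending (chromosome,
  position), making the index set independent of input row order.
* **Decile ties** go to the lower decile; deciles are recomputed within
  the analysis cohort after any exclusions.
* **Harmonization:** strand-ambiguous (A/T, C/G) pairs are dropped by
  default (policy flag to keep); every exclusion carries a reason — no
  variant is dropped silently.
* **Missing dosages** are mean-imputed per variant within ancestry group
  at scoring time.
* **`ldpred_inf`** solves the banded system exactly by sparse Cholesky
  over the whole band, which coincides with the dense whole-matrix
  solution whenever the band covers the true LD bandwidth; a singular
  system gets a 1e-6 ridge jitter, logged.
* **Perfect separation** in logistic fits is flagged; a lightly ridged
  estimate is reported with Wald inference withheld.
* **Zero cells** in 2×2 tables get the Haldane–Anscombe 0.5 correction for
  the odds ratio and Woolf CI only — never for the Fisher p; a zero margin
  leaves the OR undefined (flagged) with the Fisher p still reported. The
  reported OR is the sample cross-product OR (the quantity printed
  confusion matrices reproduce); the conditional MLE is available behind a
  flag.
* **PC sign convention:** each PC's largest-magnitude entry is made
  positive, for bitwise reproducibility across runs.
* **Seeds:** every stage derives its own seed from the master seed and the
  stage label, so re-running one stage never depends on another stage's
  draw count.

## Problem sizes in the test suite

The full study procedure (1000 repetitions, 1000 permutations, 1.9M
variants) is not desk-scale. The package's tests exercise the same code
paths at sizes chosen to keep the whole suite in the tens of minutes:
2000–5000 variants for Fst/LD recovery, cohorts of 150–5000 subjects for
calibration loops, 50 repetitions vs 99 permutations (×200 replicates) for
the permutation-calibration check, and 100 seeds for the
causal-score-selection check. These sizes are the package's own choices;
the statistical properties tested (calibration, unbiasedness, oracle
equivalence) are size-free claims checked at accessible sizes.

## Known limitations

The elastic-net AUCs under the defaults are modest (≈0.52–0.55), as
expected when a single trait carries OR ≈ 1.2 per SD; conclusions from the
classifier layer are therefore about *relative* structure (which score is
selected, which cohort carries signal), not absolute discrimination. The
univariate battery's power depends on the attenuation of the estimated
PGS, which in turn depends on GWAS sample size, causal fraction and the
2000-variant genome; absolute p-values in the demo workflow should be read
with that in mind. Cross-ancestry portability of scores is deliberately
not modelled beyond "no effect in the second ancestry".
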