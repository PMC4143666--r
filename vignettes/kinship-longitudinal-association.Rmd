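---
title: "Kinship-structured association methods for longitudinal family traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship-structured association methods for longitudinal family traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Family cohorts that measure a quantitative trait — blood pressure is the
motivating case — at several exams carry two kinds of structure that a
genome-wide association scan must respect: relatives share polygenic
background, so residuals are correlated within pedigrees; and repeated
measures on the same person are correlated across visits. `kinlong`
implements four strategies for testing a SNP dosage against such a trait,
all built on the same kinship-structured linear mixed model, together with
the preprocessing, simulation, and evaluation machinery needed to compare
them end to end.

The four methods, per SNP $s$ with dosage $\mathrm{SNP}_{ij} \in [0,2]$ for
individual $j$ in pedigree $i$:

* **baseline** — only each person's first exam is analyzed:
  $Y_{ij0} = \beta_0 + X_{ij0}\beta + \beta_s \mathrm{SNP}_{ij} + \alpha_{ij} + \varepsilon_{ij}$,
  with $\alpha_i \sim N(0, \sigma^2 \Sigma_{kin})$ block-diagonal by
  pedigree and i.i.d. residuals. Fitted by ML.
* **lme** — the longitudinal mixed-effects model uses every person-visit
  row $Y_{ijt}$ with time-varying covariates $X_{ijt}$ and the same single
  kinship-structured person intercept. Fitted by REML.
* **mean** — the trait and the time-varying covariates are averaged over
  each person's visits ($Y_{ij*}$, $X_{ij*}$) and the person-level model is
  fitted by ML.
* **twostage** — stage 1 fits the longitudinal model once *without* any
  SNP and extracts each person's predicted random intercept
  $\hat\alpha_{ij}$ (a BLUP); stage 2 regresses
  $\hat\alpha_{ij} = \beta_{20} + \beta_s \mathrm{SNP}_{ij} + \gamma_{ij} + \varepsilon_{ij}$
  per SNP, where $\gamma$ again carries the kinship covariance
  $\sigma_\gamma^2 \Sigma_{kin}$. Stage 2 deliberately has no covariates
  beyond the SNP: the BLUPs are already adjusted for the stage-1 fixed
  effects. Because stage 1 is SNP-independent, this is the cheapest exact
  per-SNP method.

Inference on $\beta_s$ is a two-sided Wald $z$ test (equivalently a 1-df
chi-square). No small-sample $t$ correction is applied; the intended use is
samples of hundreds of individuals, where the normal reference is standard
practice.

## Kinship

`kinship_matrix()` computes pairwise kinship by the classical recursion in
parents-before-children order ($\phi_{jj} = \tfrac12(1+\phi_{fm})$,
$\phi_{jk} = \tfrac12(\phi_{kf} + \phi_{km})$), with Kahn's algorithm
providing the topological order (ties broken by input row order, so results
are deterministic). Individuals in different pedigrees are unrelated, so the
matrix is block-diagonal and every model in the package exploits the blocks.

The covariance scale is a genuine free choice: the same model can be written
with $\Sigma_{kin}$ holding kinship coefficients $\phi$ or the numerator
relationships $2\phi$. We default to the numerator scale (diagonal 1 for
non-inbred individuals) so that `var_kin` reads directly as additive genetic
variance; the alternative only rescales the variance component, and both are
exposed via `scale = "phi"` / `"numerator"`.

Correctness is established against an independent Monte-Carlo oracle:
`gene_drop_ibd()` drops uniquely labelled founder alleles through the
pedigree and estimates each pair's identity-by-descent probability
empirically. The test suite requires agreement within three Monte-Carlo
standard errors on a 20-member three-generation pedigree containing a
full-sib mating (self-kinship $0.625$) and a double-first-cousin mating.

## The mixed-model engine

All four methods reduce to one computation: maximize the (restricted)
likelihood of $y \sim N(X\beta,\; \sigma^2 Z \Sigma_{kin} Z^\top + \sigma_\varepsilon^2 I)$
over $(\beta, \sigma^2, \sigma_\varepsilon^2)$, where $Z$ maps
observation rows to individuals. `fit_lmm()` profiles the problem to one
dimension: each pedigree block of $Z \Sigma_{kin} Z^\top$ is eigendecomposed
once, the model is rotated into the eigenbasis (where the covariance is
diagonal in the variance ratio $\delta = \sigma^2/\sigma_\varepsilon^2$),
and $\beta$ and the residual scale are solved in closed form at any
$\delta$. The optimum over $\delta$ is found on a 64-point $\log_{10}$ grid
spanning $[10^{-6}, 10^6]$ and refined by Brent's method (tolerance $10^{-8}$
on $\log_{10}\delta$); $\delta = 0$ always competes as an explicit boundary
candidate, and grid-edge optima are flagged `boundary`. Each likelihood
evaluation costs $O(n)$ after the one-off decomposition.

Numerical conventions worth stating:

* Standard errors come from the inverse expected information of the GLS
  step at the variance optimum; uncertainty in the variance components is
  not propagated (standard practice for association scans).
* Rows with missing modelled values are dropped with a message.
* A singular fixed-effect design is an error; a zero-residual fit (e.g.
  noiseless synthetic data) is returned with both components at the
  boundary rather than erroring.
* BLUPs are
  $\hat\alpha = \hat\sigma^2 \Sigma_{kin} Z^\top \hat V^{-1}(y - X\hat\beta)$,
  evaluated per block in the rotated basis. They match the dense-matrix
  formula to $10^{-8}$ in the tests, and the profiled likelihood matches a
  dense-covariance brute-force maximization to $10^{-4}$ on fifty random
  small instances.

### Exact and fast scan modes

The default scan (`mode = "exact"`) re-estimates the variance components
for every SNP, mirroring per-SNP model fits. For large null calibrations the
package also offers `mode = "fast"`: the variance components are frozen at
the no-SNP null fit and each SNP is score-tested against the implied
covariance, fully vectorized across SNPs (the reported effect and SE are the
one-step score/information estimates). The two modes agree closely in effect
estimates and p-value ranking; score and Wald p-values can drift apart in
the extreme tail at small sample sizes, which is inherent to the two test
forms rather than an approximation error, so fast mode is recommended for
calibration studies and exact mode for top-hit reporting.

## Trait preprocessing

`impute_medicated()` implements the medication-aware blood-pressure rule:
a treated person-visit with observed value $v$ is replaced by the mean of
all *other* subjects' pre-imputation observations of the same sex, within a
closed $\pm 10$-year age window, whose values strictly exceed $v$. Three
interpretation choices were genuinely open and are fixed as follows: "higher
values" compares against the subject's own observed on-treatment value at
that exam (the only reading that defines a per-exam rule); pools are drawn
from pre-imputation values of all subjects, medicated or not, so the result
does not depend on processing order and the rule is idempotent; an empty
pool retains the observed value with a warning rather than extrapolating.
The rule can only increase a value, and an audit table (pool sizes, old and
new values) is attached to the result.

`build_covariates()` encodes the two covariate sets used for
blood-pressure-like traits: age, sex and smoking for systolic-like traits,
plus centered age squared for diastolic-like traits. The centering mean is
computed over the rows of the analysis table actually in use (baseline
table for the baseline method, averaged table for the mean method), so each
method's design is self-contained. `screen_covariates()` reproduces the
one-at-a-time preliminary screen: each candidate is the sole fixed effect
in the kinship model and is retained at Wald $p < 0.05$.

## The synthetic cohort

`simulate_longitudinal()` generates data with exactly the structure the
four methods assume:

$$y_{ijt} = \beta_0 + \beta_{age}\,age_{ijt} + \beta_{sex}\,male_{ij} +
\beta_{smoke}\,smoke_{ijt} + \beta_s\,\mathrm{SNP}_{ij} + g_{ij} + a_{ij} + e_{ijt}$$

with $g \sim N(0, \sigma_g^2 \Sigma_{kin})$ (polygenic),
$a \sim N(0, \sigma_a^2)$ i.i.d. per person, and
$e \sim N(0, \sigma_e^2)$ i.i.d. per visit. Genotypes come from
`gene_drop()`: founders draw two Bernoulli(MAF) alleles and children inherit
one uniformly random allele from each parent, so Mendelian consistency and
the $2\phi$ additive correlation between relatives hold by construction —
the same machinery doubles as the kinship oracle.

Defaults encode the study conditions the package is designed around, and
they are deliberately not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `var_polygenic` | 0.5 | kinship-structured variance $\sigma_g^2$ |
| `var_person` | 0.5 | i.i.d. person-level variance $\sigma_a^2$ |
| `var_occasion` | 2.0 | per-visit noise $\sigma_e^2$ |
| `n_visits` | 4 | exams per person |
| `visit_gap_years` | 5 | median inter-exam gap emulated |
| `mafs` | U(0.05, 0.5) | common variants only |
| `dropout` | 0 | optional MCAR loss to baseline-only follow-up |

Pedigree templates are `sibship`/`nuclear` (two founder parents plus $k$
full siblings) and `three_generation` (12 members across three
generations). Baseline ages decrease by generation so that founders are
older, and smoking is a persistent but time-varying 0/1 covariate.
Medication masking, when enabled, subtracts a fixed treatment effect from
visits whose latent trait exceeds a threshold — a deliberately minimal
treatment model whose purpose is to exercise the imputation rule, not to
mimic any particular drug.

What the generator does *not* emulate: linkage disequilibrium beyond an
optional correlated-partner mode (used to exercise LD pruning), rare
variants, ascertainment of pedigrees, age-dependent genetic effects, and
informative dropout. Passing tests therefore demonstrate correctness of the
methods under their own assumptions, not robustness to the many ways real
cohort data violate them.

## Evaluation machinery

* `maf_filter()` keeps SNPs with estimated MAF $\ge 5\%$ (inclusive).
* `ld_prune()` greedily scans SNPs in position order and keeps a SNP iff
  its squared dosage correlation with every previously kept SNP among the
  trailing 50 position-ordered SNPs is below 0.2. Threshold and window are
  configurable; the window convention is our choice (the count an external
  pruning tool would use is not recoverable from a threshold alone), so
  kept-SNP *counts* depend on it while the no-correlated-pair guarantee
  does not.
* `bonferroni_threshold(25676)` gives the $1.947\times10^{-6}$ threshold
  used throughout the power machinery.
* `genomic_lambda()` is the median-based genomic-control estimator
  $\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$.
* `estimate_power()` reports, per method, the proportion of replicates with
  the causal SNP below threshold, with Wilson 95% intervals (chosen over
  Wald for small-count coverage).

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from code;
the sizes below were chosen as the smallest that leave the Monte-Carlo
noise clearly inside each tolerance. Kinship vs gene-dropping uses $10^5$
drops on the 20-member inbred pedigree. The engine-vs-oracle comparison
uses 50 random instances of at most 12 observations. Parameter recovery
uses 200 replicates of 125 sibship-quad pedigrees (750 individuals, 4
visits): under 4-visit averaging the person-level model is exactly
specified with components $(\sigma_g^2,\; \sigma_a^2 + \sigma_e^2/4) =
(0.5, 1.0)$, which is the truth mapping the recovery test checks, along
with the causal effect $\beta_s = 0.38$ at MAF 0.3. Null calibration runs
all four methods in fast mode over 20,000 gene-dropped SNPs; power
comparisons run 100 (tests) or 200 (acceptance script) replicates of 200
sibship-quad pedigrees with 800 phenotyped offspring, exact mode.

## Known limitations

* One kinship-structured random intercept plus i.i.d. residual is the only
  covariance family fitted (no random slopes, no separate household or
  i.i.d. person component alongside the kinship term). Under the
  three-component generator the observation-level LME is therefore
  deliberately misspecified; empirically its SNP tests remain calibrated
  (the SNP design is person-constant), but its variance components should
  not be interpreted as estimates of $\sigma_g^2$ or $\sigma_e^2$.
* Wald/score inference is asymptotic; very small samples or very rare
  dosages are outside the intended regime.
* Across-pedigree relatedness is assumed absent (block-diagonal
  $\Sigma_{kin}$); cryptic relatedness between families is not modelled.
* X-linked kinship and identity-state coefficients beyond pairwise kinship
  are out of scope.
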