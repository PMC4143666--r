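# kinlong

Family-based association testing for quantitative traits measured
repeatedly over time.

Genome-wide association studies in family cohorts face two correlations at
once: relatives share polygenic background within pedigrees, and repeated
exams of the same person are correlated across visits. Most scans sidestep
the second by analyzing a single baseline measurement. `kinlong` implements
and compares four kinship-structured linear mixed-model strategies for a
quantitative trait (blood pressure is the motivating example):

* **baseline** — each person's first exam only:
  `Y_ij0 = β0 + X_ij0 β + βs·SNP_ij + α_ij + ε_ij`, with the person
  random intercepts `α_i ~ N(0, σ² Σ_kin)` block-diagonal by pedigree (ML);
* **lme** — the longitudinal mixed-effects model on all person-visit rows
  with time-varying covariates and the same kinship random intercept (REML);
* **mean** — the person-level model on the trait (and time-varying
  covariates) averaged over visits (ML);
* **twostage** — a growth-curve model is fitted once without any SNP, each
  person's predicted random intercept (BLUP) becomes the new trait, and the
  BLUPs are regressed per SNP with their own kinship random effect (ML).

Around the four runners the package provides the full pipeline: PLINK
FAM/PED pedigree parsing and recursive kinship computation (validated
against Monte-Carlo gene-dropping), VCF(DS)/TSV dosage I/O,
medication-aware blood-pressure imputation, covariate construction and
screening, a synthetic-cohort generator (pedigree templates, gene-dropped
genotypes, three-component longitudinal phenotypes, medication masking),
and evaluation tools: MAF filtering, greedy LD pruning, Bonferroni
thresholds, genomic-control lambda, replicate-based power with Wilson
intervals, top-hit tables and Manhattan/QQ plots.

It is intended for statistical geneticists and methods students who want a
self-contained, testable implementation of these designs — every analysis
in the package runs on simulated pedigrees with no external data.

## A worked example

Simulate 50 sibship-quad pedigrees (300 individuals), 4 visits each, 200
common SNPs with one causal variant (`βs = 0.6` on the first SNP), then run
all four methods:

```r
library(kinlong)
library(dplyr)

cfg <- sim_config(n_pedigrees = 50, pedigree_template = "sibship",
                  template_size = 4, beta_snp = 0.6, n_snps = 200, seed = 42)
ped <- build_pedigrees(cfg)
K   <- kinship_matrix(ped)
set.seed(cfg$seed)
geno   <- sim_genotypes(ped, runif(cfg$n_snps, 0.05, 0.5))
causal <- setNames(unclass(geno)[, 1], rownames(geno))
sim    <- simulate_longitudinal(ped, cfg, causal = causal, K = K)

res <- run_all(sim$pheno, geno, K, trait_kind = "sbp_like")
top_hits(res, k = 1) |> select(method, snp_id, effect, se, p)
#> # A tibble: 4 × 5
#>   method   snp_id    effect     se          p
#>   <chr>    <chr>      <dbl>  <dbl>      <dbl>
#> 1 baseline 3_1405000  0.835 0.227  0.000233
#> 2 lme      3_1000000  0.516 0.117  0.0000101
#> 3 mean     3_1000000  0.515 0.111  0.00000344
#> 4 twostage 3_1000000  0.322 0.0714 0.00000647
```

The three longitudinal methods all rank the causal SNP (`3_1000000`) first
with p-values around 20-70x smaller than anything the baseline method
finds; the baseline scan, using a quarter of the measurements, tops out on
a non-causal SNP. The two-stage effect (0.32) is attenuated relative to the
lme/mean estimates (~0.52) — BLUP shrinkage deflates the effect scale — but
its p-value ranking tracks the other longitudinal methods closely, which is
exactly the behaviour that makes it a cheap substitute for the full
longitudinal fit.

Fitting one model directly and inspecting it broom-style:

```r
fit <- fit_lmm(mean_over_visits(sim$pheno), trait ~ age + sex + smoke, K)
glance(fit)
#>   logLik criterion var_kin var_resid  nobs n_individuals converged boundary
#>    -483. ML          0.736     0.873   300           300 TRUE      FALSE
tidy(fit)
#>   term        estimate std.error statistic   p.value
#> 1 (Intercept)  121.      0.336       358.  0
#> 2 age            0.401   0.00472      85.0 0
#> 3 sex            2.88    0.134        21.5 1.58e-102
#> 4 smoke          2.06    0.185        11.1 8.75e- 29
```

(The generating fixed effects were age 0.4, sex 3, smoke 2 on an intercept
of 120.) `plot_manhattan(res)` and `plot_qq(res)` produce the usual scan
figures, and `autoplot(fit)` shows the BLUP distribution.

A thin command-line wrapper over the same functions ships in
`inst/scripts/run_assoc.R` for file-based runs (FAM + phenotype TSV +
VCF/TSV dosages in, results TSV out).

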