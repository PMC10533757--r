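---
title: "Evaluating recurrent genomic selection with multi-location sparse testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating recurrent genomic selection with multi-location sparse testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgsel)
```

## The problem

Recurrent selection improves a crop population through repeated cycles of
evaluation, selection and intercrossing. When the population is a selfing
crop (here the motivating system is an upland rice synthetic population),
each cycle produces S~0~ plants whose descendants are advanced by bulk
selfing — a family after *t* selfing steps is written S~0:t~, and its
expected heterozygosity is the S~0~ value times $(1/2)^t$, so S~0:4~
families are already ~93.75% homozygous. Phenotyping happens in
multi-location trials: a convenient, well-watered *surrogate* location
(labelled PAL) where generations can also be advanced off-season, and the
rainfed *target* location (SRO) where selection decisions matter.

Genomic selection promises to shorten this cycle: genotype every S~0~
plant once, phenotype only part of the material, and predict genomic
estimated breeding values (GEBVs) for the rest. The open design questions
are where, when and on whom to spend the phenotyping budget: which
generation to phenotype, whether to pool the two locations with a
genotype-by-environment (G×E) model, whether a sparse fraction of the
target-location trial suffices, and whether choosing that fraction by an
optimality criterion (CDmean) beats choosing it at random. `rgsel`
implements the full evaluation machinery for these questions and a
synthetic-data generator so every stage is testable without any external
download.

## The models

### Stage 1 — plot-level mixed models

Plot observations from paired location trials are decomposed with the
linear mixed model

$$y_{ijkl} = \mu + Loc_i + Rep_j(Loc_i) + Bl_k(Rep_j(Loc_i)) + g_l +
g_l(Loc_i) + e_{ijkl},$$

with location and replicate-within-location fixed, and blocks, genotype
(family) and genotype-within-location random. `fit_variance_model()` fits
it by REML through lme4. Broad-sense heritability on an entry-mean basis
is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g(Loc)}/NE +
\sigma^2_e/NR},$$

where `NE` and `NR` are harmonic means of the numbers of locations and of
replicate plots per family (`harmonic_means()`); within-location
estimates drop the G×E term and use `NR` = replicates in that trial.
Genomic prediction is two-stage: `fit_blues()` first adjusts each trial
separately (genotype and replicate fixed, blocks random), and the
resulting BLUEs are the responses for stage 2.

### Stage 2 — Bayesian GBLUP with G×E kernels

Records are (family, location) pairs. With $G$ the VanRaden genomic
relationship matrix (`vanraden_g()`:
$G = ZZ^\top / 2\sum_k p_k(1-p_k)$ on column-centered dosages),
`build_kernels()` realizes four covariance structures:

* **SM** — single-environment GBLUP, main genetic effect only;
* **MM** — multi-environment, one main effect shared across locations
  (no G×E);
* **MDs** — MM plus one G×E deviation with a single variance, whose
  kernel is $G$ within a location and 0 across locations;
* **MDe** — location-specific deviation variances, one within-location
  kernel per location.

`fit_gibbs()` samples the model $y = X\beta + \sum_k u_k + e$,
$u_k \sim N(0, \sigma^2_k K_k)$, by Gibbs sampling in each kernel's
eigenbasis, where the full conditional of the transformed effects is
diagonal and therefore cheap. Variances take scaled-inverse-chi-square
conjugate updates; fixed effects (intercept + location) have flat
priors; records with missing phenotypes are re-imputed from the model
each iteration, which is exactly prediction through the joint kernel
covariance. With variances fixed at a ratio $\lambda$ the posterior mean
equals the Henderson mixed-model solution, and `gblup_closed_form()`
provides that deterministic oracle — the test suite holds the sampler to
within 2% of the response SD of it.

Predictive ability (PA) is the Pearson correlation between GEBVs and the
validation families' trial BLUEs. Scenario comparisons Fisher-Z transform
the replicate PAs, fit a one-way fixed-effect linear model, and report
Tukey-HSD compact letters (`compare_scenarios()`).

### Training-set optimization

`cdmean()` scores a candidate training set by the mean coefficient of
determination of the contrasts between each validation individual and the
population mean,
$CD(c_i) = c_i^\top (G - \lambda C^{22}) c_i / c_i^\top G c_i$, with
$C^{22}$ the random-effect block of the inverse mixed-model coefficient
matrix for the proposed set and $\lambda = (1-h^2)/h^2$ (default 1, i.e.
$h^2 = 0.5$). `ga_select()` maximizes it with a genetic algorithm
(fixed-size set encoding, tournament selection of size 3, uniform
crossover with repair, single-member swap mutation at rate 0.1, elitism;
defaults 200 iterations × population 300 × 10 elites). On problems small
enough to enumerate, the GA recovers the exhaustive optimum.

### Scenarios and costs

`build_scenario()` encodes five calibration designs for predicting the
validation sub-population B (S~0:4~, SRO): within-population
cross-validation (Uni1, 70/30), cross-population calibration from
sub-population A at generation 2 or 3 (Uni2/Uni3, deterministic),
two-location calibration at one generation (Multi1), and the
multi-generation sparse-testing design (Multi2: 100% of A's PAL records
at S~0:2~ plus a 25/50/75% fraction of A's SRO records at S~0:3~, drawn
at random or by CDmean). `run_scenario()` replicates the stochastic
designs, re-drawing training sets per replicate while asserting that
validation records never carry observed phenotypes. `scenario_ledger()`
accounts each design's cost in location-specific phenotyping units
(generation advance = 0.4 PAL units; a full phenotype evaluation = 1
unit of its location) and semester calendar, with totals kept as exact
integer hundredths.

## The synthetic-data generator

`sim_config()` + `simulate_study()` emulate the motivating study design:

* 384 + 334 S~0~ plants as two random fractions of one unstructured
  founder pool; allele frequencies Beta(0.7, 0.7) truncated to
  MAF ≥ 2.5%, genotypes as unions of two binomial gametes. This keeps
  rare alleles in the spectrum and mean S~0~ heterozygosity above 0.2.
* ~10k SNPs at full scale (desk-scale default 2000) spread over 12
  chromosomes with sorted positions.
* Bulk selfing tracked as expected genotype frequencies per family
  (infinite-bulk approximation: with 15–20 bulked plants per generation,
  family-level drift is negligible); heterozygosity halves per step.
* Six trials — sub-population A at generations 2 and 3, B at generation
  4, each in both locations — each a lattice of 8 blocks × 3 replicates
  with 50 temporal-check families fixed at generation 2 in every trial.
  The check set is taken inside sub-population A (384 = 334 + 50), so
  every trial carries 384 entries × 3 replicates = 1152 plots at full
  scale.
* Trait architecture: main marker effects plus per-location deviations
  on centered dosages, rescaled and orthogonalized in-sample so that the
  realized partition is exact: genetic variance $1-s$ shared across
  locations and $s$ location-specific (`gxe_share` = $s$; the
  between-location genetic correlation is $1-s$), residual variance
  solving the target entry-mean $H^2$. Default trait settings
  (FL 0.51/0.59, PH 0.30/0.70, YLD 0.24/0.70, ZN 0.51/0.57; block
  variance 0.10) land in the published bands: $H^2$ 0.2–0.87, G×E around
  a third of total variance, between-location phenotypic correlations of
  family means near 0.2–0.35 for the moderately interactive traits.
* Year effects are zero by default (in the real design year is
  confounded with generation; the temporal checks exist to measure it),
  switchable through `year_effects` for check-based experiments.

What the generator does *not* emulate: linkage disequilibrium between
loci (loci are independent, so LD-based summaries on simulated data
reflect the null), male-sterility-gene segregation, selection or
mutation during advance, and spatial field trends beyond the block
effect. Passing tests on synthetic data therefore validate the
machinery — estimators, samplers, optimizers, bookkeeping — not any
claim about a particular real dataset.

## Numerical choices

* **REML** by lme4 with singular fits permitted (variances may land on
  the 0 boundary); on fully balanced designs the estimates agree with
  the ANOVA method-of-moments closed form to optimizer precision
  (~1e-5 relative), which the suite asserts.
* **G stabilization**: a ridge of `1e-6 * mean(diag(G))` keeps G
  positive definite for the sampler's eigendecompositions and the
  CDmean inverse; kernel eigenvalues below 1e-8 are dropped.
* **Gibbs priors**: scaled-inverse-chi-square with 5 degrees of freedom
  and scale chosen so each of the (kernels + residual) components has
  prior mean `var(y)/(K+1)` — proper but weakly informative. The
  published chain settings (burn-in 2000, 70000 iterations, thin 100)
  are available as `mcmc_settings(preset = "paper")`; the desk preset
  (500/5000/5) is the default for replicated cross-validation.
* **CDmean** uses the Schur complement of the fixed-effect block rather
  than inverting the full coefficient matrix, and caches $G^{-1}$ in the
  problem object; the loop-wise full-inverse construction is kept in the
  tests as the oracle.
* **Outlier fences** use Tukey hinges (`fivenum`), mirroring boxplot
  semantics; quartile conventions differ across software, so the choice
  is pinned and flags are informational only.
* **Seeds**: one master seed derives named per-module streams
  (`derive_seed()`); scenario replicate *r* uses `seed + 7919 r`. All
  results are bit-reproducible given a config.
* **Cost ledgers** store integer hundredths of a phenotyping unit;
  totals are exact sums per currency. One published scenario total
  (Uni2) differs from the sum of its own printed entries by 0.05 — the
  ledger keeps the entries and reports their exact sum (0.85 PAL
  units).

## Design decisions on open points

* Table-style between-location correlations are computed on family
  means (the plot-versus-mean choice is not standardized in trial
  reporting); `descriptive_stats()` documents this.
* Marker centering uses observed allele frequencies, the common GBLUP
  practice when founder frequencies are unavailable.
* Beagle-style genotype imputation is replaced by per-SNP mean
  imputation: G is insensitive to the difference below 20% missingness,
  and the package stays free of external binaries.
* In the sparse-testing scenario the CDmean problem treats the
  PAL-phenotyped families as fixed training members (environment
  collapsed to a single record each) and optimizes only which SRO
  records to add; a flag-free alternative (optimizing on the SRO kernel
  alone) amounts to passing an empty `fixed_ts_ids`.
* In Multi1, validation families' surrogate-location records stay in the
  training set — it is their target-location records that are held out.
* Uni2/Uni3 are deterministic (the training set is the whole
  sub-population), so they enter comparisons as reference values, not as
  replicate groups.

## Problem sizes and what the tests assert

The shipped tests run the whole pipeline at reduced scale — populations
of 30–120 families, 200–400 SNPs, light MCMC chains — sizes chosen so the
full suite completes in well under a minute while every statistical
assertion still has power: sampler-vs-closed-form agreement within 2% of
the response SD at 100 individuals and 20000 iterations, REML recovery of
simulated variance components within 15% averaged over 20 study
replicates at 334 families × 2 locations × 3 replicates, CDmean equal to
exhaustive enumeration to 1e-10 on 8-choose-3, and the GA finding the
exhaustive optimum in ≥95% of seeded runs.

## Known limitations

* A null-heritability trait shows a small negative mean PA at small
  population sizes: block effects are estimated jointly within a trial,
  so the BLUE errors of training and validation families are weakly
  (negatively) correlated. The effect vanishes when the block variance
  is zero and shrinks with population size; null calibration is
  therefore asserted across independent simulated studies, not across
  splits of one study.
* Replicate PAs within one simulated study share its single noise
  realization and are strongly correlated; standard errors across
  replicates understate uncertainty across datasets.
* The MDe sampler estimates one deviation variance per location from
  within-location information only; with few records per location its
  posterior is prior-sensitive.
* No marker-effect (Bayes-alphabet) parameterizations, no reaction-norm
  or environmental-covariate models, no pedigree A matrix, and no
  spatial row-column adjustment — all outside the package's scope.
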