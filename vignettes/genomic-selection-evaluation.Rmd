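---
title: "Evaluating genomic selection accuracy in a recurrent-selection synthetic population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genomic selection accuracy in a recurrent-selection synthetic population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Recurrent selection (RS) maintains a broad-based synthetic population by
cycles of evaluation, mild selection and inter-crossing. Genomic selection
(GS) promises to accelerate such programmes: a whole-genome regression trained
on phenotyped and genotyped lines predicts genomic estimated breeding values
(GEBV) for selection candidates that are only genotyped. Whether that works
depends on properties of the population — linkage disequilibrium (LD) between
markers and causal loci, the allele-frequency spectrum, effective population
size, subpopulation structure — and on analysis choices: which markers enter
the incidence matrix, how large the training set is, which regression model is
used, and how heritable the trait is.

`gsrice` implements the full evaluation loop for an upland-rice-like setting:
a forward-in-time simulator of a multi-subpopulation synthetic of S2 lines, the
population-genetic characterization used to describe such panels, marker-set
construction, the alpha-lattice mixed-model analysis that produces the
phenotypic BLUPs, five whole-genome regression methods, and a replicated
cross-validation factorial whose accuracies are analysed by a Fisher-z ANOVA
with adjusted means.

## The simulated population

The simulator (`sim_config()`, `simulate_population()`) models the breeding
history as four phases:

1. **Founders.** `n_founders` fully inbred accessions; each locus's allele
   frequency is drawn from a symmetric `Beta(0.56, 0.56)` law and founder
   alleles are sampled independently per locus at those frequencies. The
   U-shaped beta law is taken from the observed spectrum of the real panel and
   is treated as a calibration target rather than a mechanistic claim.
2. **Base recombination cycles.** A panmictic census of `base_size = 100`
   plants is founded from the accessions and random-mated for
   `n_cycles = 10` generations. Gametes receive `Poisson(length_cM/100)`
   crossovers placed uniformly on the genetic map, without interference.
   Founders enter with geometrically decaying contributions
   (`founder_weight_decay = 0.775`): a handful of elite lines dominate the
   crossing scheme, which is both the documented history of such programmes
   and the only mechanism in this model class that produces the panel's
   combination of high short-range LD and a long low-MAF tail (see
   *Calibration* below).
3. **Subpopulation split.** Four subpopulations (86/83/82/92 lines) drift for
   three further generations at parent censuses of 32/28/48/53 with a
   per-parent migration probability of 0.08, yielding low but nonzero
   differentiation.
4. **Single seed descent.** Each extracted S0 line is selfed twice
   (`advance_ssd()`), halving heterozygosity per generation, to give the S2
   panel that is genotyped and phenotyped.

The genome is 12 chromosomes of 150 cM (18 Morgans in total) and ~31.1 Mb,
carrying 695 loci each (8,340 SNPs, one per ~45 kb on average); physical
positions are uniform random so marker spacing is irregular, and the genetic
map is linear in physical position.

### Traits and the field trial

Traits are strictly additive: `build_trait()` sums sampled QTL effects over
dosages and centers the result. The default set (`default_traits()`) spans the
heritability range of the motivating study — an oligogenic trait with one
major locus at h² = 0.86 and three polygenic traits at h² = 0.58, 0.29 and
0.10. `simulate_field_trial()` plants every line once per replicate of an
alpha-lattice (2 replicates × 21 blocks × 17 plots), with fixed sum-to-zero
replicate effects, normal block effects (default variance one quarter of the
genetic variance) and a residual variance chosen as
`s2_e = s2_g (1 − h²)/h²`, capped at `1e6 · s2_g` as h² approaches 0, so that
the plot-basis heritability `s2_g/(s2_g + s2_e)` — the definition used by the
estimation module — equals the target. (A variant with an extra factor for the
number of replicates would target an entry-mean heritability instead; we chose
the plot-basis form so the simulator and the estimator are mutually
consistent and parameter-recovery tests are meaningful.)

### Calibration

The defaults were calibrated once, before the test suite was frozen, against
the published description of the real panel: mean minor allele frequency
(MAF) ≈ 15%, median ≈ 10%; mean r² ≈ 0.59 for marker pairs within 25 kb,
halving at 500–650 kb; pairwise Weir–Cockerham F_ST between 0.025 and 0.058.
Replicate means under the frozen defaults are MAF 15–17%, r²(0–25 kb)
0.55–0.65 with half-decay near 650 kb, and all pairwise F_ST ≤ 0.06.

Two published statistics are knowingly *not* matched, because they are
incompatible with the bands above inside this model class:

* **Residual heterozygosity.** The panel's median per-line heterozygosity is
  4.7%; the simulator gives ≈ 2%. Raising it requires more haplotype
  diversity, which destroys the short-range LD band. Genotyping and
  imputation noise, which inflates the real figure, is not modelled.
* **LD-based Ne of the S2 panel.** The published estimates are 28–53 per
  subpopulation. On nearly inbred lines the composite (dosage-correlation)
  r² between unlinked loci is diluted roughly threefold relative to the
  underlying gametic disequilibrium, so the estimator applied to our S2 panel
  returns values several-fold above the split-phase parent censuses. The
  estimator itself is validated against outbred Wright–Fisher simulations
  with known Ne (recovery within a factor of two for Ne 25–100), which is the
  property the method is used for.

What passing the calibration suite shows — and does not show — about real
data: the simulator reproduces the first- and second-order genetic structure
(frequency spectrum, LD decay, differentiation) that drives genomic
prediction accuracy, but not genotyping error, missing-data imputation,
selection during the cycles (the real programme applied mild selection),
dominance/epistasis, or mutation.

## Population characterization

`allele_stats()` reports p, MAF, observed heterozygosity and
`He = 2p(1−p)/4`, the expected heterozygote fraction after the two selfing
generations. `pairwise_ld()` computes within-chromosome r² as the squared
Pearson correlation of dosages — a composite measure that approximates
haplotype r² closely for near-inbred lines — and `ld_decay_profile()` bins it
by physical distance and reports the half-decay distance.
`fst_pairwise()` implements the Weir–Cockerham theta with ratio-of-sums
combination over loci; negative multilocus estimates are reported as-is
unless truncation is requested. `estimate_ne_ld()` uses only
inter-chromosomal pairs (physical linkage cannot contribute), applies the
sample-size correction `1/S + 3.19/S²` for S ≥ 30, and inverts
`E[r²'] = 1/(3Ne)` via the standard quadratic; non-positive corrected r² is
flagged as an infinite estimate. `kinship()` is the mismatch-distance
similarity `s = 2(1 − d)`; the published description ("subtract from 2, scale
0–2") is read as this affine map because a min–max rescaling would make the
matrix depend on the sample composition.

## Marker selection

`build_incidence_matrix()` composes an inclusive MAF filter
(`filter_by_maf()`) with greedy per-chromosome LD pruning
(`prune_by_ld()`): sweeping in map order, a marker is kept iff its r² with
every already-kept marker on the chromosome is at most the threshold. The
sweep is deterministic (first-seen marker wins) and idempotent; `r² ≤ 1`
keeps everything. The source study's description leaves open whether pruning
was against all markers or the retained ones; pruning against the retained
set was chosen as the deterministic, order-stable reading. Columns are
centered at twice the allele frequency; unit-variance standardization is
available (`standardize = TRUE`) but off by default, since standardization
re-weights rare alleles, which matters in a population where half the loci
have MAF below 10%. A grid of three MAF (≥ 2.5/5/10%) by three LD
(≤ 0.75/0.90/1) thresholds gives the nine study matrices; `"MAF ≥ 0.01"` in
the wider grid is read as 0.01% — effectively all polymorphic loci.
`sample_random_sets()` draws uniform marker subsets (e.g. 100–7,200 by 100,
10 replicates = 720 matrices) with per-draw seeds derived from the master
seed.

## Phenotype analysis

`fit_lattice_model()` fits `Y = mu + g_i + R_j + b_k(j) + e` by REML (lme4):
genotype and block-within-replicate random, replicate fixed. Genotype BLUPs
are the response of all downstream prediction models.
`narrow_sense_h2()` is `s2_g/(s2_g + s2_e)`, exactly as printed in the
motivating study; note that the study's own printed h² values are *not* equal
to this ratio of its printed variance components (e.g. 46.03/(46.03+4.16) =
0.917 against a printed 0.86), so no attempt is made to force-match them —
the printed h² values are used only as simulation targets.

## Prediction methods

All five methods share the `gs_model` surface and `predict_gebv()`.

* **RR-BLUP** (`fit_rrblup()`): ridge solution
  `beta = X'(XX' + λI)⁻¹(y − mu)` with λ = s2e/s2u estimated by REML through
  one eigendecomposition of XX' and a 1-D profile likelihood.
* **G-BLUP** (`fit_gblup()`): VanRaden relationship matrix
  `G = XX'/(2Σp(1−p))` (diagonal loading 1e-6), REML for (s2g, s2e),
  individual BLUPs from the mixed-model equations. With matched scaling its
  predictions equal RR-BLUP's to numerical tolerance, which the tests assert
  at 1e-6.
* **LASSO** (`fit_lasso()`): coordinate descent via glmnet, with the penalty
  chosen by inner 5-fold cross-validation on a 50-point grid spanning four
  decades below the all-zero bound; duplicated predictors keep at most one
  member.
* **BRR** (`fit_brr()`): Gibbs sampler with a common-variance Gaussian prior
  on effects and scaled-inverse-chi-square hyper-priors whose scales target a
  prior marker R² of 0.5 (default chain 12,000/2,000/5; the CV engine uses
  shorter chains by default, see below).
* **Bayesian LASSO** (`fit_bl()`): double-exponential prior via the
  scale-mixture-of-normals representation, inverse-Gaussian updates for the
  local scales, Gamma(1.1, ·) prior on λ² centred on the R² = 0.5 rule.
  Relative to BRR it shrinks small effects harder and large effects less,
  which the tests verify on sparse-signal simulations.

Both samplers are implemented in C++ (Rcpp) with single-site updates and run
on R's RNG, so a seed makes chains exactly reproducible. The exact
hyper-parameter values and chain lengths of the motivating study were not
reported; the defaults above are this package's own documented choices.

## The cross-validation factorial

`enumerate_scenarios()` builds the factor grid in canonical order (the main
study grid is 4 traits × 5 methods × 3 MAF × 3 LD × 3 k = 540 scenarios).
`make_folds()` implements the three assignment strategies: random near-equal
folds (validation sets of `floor(N/k)` with the remainder spread one per
fold: 114–115 lines at k = 3 for N = 343), stratified folds preserving
subpopulation proportions, and leave-one-subpopulation-out.
`run_cross_validation()` runs `R = ceiling(100/k)` replicate partitions
(34/17/12 for k = 3/6/9), fits on the training folds, predicts the left-out
fold and records the Pearson correlation with the observed BLUPs and its
Fisher z. Marker selection is done once on the full panel per incidence
specification, matching the study design; `markers_per_fold = TRUE` gives the
statistically cleaner within-fold re-selection. Frequentist methods share
fold partitions; `bayes_independent = TRUE` re-partitions for the Bayesian
methods as the study did (shared partitions are the default for
comparability). Per-scenario/replicate seeds are derived from the master seed
by a stable hash, so any single cell is reproducible in isolation.

`anova_accuracy()` analyses z with fixed effects and sum-to-zero coding:
model 1 (scenario as one factor, 539 df on the main grid), model 2 (main
effects, 13 df), model 3 (mains plus all ten first-order interactions,
79 df), each term tested against its own model's MSE, with R², CV% and root
MSE reported. `lsmeans_accuracy()` computes balanced-weight adjusted means on
the model's reference grid, runs unadjusted pairwise t tests on the model MSE
at α = 0.05, assigns compact letters by insert-and-absorb, and back-transforms
means to the correlation scale.

## Numerical choices and degenerate inputs

* REML profile optimization runs on log10(λ) over [−8, 8] with tolerance
  1e-9; eigenvalues are clipped at zero.
* A constant training response yields an explicit degenerate model (zero
  effects, intercept prediction) rather than an error, so factorial runs
  continue; individual fold failures are recorded as missing with a log
  message.
* Correlations of ±1 are clipped to ±(1 − 1e-12) with a warning before the z
  transform.
* `fisher_z()`/`inv_fisher_z()` round-trip to 1e-12; fold partitions are
  validated as disjoint and exhaustive on every construction.
* Monomorphic loci are excluded by the MAF filter (even at threshold 0) and
  skipped in LD; an empty marker selection is an explicit error.
* The CV engine's default MCMC settings (2,000 iterations, 500 burn-in,
  thin 5) are deliberately shorter than the standalone fitting defaults so a
  full 540-scenario factorial stays within an hour on one CPU; pass `mcmc =
  list(iter = 12000, burnin = 2000, thin = 5)` for publication-length chains.

## Problem sizes used by the test suite

The unit and acceptance tests run the full pipeline at reduced problem sizes
chosen to exercise every code path while keeping the default suite around two
minutes: a 50-line/180-locus toy panel and a 130-line/720-locus medium panel
for engine tests, ten full-scale (343 × 8,340) replicate populations for the
calibration suite, 343 × 2,000 for the RR-BLUP/G-BLUP equivalence bound, and
Wright–Fisher oracles with 800 unlinked loci for the Ne recovery suite. The
acceptance script simulates five full-scale replicate populations.

## Known limitations

* No selection during cycles, no dominance or epistasis, no mutation, no
  genotyping error or missing data: the simulator targets population
  structure, not data artefacts.
* The male-sterility-driven outcrossing of the real programme is represented
  simply by random mating.
* LD is measured on dosages (composite), which for residually heterozygous
  lines slightly understates gametic r²; the Ne consequences are described
  under *Calibration*.
* The accuracy ANOVA treats validation tests as independent observations, as
  in the motivating study; replicate partitions overlap, so p-values are
  anti-conservative in both.
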