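# gsrice

Evaluating the accuracy of genomic selection in a recurrent-selection rice
synthetic population.

## What this package is for

Breeding programmes that improve a synthetic population by recurrent selection
want to know whether genome-wide marker data can replace part of the
phenotyping: train a whole-genome regression on phenotyped lines, predict
genomic estimated breeding values (GEBV) for the rest, and select on the
prediction. The usefulness of that scheme depends on the population — its
linkage disequilibrium (LD), allele-frequency spectrum, effective size and
subpopulation structure — and on analysis choices: marker filtering, training
set size and composition, prediction model, and trait heritability.

`gsrice` provides the complete evaluation loop for an upland-rice-like
setting of 343 S2 lines from four inter-related subpopulations genotyped at
~8,340 SNPs:

* a forward-in-time **simulator** of the synthetic population (beta-law
  founder frequencies, recombination cycles, subpopulation drift with
  migration, single seed descent, additive traits, an alpha-lattice field
  trial);
* **population genetics**: per-locus allele statistics, within-chromosome LD
  and its decay profile, pairwise Weir–Cockerham F<sub>ST</sub>, LD-based
  effective population size (inter-chromosomal pairs, Waples' sample-size
  correction), mismatch-distance kinship;
* **marker selection**: inclusive MAF filtering, greedy per-chromosome LD
  pruning, random marker sets — yielding centered incidence matrices;
* **phenotype analysis**: REML for the lattice model
  `Y = mu + g_i + R_j + b_k(j) + e`, genotype BLUPs, narrow-sense
  heritability `h² = s²_g/(s²_g + s²_e)`;
* **five prediction methods** behind one interface: RR-BLUP
  (`beta = X'(XX' + λI)⁻¹(y − mu)`, λ by REML), G-BLUP (VanRaden
  `G = XX'/(2Σp(1−p))`), LASSO (glmnet, inner-CV penalty), Bayesian ridge
  regression and the Bayesian LASSO (Rcpp Gibbs samplers);
* the **cross-validation factorial**: k ∈ {3, 6, 9} folds with
  `R = ceiling(100/k)` replicates, random / stratified /
  leave-subpopulation-out assignment, Fisher-z transform
  `z = ½ ln((1+r)/(1−r))`, three nested fixed-effects ANOVA models, and
  adjusted means (LSMeans) with compact letter displays.

Everything takes and returns tibbles where the data are tabular, fitted
objects have `tidy()`/`glance()` methods, and the main result types have
`autoplot()` methods.

## Worked example

Simulate the default-calibration population, characterize it, analyse the
trial, and run a small slice of the cross-validation factorial:

```r
library(gsrice)

pop <- simulate_population(sim_config(seed = 2026))
pop
#> <gs_population> 343 lines x 8340 loci (12 chromosomes), generation S2
#>   subpopulations: P1 (n=86), P2 (n=83), P3 (n=82), P4 (n=92)
#>   traits with true breeding values: FL, PH, YLD, PW

stats <- allele_stats(pop)
round(c(mean = mean(stats$maf[stats$maf > 0]),
        median = median(stats$maf[stats$maf > 0])), 3)
#>   mean median
#>  0.139  0.125

fst_pairwise(pop)
#> <gs_fst> pairwise Weir-Cockerham theta
#>        P1     P2     P3     P4
#> P1 0.0000 0.0402 0.0353 0.0287
#> P2 0.0402 0.0000 0.0400 0.0403
#> P3 0.0353 0.0400 0.0000 0.0312
#> P4 0.0287 0.0403 0.0312 0.0000

trial <- simulate_field_trial(pop, seed = 1)
blups <- fit_all_traits(trial)
blups
#> <gs_blup_table> 343 lines x 4 traits
#>   h2: FL = 0.870, PH = 0.613, YLD = 0.263, PW = 0.107

sc <- enumerate_scenarios(
  traits = c("FL", "PH"), methods = c("RRBLUP", "LASSO"),
  maf_thresholds = 0.05, ld_thresholds = c(0.9, 1), k_folds = 3)
rec <- run_cross_validation(sc, pop, blups, seed = 7, n_rep = 3)
average_accuracy(rec)
#> # A tibble: 8 x 11
#>   scenario trait method   maf    ld matrix_id     k strategy    AA     sd
#>      <int> <chr> <chr>  <dbl> <dbl> <chr>     <dbl> <chr>    <dbl>  <dbl>
#> 1        1 FL    RRBLUP  0.05   0.9 <NA>          3 random   0.478 0.0648
#> 2        2 FL    RRBLUP  0.05   1   <NA>          3 random   0.510 0.0208
#> 3        3 FL    LASSO   0.05   0.9 <NA>          3 random   0.767 0.0779
#> 4        4 FL    LASSO   0.05   1   <NA>          3 random   0.798 0.0356
#> 5        5 PH    RRBLUP  0.05   0.9 <NA>          3 random   0.495 0.0641
#> 6        6 PH    RRBLUP  0.05   1   <NA>          3 random   0.552 0.0521
#> 7        7 PH    LASSO   0.05   0.9 <NA>          3 random   0.573 0.0483
#> 8        8 PH    LASSO   0.05   1   <NA>          3 random   0.602 0.0686

lsmeans_accuracy(anova_accuracy(rec, model = 2), "method")
#> # A tibble: 2 x 6
#>   factor level  z_mean     se r_mean group
#>   <chr>  <chr>   <dbl>  <dbl>  <dbl> <chr>
#> 1 method LASSO   0.872 0.0240  0.702 a
#> 2 method RRBLUP  0.564 0.0240  0.511 b
```

Reading the output: the simulated panel shows the U-shaped allele-frequency
spectrum (mean MAF 13.9%), mild subpopulation differentiation
(F<sub>ST</sub> 0.029–0.040), and lattice heritabilities close to the
generating targets (0.86/0.58/0.29/0.10). In the factorial slice, `AA` is the
average accuracy — the mean Pearson correlation between predicted GEBVs and
observed BLUPs over the validation folds. On this panel the LASSO beats
RR-BLUP for the oligogenic trait FL (0.77–0.80 vs 0.48–0.51) because a single
major locus dominates FL and variable selection captures it; the LSMeans
table confirms the method difference with distinct letter groups. A full
540-scenario factorial is the same call with the full grids.

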