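Package: gsrice
Title: Genomic Selection Accuracy Evaluation in Recurrent-Selection Rice Synthetic Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the accuracy of genomic estimated breeding
    values (GEBV) in synthetic breeding populations maintained by recurrent
    selection, modelled on an upland rice programme. Includes a forward-in-time
    simulator of a multi-subpopulation synthetic population with beta-law
    founder allele frequencies, random-mating recombination cycles and single
    seed descent; population-genetic characterization (allele statistics,
    linkage disequilibrium decay, Weir-Cockerham FST, LD-based effective
    population size, marker-based kinship); marker incidence-matrix
    construction by MAF filtering, per-chromosome LD pruning and random
    sampling; alpha-lattice REML analysis producing genotype BLUPs and
    narrow-sense heritability; five whole-genome regression methods (RR-BLUP,
    G-BLUP, LASSO, Bayesian ridge regression and the Bayesian LASSO); and a
    replicated cross-validation factorial engine with Fisher-z transformation,
    fixed-effects ANOVA and adjusted means with compact letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    stats,
    utils,
    lme4,
    glmnet,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    vcfR,
    withr
Config/testthat/edition: 3
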