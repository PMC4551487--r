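test_that("the factorial grids have the study's scenario counts", {
  main <- enumerate_scenarios(
    traits = c("FL", "PH", "YLD", "PW"),
    methods = c("RRBLUP", "GBLUP", "LASSO", "BRR", "BL"),
    maf_thresholds = c(0.025, 0.05, 0.10),
    ld_thresholds = c(0.75, 0.90, 1),
    k_folds = c(3, 6, 9))
  expect_equal(nrow(main), 540)
  expect_equal(main$scenario, seq_len(540))

  supp <- enumerate_scenarios(
    traits = c("FL", "PH", "YLD", "PW"), methods = "RRBLUP",
    matrix_ids = sprintf("M%02d", 1:35), k_folds = 3)
  expect_equal(nrow(supp), 140)

  kin <- enumerate_scenarios(
    traits = c("FL", "PH", "YLD", "PW"), methods = "RRBLUP",
    matrix_ids = sprintf("M%02d", 1:35), k_folds = 3,
    strategies = c("random", "stratified",
                   paste0("loso:", c("P1", "P2", "P3", "P4"))))
  expect_equal(nrow(kin), 840)
  expect_error(enumerate_scenarios(character(), "RRBLUP",
                                   matrix_ids = "M1"), "nonempty")
})

test_that("scenario counts follow the product formula for random grids", {
  set.seed(99)
  for (i in 1:5) {
    nt <- sample(1:4, 1); nm <- sample(1:5, 1); nmaf <- sample(1:4, 1)
    nld <- sample(1:4, 1); nk <- sample(1:3, 1)
    sc <- enumerate_scenarios(sprintf("t%d", 1:nt), sprintf("m%d", 1:nm),
                              seq_len(nmaf) / 10, seq_len(nld) / 4,
                              k_folds = seq_len(nk) + 1)
    expect_equal(nrow(sc), nt * nm * nmaf * nld * nk)
  }
})

test_that("random folds reproduce the study's TP/VP sizes", {
  ids <- sprintf("L%03d", 1:343)
  for (k in c(3, 6, 9)) {
    f <- make_folds(ids, k, "random", seed = 1)
    sizes <- as.integer(table(f$fold))
    expect_equal(sum(sizes), 343)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(min(sizes), floor(343 / k))  # VP floor, TP = N - VP
  }
  f3 <- make_folds(ids, 3, "random", seed = 1)
  expect_setequal(as.integer(table(f3$fold)), c(115, 114))
  # 229- and 228-line training sets
  expect_setequal(343 - as.integer(table(f3$fold)), c(228, 229))
})

test_that("fold partitions are disjoint and exhaustive for every strategy", {
  ids <- sprintf("L%03d", 1:343)
  sp <- rep(c("P1", "P2", "P3", "P4"), c(86, 83, 82, 92))
  for (strat in c("random", "stratified", "leave_subpop_out")) {
    f <- make_folds(ids, 3, strat, subpop = sp, seed = 2)
    expect_setequal(f$line_id, ids)
    expect_false(any(duplicated(f$line_id)))
    expect_true(all(f$fold >= 1))
  }
})

test_that("stratified folds keep subpopulation proportions within one line", {
  ids <- sprintf("L%03d", 1:343)
  sp <- rep(c("P1", "P2", "P3", "P4"), c(86, 83, 82, 92))
  f <- make_folds(ids, 3, "stratified", subpop = sp, seed = 3)
  tab <- table(sp, f$fold)
  for (s in rownames(tab)) {
    expect_lte(diff(range(tab[s, ])), 1)
  }
})

test_that("leave-subpopulation-out yields one fold per subpopulation", {
  ids <- sprintf("L%03d", 1:343)
  sp <- rep(c("P1", "P2", "P3", "P4"), c(86, 83, 82, 92))
  f <- make_folds(ids, 3, "leave_subpop_out", subpop = sp)
  expect_equal(length(unique(f$fold)), 4)
  expect_setequal(as.integer(table(f$fold)), c(86, 83, 82, 92))
  # the largest subpopulation is a 92-line validation set
  expect_equal(sum(f$fold == which(levels(factor(sp)) == "P4")), 92)
  expect_error(make_folds(ids, 400, "random"), "exceeds")
  expect_error(make_folds(ids, 3, "stratified"), "subpop")
})

test_that("the Fisher z transform is exact, odd, monotone and invertible", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_lt(max(abs(r - inv_fisher_z(fisher_z(r)))), 1e-12)
  expect_warning(z <- fisher_z(1), "clipped")
  expect_true(is.finite(z))
})

test_that("the CV engine records k * ceiling(100/k) tests per scenario", {
  pop <- tiny_population(seed = 40)
  pop <- build_trait(pop, trait_architecture("t", n_qtl = 15, target_h2 = 0.8),
                     seed = 1)
  blups <- tibble::tibble(line = pop$line_id,
                          t = as.numeric(pop$tbv$t) +
                            rnorm(length(pop$line_id), 0, 0.5))
  sc <- enumerate_scenarios("t", "RRBLUP", 0.05, 1, k_folds = 9)
  rec <- run_cross_validation(sc, pop, blups, seed = 2)
  expect_equal(nrow(rec), 9 * 12)   # R = 12 for k = 9
  expect_true(all(rec$r >= -1 & rec$r <= 1, na.rm = TRUE))
  expect_equal(max(rec$replicate), 12)
  # same master seed reproduces the records
  rec2 <- run_cross_validation(sc, pop, blups, seed = 2)
  expect_equal(rec$r, rec2$r)
})

test_that("a heritability-one trait with dense markers predicts accurately", {
  cfg <- medium_config(seed = 41)
  pop <- simulate_population(cfg, traits = list(
    trait_architecture("t", n_qtl = 60, target_h2 = 1)))
  blups <- tibble::tibble(line = pop$line_id, t = as.numeric(pop$tbv$t))
  sc <- enumerate_scenarios("t", "RRBLUP", 0.025, 1, k_folds = 9)
  rec <- run_cross_validation(sc, pop, blups, seed = 3, n_rep = 2)
  expect_gt(mean(rec$r), 0.8)
})

test_that("all five methods run through the engine", {
  pop <- tiny_population(seed = 42)
  pop <- build_trait(pop, trait_architecture("t", n_qtl = 15, target_h2 = 0.9),
                     seed = 2)
  blups <- tibble::tibble(line = pop$line_id,
                          t = as.numeric(pop$tbv$t) + rnorm(50, 0, 0.3))
  sc <- enumerate_scenarios("t", c("RRBLUP", "GBLUP", "LASSO", "BRR", "BL"),
                            0.05, 1, k_folds = 3)
  rec <- run_cross_validation(sc, pop, blups, seed = 4, n_rep = 1,
                              mcmc = list(iter = 400, burnin = 100, thin = 2))
  expect_equal(nrow(rec), 15)
  expect_true(all(is.finite(rec$z)))
  aa <- average_accuracy(rec)
  expect_equal(nrow(aa), 5)
})

test_that("ANOVA models 1-3 have the study's degrees of freedom", {
  grid <- enumerate_scenarios(
    traits = c("FL", "PH", "YLD", "PW"),
    methods = c("RRBLUP", "GBLUP", "LASSO", "BRR", "BL"),
    maf_thresholds = c(0.025, 0.05, 0.10),
    ld_thresholds = c(0.75, 0.90, 1),
    k_folds = c(3, 6, 9))
  set.seed(50)
  records <- tidyr::expand_grid(grid, replicate = 1:3) %>%
    dplyr::mutate(z = rnorm(dplyr::n(), 0.3, 0.1))
  a1 <- anova_accuracy(records, model = 1)
  a2 <- anova_accuracy(records, model = 2)
  a3 <- anova_accuracy(records, model = 3)
  expect_equal(a1$fit_stats$df[1], 539)
  expect_equal(a2$fit_stats$df[1], 13)
  expect_equal(a3$fit_stats$df[1], 79)
  expect_equal(sum(a2$effects$df), 13)
  expect_equal(sum(a3$effects$df), 79)
  # nested-model fit ordering
  expect_gte(a3$r_squared, a2$r_squared - 1e-12)
  expect_gte(a1$r_squared, a3$r_squared - 1e-12)
  expect_equal(glance(a2)$df_model, 13)
})

test_that("the one-way F statistic matches the textbook oracle", {
  set.seed(51)
  dat <- tibble::tibble(
    trait = rep(c("a", "b", "c"), each = 20),
    method = "m", maf = 0.05, ld = 1, k = 3, strategy = "random",
    z = rnorm(60, rep(c(0, 0.3, 0.5), each = 20), 0.2))
  a <- anova_accuracy(dat, model = 1)
  grand <- mean(dat$z)
  ssb <- 20 * sum((tapply(dat$z, dat$trait, mean) - grand)^2)
  ssw <- sum((dat$z - ave(dat$z, dat$trait))^2)
  f_oracle <- (ssb / 2) / (ssw / 57)
  expect_equal(a$fit_stats$f[1], f_oracle, tolerance = 1e-10)
  expect_error(anova_accuracy(dat[dat$trait == "a", ], model = 1),
               "fewer than 2")
})

test_that("LSMeans equal raw level means in balanced data and letter correctly", {
  set.seed(52)
  dat <- tidyr::expand_grid(trait = c("a", "b"), method = c("m1", "m2", "m3"),
                            replicate = 1:30) %>%
    dplyr::mutate(z = rnorm(dplyr::n(), 0.2, 0.05) +
                    ifelse(method == "m3", 0.3, 0))
  a2 <- anova_accuracy(dat, model = 2, factors = c("trait", "method"))
  ls <- lsmeans_accuracy(a2, "method")
  raw <- tapply(dat$z, dat$method, mean)
  expect_equal(sort(ls$z_mean), sort(as.numeric(raw)), tolerance = 1e-10)
  expect_equal(ls$r_mean, inv_fisher_z(ls$z_mean))
  # the shifted level is alone in its letter group
  expect_false(ls$group[ls$level == "m3"] %in%
                 ls$group[ls$level != "m3"])
  expect_error(lsmeans_accuracy(a2, "nope"), "not a model factor")

  # identical data in all levels -> one shared letter
  dat0 <- tidyr::expand_grid(trait = c("a", "b"), method = c("m1", "m2", "m3"),
                             replicate = 1:30)
  base_z <- rnorm(60, 0.2, 0.05)
  dat0$z <- base_z[as.integer(interaction(dat0$trait, dat0$replicate))]
  a0 <- anova_accuracy(dat0, model = 2, factors = c("trait", "method"))
  ls0 <- lsmeans_accuracy(a0, "method")
  expect_equal(unique(ls0$group), "a")
})

test_that("LSMeans agree with the emmeans oracle on a balanced factorial", {
  skip_if_not_installed("emmeans")
  set.seed(53)
  dat <- tidyr::expand_grid(trait = c("a", "b"), method = c("m1", "m2"),
                            k = c(3, 6), replicate = 1:5) %>%
    dplyr::mutate(z = rnorm(dplyr::n(), 0.3, 0.1))
  a2 <- anova_accuracy(dat, model = 2, factors = c("trait", "method", "k"))
  ls <- lsmeans_accuracy(a2, "method")
  em <- as.data.frame(emmeans::emmeans(a2$fit, "method"))
  expect_equal(sort(ls$z_mean), sort(em$emmean), tolerance = 1e-10)
  expect_equal(sort(ls$se), sort(em$SE), tolerance = 1e-10)
})

test_that("rank-deficient accuracy designs raise an informative error", {
  dat <- tibble::tibble(trait = rep(c("a", "b"), each = 10),
                        method = rep(c("m1", "m2"), each = 10),  # aliased
                        z = rnorm(20))
  expect_error(anova_accuracy(dat, model = 2,
                              factors = c("trait", "method")),
               "rank deficient|aliased")
})
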