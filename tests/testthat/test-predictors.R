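centered <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("m%03d", seq_len(p))
  scale(X, scale = FALSE)
}

test_that("ridge solution matches closed-form algebra on orthonormal designs", {
  n <- 64
  set.seed(4)
  x <- rnorm(n); x <- x - mean(x); x <- x / sqrt(sum(x^2))  # x'x = 1
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "m1"))
  y <- 0.8 * x + rnorm(n, 0, 0.2)
  lam <- 2.5
  fit <- fit_rrblup(X, y, lambda = lam)
  # GLS intercept, then beta = x'(y - mu) / (1 + lambda)
  mu <- fit$mu
  expect_equal(unname(fit$beta), sum(x * (y - mu)) / (1 + lam),
               tolerance = 1e-10)
})

test_that("infinite shrinkage drives effects to zero and predictions to the mean", {
  X <- centered(40, 30, seed = 2)
  set.seed(5)
  y <- rnorm(40, 10)
  fit <- fit_rrblup(X, y, lambda = 1e10)
  expect_lt(max(abs(fit$beta)), 1e-6)
  expect_equal(unname(predict_gebv(fit, X)), rep(mean(y), 40),
               tolerance = 1e-3)
})

test_that("REML ridge recovers a noiseless additive signal", {
  set.seed(6)
  g <- random_geno(120, 80, seed = 6)
  X <- scale(g, scale = FALSE)
  beta <- rnorm(80, 0, 0.3)
  y <- drop(X %*% beta)
  tp <- 1:90
  fit <- fit_rrblup(X[tp, ], y[tp])
  pred <- predict_gebv(fit, X[-tp, ])
  expect_gt(cor(pred, y[-tp]), 0.99)
})

test_that("RR-BLUP and G-BLUP give identical predictions under matched scaling", {
  pop <- tiny_population(seed = 30, loci_per_chrom = 250)
  inc <- build_incidence_matrix(pop, 0.05, 1)
  set.seed(7)
  y <- drop(inc$X %*% rnorm(ncol(inc$X), 0, 0.1)) + rnorm(nrow(inc$X), 0, 1)
  fr <- fit_rrblup(inc, y)
  fg <- fit_gblup(inc, y)
  newg <- dosage(pop)[, inc$loci$locus]
  expect_equal(predict_gebv(fr, newg), predict_gebv(fg, newg),
               tolerance = 1e-6)
})

test_that("G-BLUP with an identity kernel shrinks records by heritability", {
  set.seed(8)
  y <- rnorm(50, 5, 2)
  fit <- fit_gblup(y = y, G = diag(50))
  h2 <- fit$extra$sigma2_g / (fit$extra$sigma2_g + fit$extra$sigma2_e)
  u <- predict_gebv(fit, diag(50), G_rows = TRUE) - fit$mu
  expect_equal(u, h2 * (y - fit$mu), tolerance = 1e-4)
  expect_error(fit_gblup(y = y, G = matrix(rnorm(2500), 50)), "symmetric")
  bad <- diag(50); bad[1, 1] <- -5
  expect_error(fit_gblup(y = y, G = bad), "positive semi-definite")
})

test_that("training-set permutation leaves the fitted model unchanged", {
  X <- centered(50, 40, seed = 9)
  set.seed(9)
  y <- rnorm(50)
  f1 <- fit_rrblup(X, y)
  pp <- sample(50)
  f2 <- fit_rrblup(X[pp, ], y[pp])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("LASSO obeys the KKT zero bound and soft-thresholding", {
  n <- 80
  X <- centered(n, 20, seed = 10)
  set.seed(10)
  y <- drop(X %*% c(rep(1, 3), rep(0, 17))) + rnorm(n, 0, 0.5)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n
  fit0 <- fit_lasso(X, y, lambda = lmax * 1.01)
  expect_true(all(fit0$beta == 0))

  # orthonormal columns scaled so x_j'x_j = n: beta_j = S(x_j'y/n, lambda)
  Q <- qr.Q(qr(centered(n, 5, seed = 11)))  # columns of 1-perp, orthonormal
  Q <- scale(Q, scale = FALSE)              # guard against qr sign drift
  Q <- qr.Q(qr(Q)) * sqrt(n)
  colnames(Q) <- sprintf("m%03d", 1:5)
  set.seed(12)
  y2 <- drop(Q %*% c(2, -1, 0.5, 0, 0)) + rnorm(n, 0, 0.3)
  y2 <- y2 - mean(y2)
  lam <- 0.4
  fit <- fit_lasso(Q, y2, lambda = lam)
  ols <- drop(crossprod(Q, y2)) / n
  soft <- sign(ols) * pmax(abs(ols) - lam, 0)
  expect_equal(unname(fit$beta), unname(soft), tolerance = 1e-4)
})

test_that("LASSO keeps at most one of a duplicated predictor pair", {
  n <- 100
  set.seed(13)
  x <- rnorm(n)
  X <- cbind(x, x, matrix(rnorm(n * 8), n))
  X <- scale(X, scale = FALSE)
  colnames(X) <- sprintf("m%03d", 1:10)
  y <- 2 * x + rnorm(n, 0, 0.3)
  fit <- fit_lasso(X, y, seed = 1)
  expect_lte(sum(fit$beta[1:2] != 0), 1)
})

test_that("Gibbs samplers are reproducible under a seed", {
  X <- centered(40, 25, seed = 14)
  set.seed(14)
  y <- rnorm(40)
  b1 <- fit_brr(X, y, iter = 400, burnin = 100, seed = 3)
  b2 <- fit_brr(X, y, iter = 400, burnin = 100, seed = 3)
  expect_identical(b1$beta, b2$beta)
  l1 <- fit_bl(X, y, iter = 400, burnin = 100, seed = 3)
  l2 <- fit_bl(X, y, iter = 400, burnin = 100, seed = 3)
  expect_identical(l1$beta, l2$beta)
  expect_false(identical(b1$beta, l1$beta))
  expect_error(fit_brr(X, y, iter = 100, burnin = 100), "burnin")
})

test_that("with fixed variances BRR converges to the matching ridge solution", {
  n <- 60; p <- 30
  X <- centered(n, p, seed = 15)
  set.seed(15)
  y <- drop(X %*% rnorm(p, 0, 0.5)) + rnorm(n)
  varE <- 1; varB <- 0.25          # lambda = varE / varB = 4
  ridge <- fit_rrblup(X, y, lambda = varE / varB)
  brr <- fit_brr(X, y, iter = 6000, burnin = 1000, thin = 2,
                 varB = varB, varE = varE, seed = 8)
  mcse <- brr$extra$beta_sd / sqrt(brr$extra$n_samples / 10)
  expect_true(all(abs(brr$beta - ridge$beta) < pmax(3 * mcse, 0.02)))
})

test_that("BRR posterior of the residual variance matches the conjugate answer", {
  # zero design column: the model collapses to y = mu + e with a
  # scaled-inverse-chi-square prior, whose marginal posterior is closed form
  n <- 40
  X <- matrix(0, n, 1, dimnames = list(NULL, "m1"))
  set.seed(16)
  y <- rnorm(n, 2, 1.5)
  df0 <- 5
  hy_Se <- (1 - 0.5) * var(y) * (df0 + 2)
  brr <- fit_brr(X, y, iter = 8000, burnin = 1000, thin = 2, df = df0,
                 varB = 1, seed = 4)
  sse <- sum((y - mean(y))^2)
  analytic <- (hy_Se + sse) / (df0 + n - 1 - 2)
  chain <- brr$extra$varE_chain
  mcse <- sd(chain) / sqrt(length(chain) / 10)
  expect_lt(abs(brr$extra$varE - analytic), 3 * mcse + 0.02)
})

test_that("null data leave BRR effects within their posterior spread", {
  n <- 80; p <- 100
  X <- centered(n, p, seed = 17)
  set.seed(17)
  y <- rnorm(n)
  brr <- fit_brr(X, y, iter = 1500, burnin = 500, seed = 5)
  frac <- mean(abs(brr$beta) < 3 * brr$extra$beta_sd)
  expect_gte(frac, 0.95)
})

test_that("the Bayesian LASSO shrinks adaptively relative to BRR", {
  set.seed(18)
  null_ratio <- big_ratio <- numeric(4)
  for (r in 1:4) {
    n <- 120; p <- 200
    X <- centered(n, p, seed = 18 + r)
    big <- 1:5
    beta <- c(rnorm(5, 0, 1.2), rep(0, p - 5))
    y <- drop(X %*% beta) + rnorm(n, 0, 0.5)
    brr <- fit_brr(X, y, iter = 1500, burnin = 500, seed = r)
    bl <- fit_bl(X, y, iter = 1500, burnin = 500, seed = r)
    null_ratio[r] <- mean(abs(bl$beta[-big])) / mean(abs(brr$beta[-big]))
    big_ratio[r] <- mean(abs(bl$beta[big])) / mean(abs(brr$beta[big]))
  }
  expect_lt(mean(null_ratio), 1)   # small effects shrunk harder by BL
  expect_gt(mean(big_ratio), 1)    # large effects shrunk less by BL
})

test_that("a huge fixed lambda collapses the Bayesian LASSO to zero", {
  X <- centered(50, 20, seed = 19)
  set.seed(19)
  y <- drop(X %*% rnorm(20)) + rnorm(50)
  bl <- fit_bl(X, y, iter = 600, burnin = 200, lambda2 = 1e10, seed = 2)
  expect_lt(max(abs(bl$beta)), 1e-3)
})

test_that("prediction handles fitted values, degeneracy and locus checks", {
  pop <- tiny_population(seed = 31)
  inc <- build_incidence_matrix(pop, 0.05, 1)
  set.seed(20)
  y <- rnorm(nrow(inc$X))
  fit <- fit_rrblup(inc, y)
  # training genotypes reproduce fitted values
  geno <- dosage(pop)[, inc$loci$locus]
  expect_equal(unname(predict_gebv(fit, geno)),
               unname(fit$mu + drop(inc$X %*% fit$beta)), tolerance = 1e-10)
  # degenerate constant response
  fit0 <- fit_rrblup(inc, rep(3, nrow(inc$X)))
  expect_true(fit0$degenerate)
  expect_equal(unname(predict_gebv(fit0, geno)), rep(3, nrow(geno)))
  # missing loci are named
  expect_error(predict_gebv(fit, geno[, -1]), "lacks")
})

test_that("GEBVs are invariant to a constant shift of a raw marker coding", {
  pop <- tiny_population(seed = 32)
  g <- dosage(pop)
  # pick a column with no homozygous-alt calls so +1 keeps a valid coding
  j <- which(apply(g, 2, max) == 1)[1]
  skip_if(is.na(j))
  g2 <- g
  g2[, j] <- g2[, j] + 1L
  set.seed(21)
  y <- rnorm(nrow(g))
  f1 <- fit_rrblup(build_incidence_matrix(g, 0, 1, map = pop$map), y)
  f2 <- fit_rrblup(build_incidence_matrix(g2, 0, 1, map = pop$map), y)
  expect_equal(predict_gebv(f1, g), predict_gebv(f2, g2), tolerance = 1e-8)
})

test_that("tidiers expose effects and fit summaries", {
  X <- centered(30, 10, seed = 22)
  set.seed(22)
  y <- rnorm(30)
  fit <- fit_rrblup(X, y)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 10)
  expect_equal(glance(fit)$method, "RRBLUP")
})
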