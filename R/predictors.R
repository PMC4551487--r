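# Whole-genome regression methods sharing one TrainedModel surface.

new_gs_model <- function(method, mu, beta = NULL, loci = NULL, centers = NULL,
                         scales = NULL, extra = list(), degenerate = FALSE) {
  structure(list(method = method, mu = mu, beta = beta, loci = loci,
                 centers = centers, scales = scales, extra = extra,
                 degenerate = degenerate), class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("<gs_model> %s: intercept %.4g, %d marker effects%s\n",
              x$method, x$mu,
              if (is.null(x$beta)) 0L else length(x$beta),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

as_design <- function(X) {
  if (inherits(X, "gs_incidence")) {
    list(X = X$X, loci = X$loci$locus, centers = X$centers, scales = X$scales)
  } else {
    stopifnot(is.matrix(X))
    list(X = X, loci = colnames(X),
         centers = rep(0, ncol(X)), scales = rep(1, ncol(X)))
  }
}

# REML for y = 1*mu + g + e with g ~ N(0, s2u * K), via a single spectral
# decomposition of K and 1-D profile optimization over delta = s2e/s2u.
reml_kernel <- function(K, y, interval = c(-8, 8)) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ty <- drop(crossprod(U, y))
  tx <- drop(crossprod(U, rep(1, n)))
  neg_rll <- function(log10_delta) {
    delta <- 10^log10_delta
    v <- d + delta
    sx <- sum(tx^2 / v)
    mu <- sum(tx * ty / v) / sx
    s2u <- sum((ty - tx * mu)^2 / v) / (n - 1)
    0.5 * ((n - 1) * log(s2u) + sum(log(v)) + log(sx))
  }
  opt <- optimize(neg_rll, interval = interval, tol = 1e-9)
  delta <- 10^opt$minimum
  v <- d + delta
  sx <- sum(tx^2 / v)
  mu <- sum(tx * ty / v) / sx
  s2u <- sum((ty - tx * mu)^2 / v) / (n - 1)
  list(delta = delta, mu = mu, s2u = s2u, s2e = delta * s2u,
       U = U, d = d)
}

gls_mu <- function(K, delta, y) {
  n <- length(y)
  Vi <- solve(K + delta * diag(n))
  one <- rep(1, n)
  drop((one %*% Vi %*% y) / (one %*% Vi %*% one))
}

#' Ridge-regression BLUP (RR-BLUP)
#'
#' Fits `y = mu + X beta + e` with `beta ~ N(0, s2u I)`, i.e. the ridge
#' solution `beta = X'(XX' + lambda I)^-1 (y - mu)` with
#' `lambda = s2e / s2u`. When `lambda` is `NULL` it is estimated by REML on
#' the equivalent mixed model through a single eigendecomposition of `XX'`.
#'
#' @param X Centered design matrix or a `gs_incidence`.
#' @param y Response (phenotypic BLUPs), length `nrow(X)`, at least 10.
#' @param lambda Optional fixed ridge parameter (`s2e/s2u`).
#' @return A `gs_model` with marker effects, intercept and variance
#'   components in `$extra`.
#' @export
fit_rrblup <- function(X, y, lambda = NULL) {
  ds <- as_design(X)
  n <- nrow(ds$X)
  if (n != length(y)) abort("rows(X) must equal length(y).")
  if (n < 10) abort("Need at least 10 training lines.")
  if (sd(y) == 0) {
    return(new_gs_model("RRBLUP", mu = y[1],
                        beta = setNames(rep(0, ncol(ds$X)), ds$loci),
                        loci = ds$loci, centers = ds$centers,
                        scales = ds$scales, degenerate = TRUE))
  }
  K <- tcrossprod(ds$X)
  if (is.null(lambda)) {
    rm_ <- reml_kernel(K, y)
    delta <- rm_$delta
    mu <- rm_$mu
    extra <- list(lambda = delta, sigma2_u = rm_$s2u, sigma2_e = rm_$s2e)
  } else {
    delta <- lambda
    mu <- gls_mu(K, delta, y)
    extra <- list(lambda = delta)
  }
  W <- solve(K + delta * diag(n), y - mu)
  beta <- drop(crossprod(ds$X, W))
  new_gs_model("RRBLUP", mu = mu, beta = setNames(beta, ds$loci),
               loci = ds$loci, centers = ds$centers, scales = ds$scales,
               extra = extra)
}

#' Genomic BLUP (G-BLUP)
#'
#' Builds the VanRaden genomic relationship matrix
#' `G = X X' / (2 sum p (1 - p))` from the centered incidence matrix (or
#' accepts a precomputed `G`), estimates `(s2g, s2e)` by REML, and predicts
#' individual genetic values from the mixed-model equations. When built from
#' markers the fit is stored as the equivalent marker-effect vector, so
#' predictions for new individuals use their genotypes and equal RR-BLUP
#' predictions under matched scaling.
#'
#' @param X Centered design matrix or `gs_incidence` (ignored when `G` is
#'   supplied).
#' @param y Response vector.
#' @param G Optional precomputed relationship matrix (symmetric PSD).
#' @param loading Diagonal loading added to `G` for numerical PSD tolerance.
#' @return A `gs_model`; for a marker-built G the object carries marker
#'   effects, otherwise `$extra$alpha` supports prediction from G rows.
#' @export
fit_gblup <- function(X = NULL, y, G = NULL, loading = 1e-6) {
  if (is.null(G)) {
    ds <- as_design(X)
    p <- ds$centers / 2
    denom <- 2 * sum(p * (1 - p))
    if (denom <= 0) {
      # raw matrix without frequency provenance: fall back to trace scaling
      denom <- mean(diag(tcrossprod(ds$X)))
    }
    G <- tcrossprod(ds$X) / denom
  } else {
    ds <- NULL
    denom <- NA_real_
    if (max(abs(G - t(G))) > 1e-8) abort("G must be symmetric.")
    ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-6 * max(diag(G))) {
      abort(paste("G is not positive semi-definite beyond tolerance;",
                  "consider diagonal loading."))
    }
  }
  n <- length(y)
  G <- G + loading * diag(n)
  if (sd(y) == 0) {
    return(new_gs_model("GBLUP", mu = y[1],
                        beta = if (!is.null(ds))
                          setNames(rep(0, ncol(ds$X)), ds$loci),
                        loci = ds$loci, centers = ds$centers,
                        scales = ds$scales, degenerate = TRUE))
  }
  rm_ <- reml_kernel(G, y)
  alpha <- solve(G + rm_$delta * diag(n), y - rm_$mu)
  extra <- list(sigma2_g = rm_$s2u, sigma2_e = rm_$s2e, delta = rm_$delta,
                alpha = alpha, vanraden_denom = denom)
  if (!is.null(ds)) {
    beta <- drop(crossprod(ds$X, alpha)) / denom
    new_gs_model("GBLUP", mu = rm_$mu, beta = setNames(beta, ds$loci),
                 loci = ds$loci, centers = ds$centers, scales = ds$scales,
                 extra = extra)
  } else {
    new_gs_model("GBLUP", mu = rm_$mu, beta = NULL, extra = extra)
  }
}

#' LASSO whole-genome regression
#'
#' l1-penalized regression via coordinate descent (glmnet), with the penalty
#' `lambda` chosen to minimize inner K-fold cross-validated prediction error
#' on the training set only. The grid spans four decades below the smallest
#' `lambda` that zeroes all effects. Collinear markers are handled by the
#' l1 penalty's property of retaining at most one member of a duplicated
#' group.
#'
#' @param X Centered design matrix or `gs_incidence`.
#' @param y Response vector.
#' @param nfolds Inner CV folds (default 5).
#' @param lambda Optional fixed penalty (skips the inner CV).
#' @param n_lambda,decades Grid resolution and span.
#' @param seed Seed for the inner fold assignment.
#' @return A `gs_model` with a sparse effect vector; `$extra$lambda` is the
#'   selected penalty.
#' @export
fit_lasso <- function(X, y, nfolds = 5, lambda = NULL, n_lambda = 50,
                      decades = 4, seed = NULL) {
  ds <- as_design(X)
  n <- nrow(ds$X)
  if (sd(y) == 0) {
    return(new_gs_model("LASSO", mu = y[1],
                        beta = setNames(rep(0, ncol(ds$X)), ds$loci),
                        loci = ds$loci, centers = ds$centers,
                        scales = ds$scales, degenerate = TRUE))
  }
  lambda_max <- max(abs(crossprod(ds$X, y - mean(y)))) / n
  grid <- 10^seq(log10(lambda_max), log10(lambda_max) - decades,
                 length.out = n_lambda)
  if (is.null(lambda)) {
    if (!is.null(seed)) set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    cv <- glmnet::cv.glmnet(ds$X, y, alpha = 1, lambda = grid,
                            foldid = foldid, standardize = FALSE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(ds$X, y, alpha = 1,
                          lambda = sort(unique(c(grid, lambda)),
                                        decreasing = TRUE),
                          standardize = FALSE)
  }
  cf <- coef(fit, s = lambda, exact = TRUE, x = ds$X, y = y)
  beta <- drop(cf[-1])
  new_gs_model("LASSO", mu = cf[1], beta = setNames(beta, ds$loci),
               loci = ds$loci, centers = ds$centers, scales = ds$scales,
               extra = list(lambda = lambda, n_nonzero = sum(beta != 0)))
}

# Shared hyper-parameter rule: scale the priors so the markers explain a
# target fraction r2 of var(y) a priori.
bayes_hyper <- function(X, y, r2, df) {
  msx <- sum(colMeans(X^2))
  vy <- var(y)
  list(msx = msx, vy = vy,
       S_b = r2 * vy / msx * (df + 2),
       S_e = (1 - r2) * vy * (df + 2))
}

#' Bayesian ridge regression (BRR)
#'
#' Gibbs sampler for `y = mu + X beta + e` with a Gaussian prior of common
#' variance on all marker effects (`beta_j ~ N(0, s2b)`), scaled-inverse
#' chi-square hyper-priors on `s2b` and `s2e`, and prior scales set so the
#' markers account a priori for `r2` of the phenotypic variance.
#'
#' @param X Centered design matrix or `gs_incidence`.
#' @param y Response vector.
#' @param iter,burnin,thin Chain length, burn-in and thinning
#'   (`iter > burnin >= 0`).
#' @param r2 Target prior proportion of variance captured by markers.
#' @param df Prior degrees of freedom for both variances.
#' @param varB,varE Optional fixed variances (no hyper-parameter updates);
#'   used mainly for conjugate checks against the ridge solution.
#' @param seed Chain seed.
#' @return A `gs_model`; `$extra` carries posterior means of the variances,
#'   posterior SDs of the effects and the thinned residual-variance chain.
#' @export
fit_brr <- function(X, y, iter = 12000, burnin = 2000, thin = 5, r2 = 0.5,
                    df = 5, varB = NULL, varE = NULL, seed = NULL) {
  ds <- as_design(X)
  if (iter <= burnin || burnin < 0) abort("Need iter > burnin >= 0.")
  if (!is.null(seed)) set.seed(seed)
  hy <- bayes_hyper(ds$X, y, r2, df)
  fixB <- !is.null(varB)
  fixE <- !is.null(varE)
  res <- brr_gibbs(ds$X, y, as.integer(iter), as.integer(burnin),
                   as.integer(thin), df, hy$S_b, df, hy$S_e,
                   varB %||% (hy$S_b / df), varE %||% (hy$S_e / df),
                   !fixB, !fixE)
  new_gs_model("BRR", mu = res$mu,
               beta = setNames(drop(res$beta), ds$loci),
               loci = ds$loci, centers = ds$centers, scales = ds$scales,
               extra = list(varB = res$varB, varE = res$varE,
                            beta_sd = drop(res$beta_sd),
                            varE_chain = drop(res$varE_chain),
                            varB_chain = drop(res$varB_chain),
                            n_samples = res$n_samples))
}

#' Bayesian LASSO (BL)
#'
#' Gibbs sampler with a double-exponential prior on marker effects via its
#' scale-mixture-of-normals representation (`beta_j ~ N(0, s2e tau2_j)`,
#' `tau2_j ~ Exp(lambda^2/2)`), and a Gamma prior on `lambda^2` whose scale is
#' set to the target prior R2. Relative to BRR this shrinks small effects
#' harder and large effects less.
#'
#' @inheritParams fit_brr
#' @param lambda2 Optional fixed `lambda^2` (no update); large values force
#'   all effects to zero.
#' @param shape Shape of the Gamma prior on `lambda^2`.
#' @return A `gs_model` with `$extra$lambda2` the posterior mean of the
#'   regularization parameter.
#' @export
fit_bl <- function(X, y, iter = 12000, burnin = 2000, thin = 5, r2 = 0.5,
                   df = 5, lambda2 = NULL, shape = 1.1, seed = NULL) {
  ds <- as_design(X)
  if (iter <= burnin || burnin < 0) abort("Need iter > burnin >= 0.")
  if (!is.null(seed)) set.seed(seed)
  hy <- bayes_hyper(ds$X, y, r2, df)
  lambda2_0 <- 2 * (1 - r2) * hy$msx / max(r2, 1e-6)
  fixL <- !is.null(lambda2)
  res <- bl_gibbs(ds$X, y, as.integer(iter), as.integer(burnin),
                  as.integer(thin), shape, shape / lambda2_0,
                  df, hy$S_e, lambda2 %||% lambda2_0,
                  hy$S_e / df, !fixL)
  new_gs_model("BL", mu = res$mu,
               beta = setNames(drop(res$beta), ds$loci),
               loci = ds$loci, centers = ds$centers, scales = ds$scales,
               extra = list(varE = res$varE, lambda2 = res$lambda2,
                            beta_sd = drop(res$beta_sd),
                            n_samples = res$n_samples))
}

#' Predict genomic estimated breeding values
#'
#' `GEBV = mu + X_c beta` for marker-based models, where new genotypes are
#' re-centered (and re-scaled, if the model was standardized) with the vectors
#' stored at training time, making predictions invariant to constant shifts of
#' raw marker codings. For a G-BLUP model fitted from a relationship matrix
#' alone, supply the new individuals' G rows against the training lines.
#'
#' @param model A `gs_model`.
#' @param newdata Raw dosage matrix (lines x loci, colnames covering the
#'   training loci), an already-centered design from the same
#'   `gs_incidence`, or G rows (`G_rows = TRUE`).
#' @param G_rows Interpret `newdata` as rows of the relationship matrix
#'   between new and training individuals.
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, newdata, G_rows = FALSE) {
  stopifnot(inherits(model, "gs_model"))
  if (G_rows) {
    if (is.null(model$extra$alpha)) abort("Model carries no G-based solution.")
    return(drop(model$mu + as.matrix(newdata) %*% model$extra$alpha))
  }
  if (is.null(model$beta)) abort("Model has no marker effects; pass G rows.")
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(model$loci)) {
    missing_loci <- setdiff(model$loci, colnames(X))
    if (length(missing_loci)) {
      abort(sprintf("newdata lacks %d training loci (first: %s).",
                    length(missing_loci),
                    paste(utils::head(missing_loci, 3), collapse = ", ")))
    }
    X <- X[, model$loci, drop = FALSE]
  } else if (ncol(X) != length(model$beta)) {
    abort("newdata column count does not match the training loci.")
  }
  Xc <- sweep(X, 2, model$centers)
  if (any(model$scales != 1)) Xc <- sweep(Xc, 2, model$scales, "/")
  drop(model$mu + Xc %*% model$beta)
}

#' @export
predict.gs_model <- function(object, newdata, ...) {
  predict_gebv(object, newdata, ...)
}

#' @export
tidy.gs_model <- function(x, ...) {
  tibble::tibble(term = names(x$beta) %||% seq_along(x$beta),
                 estimate = unname(x$beta))
}

#' @export
glance.gs_model <- function(x, ...) {
  tibble::tibble(method = x$method, n_markers = length(x$beta),
                 intercept = x$mu,
                 lambda = x$extra$lambda %||% NA_real_,
                 sigma2_e = x$extra$sigma2_e %||% x$extra$varE %||% NA_real_,
                 degenerate = x$degenerate)
}
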