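#' Fisher z-transform of a correlation
#'
#' `z = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilizing transform used
#' before the accuracy ANOVA. Correlations at or beyond +-1 are clipped to
#' +-(1 - 1e-12) with a warning. [inv_fisher_z()] is the inverse (`tanh`).
#'
#' @param r Numeric vector of correlations.
#' @return Numeric vector of z values.
#' @export
#' @examples
#' fisher_z(0.5) # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warn("Correlations at or beyond +-1 clipped to +-(1 - 1e-12).")
    r <- pmax(pmin(r, 1 - 1e-12), -1 + 1e-12)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisher_z
#' @param z Numeric vector of z values.
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Enumerate cross-validation scenarios
#'
#' Cartesian product of the factor grids in a fixed canonical order (trait
#' varies slowest, then method, MAF, LD, k, strategy). The main factorial of
#' the study is 4 traits x 5 methods x 3 MAF x 3 LD x 3 k = 540 scenarios.
#'
#' @param traits,methods Character vectors.
#' @param maf_thresholds,ld_thresholds Numeric grids (proportions / r2), or
#'   `NULL` when `matrix_ids` is used instead.
#' @param k_folds Integer grid of fold counts.
#' @param strategies Assignment strategies: `"random"`, `"stratified"`, or
#'   `"loso:<subpop>"` for leave-one-subpopulation-out.
#' @param matrix_ids Optional identifiers of prebuilt incidence matrices
#'   (replaces the MAF x LD grid, e.g. for random marker sets).
#' @return Tibble of scenarios with a `scenario` integer id.
#' @export
enumerate_scenarios <- function(traits, methods, maf_thresholds = NULL,
                                ld_thresholds = NULL, k_folds = 3,
                                strategies = "random", matrix_ids = NULL) {
  if (!length(traits) || !length(methods) || !length(k_folds) ||
      !length(strategies)) {
    abort("All scenario grids must be nonempty.")
  }
  grid <- if (is.null(matrix_ids)) {
    if (!length(maf_thresholds) || !length(ld_thresholds)) {
      abort("Supply maf/ld grids or `matrix_ids`.")
    }
    tidyr::expand_grid(trait = traits, method = methods,
                       maf = maf_thresholds, ld = ld_thresholds,
                       k = k_folds, strategy = strategies)
  } else {
    tidyr::expand_grid(trait = traits, method = methods,
                       matrix_id = matrix_ids, k = k_folds,
                       strategy = strategies)
  }
  dplyr::mutate(grid, scenario = dplyr::row_number(), .before = 1)
}

#' Partition lines into cross-validation folds
#'
#' Three strategies mirror the training/validation assignment designs:
#' `"random"` ignores structure and yields near-equal folds (sizes
#' `floor(N/k)` with the remainder spread one per fold, so validation sets of
#' 343 lines at k = 3 have 114-115 lines); `"stratified"` assigns folds
#' within each subpopulation so every fold's training set keeps the
#' subpopulation proportions (each subpopulation contributes (k-1)/k to
#' training and 1/k to validation); `"leave_subpop_out"` makes each
#' subpopulation one validation fold in turn.
#'
#' @param line_id Character vector of line identifiers.
#' @param k Number of folds (>= 2; ignored for `leave_subpop_out`).
#' @param strategy One of `"random"`, `"stratified"`, `"leave_subpop_out"`.
#' @param subpop Subpopulation labels (required unless `strategy = "random"`).
#' @param seed Integer seed.
#' @return Tibble of class `gs_folds`: `line_id`, `fold` (1..k), plus the
#'   strategy and seed as attributes. Folds are disjoint and exhaustive.
#' @export
make_folds <- function(line_id, k, strategy = c("random", "stratified",
                                                "leave_subpop_out"),
                       subpop = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  n <- length(line_id)
  if (strategy != "leave_subpop_out") {
    if (k < 2) abort("`k` must be >= 2.")
    if (k > n) abort("`k` exceeds the number of lines.")
  }
  if (strategy != "random" && is.null(subpop)) {
    abort("`subpop` labels are required for structured strategies.")
  }
  set.seed(seed)
  fold <- switch(strategy,
    random = {
      base <- rep(seq_len(k), times = n %/% k)
      extra <- seq_len(n %% k)
      sample(c(base, extra))
    },
    stratified = {
      f <- integer(n)
      for (sp in unique(subpop)) {
        idx <- which(subpop == sp)
        ni <- length(idx)
        base <- rep(seq_len(k), times = ni %/% k)
        extra <- if (ni %% k) sample(k, ni %% k) else integer(0)
        f[idx] <- sample(c(base, extra))
      }
      f
    },
    leave_subpop_out = as.integer(factor(subpop))
  )
  res <- tibble::tibble(line_id = line_id, fold = as.integer(fold))
  attr(res, "strategy") <- strategy
  attr(res, "seed") <- seed
  class(res) <- c("gs_folds", class(res))
  res
}

parse_strategy <- function(strategy) {
  if (startsWith(strategy, "loso")) {
    target <- sub("^loso:?", "", strategy)
    list(base = "leave_subpop_out", target = if (nzchar(target)) target)
  } else {
    list(base = strategy, target = NULL)
  }
}

default_mcmc <- function() list(iter = 2000, burnin = 500, thin = 5)

fit_method <- function(method, X, y, mcmc = default_mcmc(), seed = NULL) {
  switch(toupper(method),
    RRBLUP = fit_rrblup(X, y),
    GBLUP = fit_gblup(X, y),
    LASSO = fit_lasso(X, y, seed = seed),
    BRR = fit_brr(X, y, iter = mcmc$iter, burnin = mcmc$burnin,
                  thin = mcmc$thin, seed = seed),
    BL = fit_bl(X, y, iter = mcmc$iter, burnin = mcmc$burnin,
                thin = mcmc$thin, seed = seed),
    abort(sprintf("Unknown method '%s'.", method))
  )
}

#' Run the cross-validation factorial
#'
#' For every scenario, runs `R = ceiling(100 / k)` replicate fold partitions
#' (34/17/12 for k = 3/6/9, so each scenario accumulates at least 100
#' validation tests), fits the scenario's method on each training set,
#' predicts the left-out fold, and records the Pearson correlation `r`
#' between predicted GEBVs and observed BLUPs together with its Fisher z.
#' Marker selection (MAF/LD) is performed once on the full data per incidence
#' specification, matching the study design; `markers_per_fold = TRUE`
#' re-selects within each training fold instead. Leave-subpopulation-out
#' scenarios are deterministic splits and run one replicate.
#'
#' @param scenarios Tibble from [enumerate_scenarios()].
#' @param population `gs_population` (or list with `geno` dosage matrix and
#'   `map`).
#' @param blups Wide tibble of observed BLUPs (`line` column plus one column
#'   per trait), or a `gs_blup_table`.
#' @param seed Master seed; per-scenario/replicate seeds are derived from it
#'   so any cell of the factorial is reproducible in isolation.
#' @param mcmc List with `iter`, `burnin`, `thin` for the Bayesian samplers.
#' @param n_rep Optional replicate-count override.
#' @param incidences Optional named list of prebuilt `gs_incidence` objects,
#'   keyed by `matrix_id`, for scenarios enumerated over `matrix_ids`.
#' @param bayes_independent Use independent fold partitions for the Bayesian
#'   methods (the frequentist methods always share partitions).
#' @param markers_per_fold Re-run marker selection within each training fold.
#' @return A tibble of class `gs_accuracy`, one row per validation test:
#'   scenario key columns, `replicate`, `fold`, `n_vp`, `r`, `z`.
#' @export
run_cross_validation <- function(scenarios, population, blups, seed = 1L,
                                 mcmc = default_mcmc(), n_rep = NULL,
                                 incidences = NULL,
                                 bayes_independent = FALSE,
                                 markers_per_fold = FALSE) {
  if (inherits(population, "gs_population")) {
    geno <- dosage(population)
    map <- population$map
    subpop <- population$subpop
    line_id <- population$line_id
  } else {
    geno <- population$geno
    map <- population$map
    subpop <- population$subpop
    line_id <- rownames(geno)
  }
  if (inherits(blups, "gs_blup_table")) blups <- blups$blups
  stopifnot("line" %in% names(blups))
  blups <- blups[match(line_id, blups$line), ]
  if (anyNA(blups$line)) abort("BLUPs are missing for some lines.")

  inc_cache <- new.env(parent = emptyenv())
  get_incidence <- function(scn) {
    if (!is.null(scn$matrix_id)) {
      inc <- incidences[[as.character(scn$matrix_id)]]
      if (is.null(inc)) abort(sprintf("No incidence '%s'.", scn$matrix_id))
      return(inc)
    }
    key <- sprintf("maf%.6f_ld%.6f", scn$maf, scn$ld)
    if (!exists(key, inc_cache)) {
      assign(key, build_incidence_matrix(geno, scn$maf, scn$ld, map = map),
             inc_cache)
    }
    get(key, inc_cache)
  }

  records <- vector("list", nrow(scenarios))
  for (si in seq_len(nrow(scenarios))) {
    scn <- as.list(scenarios[si, ])
    strat <- parse_strategy(scn$strategy)
    k_eff <- if (strat$base == "leave_subpop_out")
      length(unique(subpop)) else scn$k
    R <- n_rep %||%
      if (strat$base == "leave_subpop_out") 1L else as.integer(ceiling(100 / scn$k))
    inc <- get_incidence(scn)
    y_all <- blups[[scn$trait]]
    if (is.null(y_all)) abort(sprintf("No BLUPs for trait '%s'.", scn$trait))
    key0 <- paste(scn$trait, scn$method, scn$maf %||% scn$matrix_id,
                  scn$ld %||% "", scn$k, scn$strategy, sep = "|")
    is_bayes <- toupper(scn$method) %in% c("BRR", "BL")
    rows <- list()
    for (rep_i in seq_len(R)) {
      fold_key <- if (is_bayes && bayes_independent)
        paste0(key0, "|bayes|", rep_i)
      else paste(scn$trait, scn$maf %||% scn$matrix_id, scn$ld %||% "",
                 scn$k, scn$strategy, rep_i, sep = "|")
      folds <- make_folds(line_id, k = scn$k, strategy = strat$base,
                          subpop = subpop,
                          seed = derive_seed(seed, fold_key))
      eval_folds <- sort(unique(folds$fold))
      if (!is.null(strat$target)) {
        eval_folds <- unique(folds$fold[subpop == strat$target])
      }
      for (fd in eval_folds) {
        vp <- folds$fold == fd
        X_tp <- inc$X[!vp, , drop = FALSE]
        inc_fold <- inc
        if (markers_per_fold && is.null(scn$matrix_id)) {
          inc_fold <- build_incidence_matrix(geno[!vp, , drop = FALSE],
                                             scn$maf, scn$ld, map = map)
          X_tp <- inc_fold$X
        }
        r <- tryCatch({
          fit <- fit_method(scn$method, X_tp, y_all[!vp], mcmc = mcmc,
                            seed = derive_seed(seed, paste0(key0, rep_i, fd)))
          gebv <- predict_gebv(fit, geno[vp, inc_fold$loci$locus,
                                         drop = FALSE])
          suppressWarnings(cor(gebv, y_all[vp]))
        }, error = function(e) {
          message(sprintf("scenario %s fold %d failed: %s", key0, fd,
                          conditionMessage(e)))
          NA_real_
        })
        rows[[length(rows) + 1]] <- tibble::tibble(
          scenario = scn$scenario, trait = scn$trait, method = scn$method,
          maf = scn$maf %||% NA_real_, ld = scn$ld %||% NA_real_,
          matrix_id = as.character(scn$matrix_id %||% NA_character_),
          k = scn$k, strategy = scn$strategy, replicate = rep_i, fold = fd,
          n_vp = sum(vp), r = r)
      }
    }
    records[[si]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(records)
  res$z <- ifelse(is.na(res$r), NA_real_, fisher_z(res$r))
  class(res) <- c("gs_accuracy", class(res))
  res
}

#' Average accuracy per scenario
#'
#' @param records A `gs_accuracy` tibble.
#' @return Tibble with one row per scenario: mean accuracy (AA), its SD and
#'   the number of validation tests.
#' @export
average_accuracy <- function(records) {
  records %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("scenario", "trait", "method", "maf", "ld", "matrix_id", "k",
        "strategy")))) %>%
    dplyr::summarise(AA = mean(.data$r, na.rm = TRUE),
                     sd = sd(.data$r, na.rm = TRUE),
                     n_tests = sum(!is.na(.data$r)), .groups = "drop")
}

anova_factors <- function(records) {
  fac <- c("trait", "method", "maf", "ld", "k")
  fac <- fac[vapply(fac, function(f)
    f %in% names(records) && length(unique(records[[f]])) > 1, logical(1))]
  if (!"maf" %in% fac && "matrix_id" %in% names(records) &&
      length(unique(records$matrix_id)) > 1) fac <- c(fac, "matrix_id")
  if (length(unique(records$strategy)) > 1) fac <- c(fac, "strategy")
  fac
}

#' ANOVA of cross-validation accuracy
#'
#' Fixed-effects least squares on the Fisher-z accuracies with sum-to-zero
#' coding and Type III tests. Three nested models: model 1 treats the
#' scenario as a single factor (pooled dispersion per scenario); model 2 has
#' the factor main effects only; model 3 adds all first-order interactions.
#' Each term's F uses its own model's mean squared error.
#'
#' @param records A `gs_accuracy` tibble (or any tibble with a `z` column and
#'   the factor columns).
#' @param model 1, 2 or 3.
#' @param factors Factor columns for models 2-3; defaults to those varying in
#'   the records.
#' @return Object of class `gs_anova`: list with `model`, `fit_stats`
#'   (tibble: df, ss, ms, f, p for Model/Error/Total plus R2, CV%, root MSE),
#'   `effects` (per-term tibble), and the underlying `lm`.
#' @export
anova_accuracy <- function(records, model = 2, factors = NULL) {
  stopifnot(model %in% 1:3, "z" %in% names(records))
  dat <- dplyr::filter(records, !is.na(.data$z))
  factors <- factors %||% anova_factors(dat)
  if (model > 1 && length(factors) < 1) {
    abort("No varying factors found for models 2-3.")
  }
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  dat$scenario_f <- if (length(factors)) {
    do.call(interaction, c(unname(as.list(dat[factors])), list(drop = TRUE)))
  } else {
    factor(rep("s", nrow(dat)))
  }
  if (nlevels(dat$scenario_f) < 2) abort("Records span fewer than 2 scenarios.")
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  form <- switch(as.character(model),
    "1" = z ~ scenario_f,
    "2" = stats::reformulate(factors, response = "z"),
    "3" = stats::reformulate(
      c(factors, utils::combn(factors, 2, paste, collapse = ":")),
      response = "z"))
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(sprintf("Design is rank deficient; aliased terms: %s.",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  aov_tab <- if (model == 1) {
    a <- anova(fit)
    tibble::tibble(term = c("scenario_f"), df = a$Df[1], ss = a$`Sum Sq`[1])
  } else {
    a <- car::Anova(fit, type = 3)
    keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
    tibble::tibble(term = rownames(a)[keep], df = a$Df[keep],
                   ss = a$`Sum Sq`[keep])
  }
  n <- nrow(dat)
  rdf <- fit$df.residual
  sse <- sum(fit$residuals^2)
  mse <- sse / rdf
  sst <- sum((dat$z - mean(dat$z))^2)
  model_df <- n - 1 - rdf
  ssm <- sst - sse
  effects <- aov_tab %>%
    dplyr::mutate(ms = .data$ss / .data$df,
                  f = .data$ms / mse,
                  p = pf(.data$f, .data$df, rdf, lower.tail = FALSE))
  fit_stats <- tibble::tibble(
    source = c("Model", "Error", "Corrected Total"),
    df = c(model_df, rdf, n - 1),
    ss = c(ssm, sse, sst),
    ms = c(ssm / model_df, mse, NA),
    f = c((ssm / model_df) / mse, NA, NA),
    p = c(pf((ssm / model_df) / mse, model_df, rdf, lower.tail = FALSE),
          NA, NA))
  structure(list(model = model, factors = factors, fit_stats = fit_stats,
                 effects = effects,
                 r_squared = 1 - sse / sst,
                 cv_pct = 100 * sqrt(mse) / mean(dat$z),
                 root_mse = sqrt(mse),
                 fit = fit, data = dat),
            class = "gs_anova")
}

#' @export
print.gs_anova <- function(x, ...) {
  cat(sprintf("<gs_anova> model %d (%s)\n", x$model,
              paste(x$factors, collapse = ", ")))
  print(dplyr::mutate(x$fit_stats, dplyr::across(dplyr::where(is.numeric),
                                                 ~ round(.x, 4))))
  cat(sprintf("R2 = %.3f, CV%% = %.2f, root MSE = %.4f\n",
              x$r_squared, x$cv_pct, x$root_mse))
  if (x$model > 1) {
    cat("effects:\n")
    print(dplyr::mutate(x$effects, dplyr::across(dplyr::where(is.numeric),
                                                 ~ signif(.x, 4))))
  }
  invisible(x)
}

#' @export
tidy.gs_anova <- function(x, ...) x$effects

#' @export
glance.gs_anova <- function(x, ...) {
  tibble::tibble(model = x$model, r_squared = x$r_squared,
                 cv_pct = x$cv_pct, root_mse = x$root_mse,
                 df_model = x$fit_stats$df[1], df_error = x$fit_stats$df[2])
}

# Compact letter display by insert-and-absorb: levels not significantly
# different share a letter.
cld_letters <- function(level_names, sig_pairs) {
  cols <- list(seq_along(level_names))
  if (nrow(sig_pairs)) {
    for (pr in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs$i[pr]; j <- sig_pairs$j[pr]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  ord <- order(vapply(cols, min, numeric(1)))
  cols <- cols[ord]
  letts <- vapply(seq_along(level_names), function(l) {
    paste0(letters[which(vapply(cols, function(cl) l %in% cl, logical(1)))],
           collapse = "")
  }, character(1))
  letts
}

#' Adjusted means (LSMeans) of accuracy with letter groups
#'
#' Balanced-weight adjusted means of Fisher z per level of a model factor,
#' computed on the fitted ANOVA model's reference grid, with pairwise
#' unadjusted t tests on the model mean squared error and a compact letter
#' display at `alpha`. Means are back-transformed to the correlation scale
#' for reporting.
#'
#' @param anova_res A `gs_anova` from [anova_accuracy()] (model 2 or 3).
#' @param factor Name of a model factor.
#' @param alpha Significance level for the letter display.
#' @return Tibble of class `gs_lsmeans`: `level`, `z_mean`, `se`, `r_mean`,
#'   `group` (levels sharing a letter are not significantly different),
#'   ordered by decreasing mean.
#' @export
lsmeans_accuracy <- function(anova_res, factor, alpha = 0.05) {
  stopifnot(inherits(anova_res, "gs_anova"))
  if (anova_res$model == 1) abort("LSMeans need model 2 or 3.")
  if (!factor %in% anova_res$factors) {
    abort(sprintf("'%s' is not a model factor.", factor))
  }
  dat <- anova_res$data
  grid <- do.call(tidyr::expand_grid,
                  setNames(lapply(anova_res$factors,
                                  function(f) levels(dat[[f]])),
                           anova_res$factors))
  for (f in anova_res$factors) grid[[f]] <- factor(grid[[f]],
                                                   levels(dat[[f]]))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  mm <- model.matrix(stats::delete.response(stats::terms(anova_res$fit)),
                     grid)
  lv <- levels(dat[[factor]])
  L <- t(vapply(lv, function(l) {
    colMeans(mm[grid[[factor]] == l, , drop = FALSE])
  }, numeric(ncol(mm))))
  est <- drop(L %*% coef(anova_res$fit))
  V <- vcov(anova_res$fit)
  se <- sqrt(diag(L %*% V %*% t(L)))
  rdf <- anova_res$fit$df.residual
  pairs <- utils::combn(seq_along(lv), 2)
  sig <- tibble::tibble(i = integer(), j = integer())
  for (cidx in seq_len(ncol(pairs))) {
    i <- pairs[1, cidx]; j <- pairs[2, cidx]
    dvec <- L[i, ] - L[j, ]
    sed <- sqrt(drop(dvec %*% V %*% dvec))
    tval <- (est[i] - est[j]) / sed
    if (2 * pt(abs(tval), rdf, lower.tail = FALSE) < alpha) {
      sig <- dplyr::bind_rows(sig, tibble::tibble(i = i, j = j))
    }
  }
  ord <- order(est, decreasing = TRUE)
  # letters computed on the ordered levels so 'a' is the top group
  remap <- match(seq_along(lv), ord)
  sig_ord <- dplyr::mutate(sig, i = remap[.data$i], j = remap[.data$j])
  letts <- cld_letters(lv[ord], sig_ord)
  res <- tibble::tibble(factor = factor, level = lv[ord],
                        z_mean = unname(est[ord]), se = unname(se[ord]),
                        r_mean = unname(inv_fisher_z(est[ord])),
                        group = letts)
  class(res) <- c("gs_lsmeans", class(res))
  res
}
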