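#' Fit the alpha-lattice mixed model for one trait
#'
#' REML fit of `Y_ijk = mu + g_i + R_j + b_k(j) + e_ijk`: genotype `g_i`
#' random, replicate `R_j` fixed, block-within-replicate `b_k(j)` random.
#' Returns variance components and the genotype BLUPs used as the response of
#' the genomic prediction models.
#'
#' @param trial Plot-level tibble with columns `line`, `trait`, `replicate`,
#'   `block`, `value` (see [simulate_field_trial()]).
#' @param trait Trait to analyse; may be omitted when the trial holds a single
#'   trait.
#' @return An object of class `gs_lattice_fit`: list with `trait`, `vc`
#'   (tibble of variance components), `blups` (tibble line, blup), `fixef`,
#'   `h2` (narrow-sense, plot basis), `converged`, `fit` (the underlying
#'   `lmerMod`).
#' @export
fit_lattice_model <- function(trial, trait = NULL) {
  stopifnot(is.data.frame(trial),
            all(c("line", "replicate", "block", "value") %in% names(trial)))
  if (!is.null(trait)) {
    trial <- dplyr::filter(trial, .data$trait == !!trait)
  } else if ("trait" %in% names(trial)) {
    trs <- unique(trial$trait)
    if (length(trs) > 1) {
      abort("Multiple traits present; supply `trait`.")
    }
    trait <- trs
  }
  if (nrow(trial) == 0) abort("No records for the requested trait.")
  if (length(unique(trial$replicate)) < 2) {
    abort("The lattice model needs at least two replicates.")
  }
  dat <- dplyr::mutate(trial,
                       line = factor(.data$line),
                       replicate = factor(.data$replicate),
                       block = factor(paste(.data$replicate, .data$block,
                                            sep = ":")))
  fit <- suppressMessages(lme4::lmer(
    value ~ replicate + (1 | line) + (1 | block),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc_raw <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vc_raw$vcov[vc_raw$grp == g]
    if (length(v)) v else 0
  }
  s2g <- get_vc("line")
  s2b <- get_vc("block")
  s2e <- get_vc("Residual")
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  re <- lme4::ranef(fit)$line
  blups <- tibble::tibble(line = rownames(re), blup = re[["(Intercept)"]])
  # shrinkage factor relative to the line-mean deviation (balanced case)
  lm_dev <- dat %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(m = mean(.data$value), .groups = "drop") %>%
    dplyr::mutate(dev = .data$m - mean(.data$m))
  blups <- dplyr::left_join(blups,
                            dplyr::select(lm_dev, "line", line_mean_dev = "dev"),
                            by = "line")
  structure(list(
    trait = trait,
    vc = tibble::tibble(component = c("genotype", "block", "residual"),
                        variance = c(s2g, s2b, s2e)),
    blups = blups,
    fixef = lme4::fixef(fit),
    h2 = if (s2g + s2e > 0) s2g / (s2g + s2e) else NA_real_,
    converged = conv,
    fit = fit), class = "gs_lattice_fit")
}

#' @export
print.gs_lattice_fit <- function(x, ...) {
  cat(sprintf("<gs_lattice_fit> trait %s (%sconverged)\n",
              x$trait %||% "?", if (x$converged) "" else "NOT "))
  v <- setNames(x$vc$variance, x$vc$component)
  cat(sprintf("  s2_g = %.4g, s2_b = %.4g, s2_e = %.4g, h2 = %.3f\n",
              v["genotype"], v["block"], v["residual"], x$h2))
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = s2_g / (s2_g + s2_e)` on the plot basis, assuming purely additive
#' genetic variance among the selfed families. Block variance does not enter
#' the denominator.
#'
#' @param vc A `gs_lattice_fit`, or a tibble/list with genotype and residual
#'   variances (named `genotype` / `residual` or `sigma2_g` / `sigma2_e`).
#' @return Heritability in `[0, 1]`; `NA` (with a warning) when both
#'   variances are zero.
#' @export
narrow_sense_h2 <- function(vc) {
  if (inherits(vc, "gs_lattice_fit")) {
    v <- setNames(vc$vc$variance, vc$vc$component)
    s2g <- v[["genotype"]]; s2e <- v[["residual"]]
  } else if (is.data.frame(vc)) {
    v <- setNames(vc$variance, vc$component)
    s2g <- v[["genotype"]]; s2e <- v[["residual"]]
  } else {
    s2g <- vc$sigma2_g %||% vc[["genotype"]]
    s2e <- vc$sigma2_e %||% vc[["residual"]]
  }
  if (s2g < 0 || s2e < 0) abort("Variances must be >= 0.")
  if (s2g + s2e == 0) {
    warn("Both variance components are zero; heritability undefined.")
    return(NA_real_)
  }
  s2g / (s2g + s2e)
}

#' Fit the lattice model for every trait and assemble the BLUP table
#'
#' @param trial Plot-level tibble covering one or more traits.
#' @return A list of class `gs_blup_table`: `fits` (named list of
#'   `gs_lattice_fit`), `blups` (wide tibble line x trait), `h2` (named
#'   numeric).
#' @export
fit_all_traits <- function(trial) {
  traits <- unique(trial$trait)
  fits <- lapply(traits, function(tr) fit_lattice_model(trial, trait = tr))
  names(fits) <- traits
  wide <- purrr::imap(fits, function(f, tr) {
    setNames(f$blups[, c("line", "blup")], c("line", tr))
  }) %>% purrr::reduce(dplyr::left_join, by = "line")
  structure(list(fits = fits, blups = tibble::as_tibble(wide),
                 h2 = vapply(fits, narrow_sense_h2, numeric(1))),
            class = "gs_blup_table")
}

#' @export
print.gs_blup_table <- function(x, ...) {
  cat(sprintf("<gs_blup_table> %d lines x %d traits\n",
              nrow(x$blups), length(x$fits)))
  cat("  h2:", paste(sprintf("%s = %.3f", names(x$h2), x$h2),
                     collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.gs_lattice_fit <- function(x, ...) {
  dplyr::mutate(x$vc, trait = x$trait, .before = 1)
}

#' @export
glance.gs_lattice_fit <- function(x, ...) {
  v <- setNames(x$vc$variance, x$vc$component)
  tibble::tibble(trait = x$trait, sigma2_g = v[["genotype"]],
                 sigma2_b = v[["block"]], sigma2_e = v[["residual"]],
                 h2 = x$h2, converged = x$converged,
                 n_lines = nrow(x$blups))
}
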