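# ggplot2 views of the main result types.

#' Histogram of minor allele frequencies
#'
#' @param stats A `gs_allele_stats` tibble.
#' @param binwidth Histogram bin width on the MAF scale.
#' @return A ggplot.
#' @export
plot_maf <- function(stats, binwidth = 0.025) {
  stopifnot(is.data.frame(stats), "maf" %in% names(stats))
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$maf)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "minor allele frequency", y = "loci") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_ld_profile <- function(object, ...) {
  dat <- dplyr::filter(object$pooled, !is.na(.data$mean_r2))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid_kb,
                                         y = .data$mean_r2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
  if (!is.na(object$half_decay_kb)) {
    p <- p + ggplot2::geom_vline(xintercept = object$half_decay_kb,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' @export
autoplot.gs_accuracy <- function(object, x = "method", ...) {
  stopifnot(x %in% names(object))
  dat <- dplyr::filter(object, !is.na(.data$r))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data[[x]]), y = .data$r)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.5) +
    ggplot2::labs(x = x, y = "GEBV accuracy (r)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_lsmeans <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       level = factor(.data$level, levels = .data$level))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$r_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$group),
                       vjust = -0.4, size = 3.5) +
    ggplot2::labs(x = unique(dat$factor), y = "adjusted mean accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gs_lattice_fit <- function(object, ...) {
  ggplot2::ggplot(object$blups,
                  ggplot2::aes(x = .data$line_mean_dev, y = .data$blup)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = "dashed") +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = "line-mean deviation", y = "genotype BLUP",
                  title = sprintf("BLUP shrinkage (%s)", object$trait)) +
    ggplot2::theme_minimal()
}
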