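#' Per-locus allele statistics
#'
#' Computes, for each locus, the alternate-allele frequency `p` (mean dosage /
#' 2), the minor allele frequency `maf = min(p, 1 - p)`, the observed
#' heterozygote fraction `ho` (fraction of dosage-1 calls) and the expected
#' heterozygote fraction `he = 2 p (1 - p) / 4`. The divisor 4 in `he` reflects
#' the two selfing generations separating the genotyped lines from the
#' random-mated S0 generation, so `he <= 0.125`.
#'
#' @param geno Dosage matrix (lines x loci, values in \{0, 1, 2\}) or a
#'   `gs_population`.
#' @param map Optional locus map tibble (`locus`, `chrom`, `pos_kb`, `pos_cM`)
#'   joined onto the result; taken from the population when available.
#' @return A tibble with one row per locus: `locus`, (`chrom`, `pos_kb`,
#'   `pos_cM` when a map is known), `p`, `maf`, `ho`, `he`.
#' @export
#' @examples
#' g <- matrix(c(0, 1, 2, 1), ncol = 1, dimnames = list(NULL, "L1"))
#' allele_stats(g) # p = 0.5, maf = 0.5, ho = 0.5, he = 0.125
allele_stats <- function(geno, map = NULL) {
  if (inherits(geno, "gs_population")) {
    if (is.null(map)) map <- geno$map
    geno <- dosage(geno)
  }
  if (!is.matrix(geno) || ncol(geno) == 0 || nrow(geno) == 0) {
    abort("`geno` must be a non-empty lines x loci dosage matrix.")
  }
  if (!all(geno %in% c(0, 1, 2))) abort("Dosages must be in {0, 1, 2}.")
  p <- unname(colMeans(geno)) / 2
  res <- tibble::tibble(
    locus = colnames(geno) %||% sprintf("L%d", seq_len(ncol(geno))),
    p = p,
    maf = pmin(p, 1 - p),
    ho = unname(colMeans(geno == 1)),
    he = 2 * p * (1 - p) / 4
  )
  if (!is.null(map)) {
    res <- dplyr::left_join(res,
                            dplyr::select(map, "locus", "chrom", "pos_kb",
                                          "pos_cM"),
                            by = "locus") %>%
      dplyr::select("locus", "chrom", "pos_kb", "pos_cM", dplyr::everything())
  }
  class(res) <- c("gs_allele_stats", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise linkage disequilibrium within chromosomes
#'
#' Computes r2 between all pairs of markers on the same chromosome as the
#' squared Pearson correlation of allele dosages (the composite measure; with
#' near-inbred lines it closely approximates the haplotype-based r2 of Hill and
#' Robertson). Monomorphic loci are skipped.
#'
#' @param geno Dosage matrix or `gs_population`.
#' @param map Locus map; required when `geno` is a matrix.
#' @param chroms Optional subset of chromosomes.
#' @param max_pairs_per_chrom Optional cap on pairs per chromosome; when the
#'   full pair count exceeds it, a seeded uniform subsample is taken.
#' @param seed Seed for the optional subsampling.
#' @return A tibble of class `gs_ld`: `locus_a`, `locus_b`, `chrom`,
#'   `dist_kb`, `r2`.
#' @export
pairwise_ld <- function(geno, map = NULL, chroms = NULL,
                        max_pairs_per_chrom = Inf, seed = 1L) {
  if (inherits(geno, "gs_population")) {
    if (is.null(map)) map <- geno$map
    geno <- dosage(geno)
  }
  if (is.null(map)) abort("A locus `map` is required.")
  keep_chroms <- chroms %||% unique(map$chrom)
  out <- vector("list", length(keep_chroms))
  set.seed(seed)
  for (i in seq_along(keep_chroms)) {
    ch <- keep_chroms[i]
    mi <- map[map$chrom == ch, ]
    idx <- match(mi$locus, colnames(geno))
    g <- geno[, idx, drop = FALSE]
    poly <- apply(g, 2, function(x) var(x) > 0)
    if (sum(poly) < 2) next
    g <- g[, poly, drop = FALSE]
    mi <- mi[poly, ]
    cc <- suppressWarnings(cor(g))^2
    ut <- which(upper.tri(cc), arr.ind = TRUE)
    if (nrow(ut) > max_pairs_per_chrom) {
      ut <- ut[sample.int(nrow(ut), max_pairs_per_chrom), , drop = FALSE]
    }
    out[[i]] <- tibble::tibble(
      locus_a = mi$locus[ut[, 1]],
      locus_b = mi$locus[ut[, 2]],
      chrom = ch,
      dist_kb = abs(mi$pos_kb[ut[, 2]] - mi$pos_kb[ut[, 1]]),
      r2 = cc[ut]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) abort("Fewer than two polymorphic loci in scope.")
  class(res) <- c("gs_ld", class(res))
  res
}

#' Distance-binned LD decay profile
#'
#' Averages r2 within physical-distance bins, pooled and per chromosome, and
#' reports the half-decay distance: the midpoint of the first bin whose pooled
#' mean r2 falls to half the value of the first (0-25 kb by default) bin.
#'
#' @param ld A `gs_ld` tibble from [pairwise_ld()].
#' @param breaks Increasing numeric vector of bin edges in kb.
#' @return A list of class `gs_ld_profile` with `pooled` (tibble: bin,
#'   mid_kb, n_pairs, mean_r2), `by_chrom`, and `half_decay_kb` (NA when the
#'   profile never halves within the binned range).
#' @export
ld_decay_profile <- function(ld,
                             breaks = c(0, 25, 50, 100, 200, 300, 400, 500,
                                        650, 800, 1000, 1500, 2000, 3000)) {
  stopifnot(inherits(ld, "gs_ld"))
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing.")
  }
  bin_it <- function(d) cut(d, breaks = breaks, include.lowest = TRUE)
  pooled <- ld %>%
    dplyr::filter(.data$dist_kb <= max(breaks)) %>%
    dplyr::mutate(bin = bin_it(.data$dist_kb)) %>%
    dplyr::group_by(.data$bin, .drop = FALSE) %>%
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2),
                     .groups = "drop") %>%
    dplyr::mutate(mid_kb = (breaks[-length(breaks)] + breaks[-1]) / 2,
                  mean_r2 = ifelse(.data$n_pairs == 0, NA_real_,
                                   .data$mean_r2))
  by_chrom <- ld %>%
    dplyr::filter(.data$dist_kb <= max(breaks)) %>%
    dplyr::mutate(bin = bin_it(.data$dist_kb)) %>%
    dplyr::group_by(.data$chrom, .data$bin) %>%
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2),
                     .groups = "drop")
  r2_0 <- pooled$mean_r2[1]
  half <- NA_real_
  if (!is.na(r2_0)) {
    hit <- which(!is.na(pooled$mean_r2) & pooled$mean_r2 <= r2_0 / 2)
    hit <- hit[hit > 1]
    if (length(hit)) half <- pooled$mid_kb[min(hit)]
  }
  structure(list(pooled = pooled, by_chrom = by_chrom,
                 half_decay_kb = half),
            class = "gs_ld_profile")
}

#' @export
print.gs_ld_profile <- function(x, ...) {
  cat("<gs_ld_profile>\n")
  print(x$pooled)
  cat(sprintf("half-decay distance: %s kb\n",
              format(x$half_decay_kb)))
  invisible(x)
}

# Weir-Cockerham per-locus variance components a, b, c for two subpopulations.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham FST between subpopulations
#'
#' Computes the Weir-Cockerham theta estimator per locus and combines loci by
#' the ratio-of-sums multilocus estimate for every subpopulation pair. Loci
#' monomorphic across both members of a pair contribute nothing. Negative
#' multilocus estimates are reported as-is unless `truncate = TRUE`.
#'
#' @param geno Dosage matrix or `gs_population`.
#' @param subpop Character/factor of subpopulation labels, one per line
#'   (taken from the population when omitted).
#' @param truncate Truncate negative multilocus estimates at 0.
#' @return A list of class `gs_fst`: `theta` (symmetric matrix, diagonal 0)
#'   and `pairs` (tibble pop_a, pop_b, theta, n_loci).
#' @export
fst_pairwise <- function(geno, subpop = NULL, truncate = FALSE) {
  if (inherits(geno, "gs_population")) {
    if (is.null(subpop)) subpop <- geno$subpop
    geno <- dosage(geno)
  }
  if (is.null(subpop)) abort("`subpop` labels are required.")
  subpop <- as.character(subpop)
  pops <- unique(subpop)
  if (length(pops) < 2) abort("Need at least two subpopulations.")
  if (any(table(subpop) < 2)) abort("Each subpopulation needs n >= 2.")
  stats <- lapply(pops, function(sp) {
    g <- geno[subpop == sp, , drop = FALSE]
    list(n = nrow(g), p = colMeans(g) / 2, h = colMeans(g == 1))
  })
  names(stats) <- pops
  theta <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  rows <- list()
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq((i + 1), length(pops))) {
      si <- stats[[i]]; sj <- stats[[j]]
      comp <- wc_components(si$n, sj$n, si$p, sj$p, si$h, sj$h)
      keep <- (si$p + sj$p) > 0 & (si$p + sj$p) < 2
      th <- sum(comp$a[keep]) /
        sum(comp$a[keep] + comp$b[keep] + comp$c[keep])
      if (truncate) th <- max(th, 0)
      theta[i, j] <- theta[j, i] <- th
      rows[[length(rows) + 1]] <- tibble::tibble(
        pop_a = pops[i], pop_b = pops[j], theta = th, n_loci = sum(keep))
    }
  }
  structure(list(theta = theta, pairs = dplyr::bind_rows(rows)),
            class = "gs_fst")
}

#' @export
print.gs_fst <- function(x, ...) {
  cat("<gs_fst> pairwise Weir-Cockerham theta\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Effective population size from inter-chromosomal LD
#'
#' Implements the linkage-disequilibrium method of Waples and Do restricted to
#' pairs of loci on different chromosomes (so physical linkage cannot inflate
#' the estimate). After dropping loci below the MAF floor, the mean squared
#' dosage correlation is corrected for finite sample size with the Waples
#' (2006) random-mating constants for S >= 30, `E_S = 1/S + 3.19/S^2`, and Ne
#' is recovered from the drift component `r2' = r2 - E_S` by the quadratic
#' inversion `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`. A non-positive
#' `r2'` is flagged as an infinite estimate. The parametric CI treats the pair
#' count as the chi-square degrees of freedom; with correlated pairs it is
#' optimistic and is reported as indicative only.
#'
#' @param geno Dosage matrix or `gs_population`.
#' @param map Locus map (needed for chromosome assignment).
#' @param maf_floor Minimum MAF for a locus to enter (default 0.05).
#' @param max_pairs Cap on the number of inter-chromosomal pairs (seeded
#'   subsample above the cap).
#' @param seed Seed for the subsample.
#' @return A list of class `gs_ne`: `ne` (point estimate, `Inf` when flagged),
#'   `r2_mean`, `r2_drift`, `n_pairs`, `S`, `ci` (length-2 numeric).
#' @export
estimate_ne_ld <- function(geno, map = NULL, maf_floor = 0.05,
                           max_pairs = 50000, seed = 1L) {
  if (inherits(geno, "gs_population")) {
    if (is.null(map)) map <- geno$map
    geno <- dosage(geno)
  }
  if (is.null(map)) abort("A locus `map` is required.")
  S <- nrow(geno)
  if (S < 30) {
    abort("LD-based Ne supports S >= 30 only (Waples 2006 constants).")
  }
  p <- colMeans(geno) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_floor
  chrom <- map$chrom[match(colnames(geno), map$locus)]
  g <- geno[, keep, drop = FALSE]
  chrom <- chrom[keep]
  if (length(unique(chrom)) < 2) {
    abort("Need loci on at least two chromosomes for inter-chromosomal pairs.")
  }
  gs <- scale(g)
  # enumerate inter-chromosomal pairs (subsampled above the cap)
  m <- ncol(gs)
  set.seed(seed)
  total_pairs <- sum(outer(table(chrom), table(chrom))[
    upper.tri(diag(length(unique(chrom))))])
  if (total_pairs > max_pairs) {
    ii <- sample.int(m, 4 * max_pairs, replace = TRUE)
    jj <- sample.int(m, 4 * max_pairs, replace = TRUE)
    ok <- chrom[ii] != chrom[jj]
    ii <- ii[ok][seq_len(max_pairs)]
    jj <- jj[ok][seq_len(max_pairs)]
    r2 <- colMeans(gs[, ii, drop = FALSE] * gs[, jj, drop = FALSE])^2 *
      (S / (S - 1))^2
    n_pairs <- max_pairs
  } else {
    cc <- crossprod(gs) / (S - 1)
    sel <- outer(chrom, chrom, `!=`) & upper.tri(cc)
    r2 <- cc[sel]^2
    n_pairs <- length(r2)
  }
  r2_mean <- mean(r2)
  es <- 1 / S + 3.19 / S^2
  invert <- function(r2d) {
    if (is.na(r2d) || r2d <= 0) return(Inf)
    disc <- max(1 / 9 - 2.76 * r2d, 0)
    (1 / 3 + sqrt(disc)) / (2 * r2d)
  }
  r2_drift <- r2_mean - es
  ci_r2 <- r2_mean * n_pairs / qchisq(c(0.975, 0.025), df = n_pairs)
  structure(list(ne = invert(r2_drift), r2_mean = r2_mean,
                 r2_drift = r2_drift, n_pairs = n_pairs, S = S,
                 ci = sort(vapply(ci_r2 - es, invert, numeric(1)))),
            class = "gs_ne")
}

#' @export
print.gs_ne <- function(x, ...) {
  cat(sprintf(
    "<gs_ne> Ne = %s (S = %d, %d inter-chromosomal pairs, r2' = %.5f)\n",
    format(round(x$ne, 1)), x$S, x$n_pairs, x$r2_drift))
  cat(sprintf("  parametric CI: [%s, %s]\n",
              format(round(x$ci[1], 1)), format(round(x$ci[2], 1))))
  invisible(x)
}

#' Marker-based kinship matrix
#'
#' Kinship between lines i and j is defined from the mismatch distance
#' `d_ij = (# loci with differing dosage) / M`, converted to a similarity
#' `s_ij = 2 (1 - d_ij)` in `[0, 2]` with `s_ii = 2`.
#'
#' @param geno Dosage matrix or `gs_population`; no missing data allowed.
#' @return A symmetric similarity matrix of class `gs_kinship` with the
#'   distance matrix attached as attribute `"distance"`.
#' @export
kinship <- function(geno) {
  if (inherits(geno, "gs_population")) geno <- dosage(geno)
  if (!is.matrix(geno) || ncol(geno) == 0) {
    abort("`geno` must have at least one locus.")
  }
  if (anyNA(geno)) abort("Kinship requires complete dosage data.")
  m <- ncol(geno)
  matches <- matrix(0, nrow(geno), nrow(geno))
  for (g in 0:2) {
    ind <- (geno == g) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- (m - matches) / m
  s <- 2 * (1 - d)
  dimnames(s) <- list(rownames(geno), rownames(geno))
  dimnames(d) <- dimnames(s)
  structure(s, distance = d, class = c("gs_kinship", "matrix", "array"))
}
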