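#' Filter loci by minor allele frequency
#'
#' Retains the loci whose MAF is greater than or equal to the threshold
#' (inclusive), preserving the original locus order. Monomorphic loci
#' (MAF = 0) are never retained.
#'
#' @param stats A `gs_allele_stats` tibble from [allele_stats()].
#' @param threshold MAF threshold as a proportion in `[0, 0.5]` (e.g. 0.05
#'   for the "MAF >= 5%" rule).
#' @return Integer vector of retained locus indices (positions in `stats`).
#' @export
filter_by_maf <- function(stats, threshold) {
  stopifnot(is.data.frame(stats), "maf" %in% names(stats))
  if (threshold < 0 || threshold > 0.5) {
    abort("`threshold` must lie in [0, 0.5].")
  }
  which(stats$maf >= threshold & stats$maf > 0)
}

#' Prune loci by pairwise LD within chromosomes
#'
#' Greedy sweep in map order, per chromosome: a candidate locus is retained iff
#' its r2 with every already-retained locus on the same chromosome is at most
#' `r2_max`. The first-seen locus always wins, which makes the sweep
#' deterministic and idempotent. `r2_max = 1` retains every candidate
#' (r2 = 1 passes the inclusive threshold).
#'
#' @param geno Dosage matrix or `gs_population`.
#' @param map Locus map; required when `geno` is a matrix.
#' @param candidates Integer vector of candidate locus indices (columns of
#'   `geno`), typically MAF-filtered.
#' @param r2_max LD threshold in `(0, 1]`.
#' @return Integer vector of retained locus indices (subset of `candidates`,
#'   original order).
#' @export
prune_by_ld <- function(geno, map = NULL, candidates, r2_max) {
  if (inherits(geno, "gs_population")) {
    if (is.null(map)) map <- geno$map
    geno <- dosage(geno)
  }
  if (is.null(map)) abort("A locus `map` is required.")
  if (r2_max <= 0 || r2_max > 1) abort("`r2_max` must lie in (0, 1].")
  if (r2_max >= 1) return(candidates)
  chrom <- map$chrom[match(colnames(geno), map$locus)]
  pos <- map$pos_kb[match(colnames(geno), map$locus)]
  kept <- integer(0)
  for (ch in unique(chrom[candidates])) {
    cand <- candidates[chrom[candidates] == ch]
    cand <- cand[order(pos[cand])]
    z <- scale(geno[, cand, drop = FALSE])
    n <- nrow(z)
    kept_local <- integer(0)
    for (k in seq_along(cand)) {
      if (length(kept_local) == 0) {
        kept_local <- k
        next
      }
      r <- crossprod(z[, kept_local, drop = FALSE], z[, k]) / (n - 1)
      if (all(r^2 <= r2_max + 1e-12)) kept_local <- c(kept_local, k)
    }
    kept <- c(kept, cand[kept_local])
  }
  sort(kept)
}

#' Build a marker incidence matrix
#'
#' Composes MAF filtering, per-chromosome LD pruning and column centering into
#' the design matrix X entering the whole-genome regressions. Columns are
#' centered on twice the allele frequency (the column mean); variance
#' standardization is off by default and available via `standardize`.
#'
#' @param population A `gs_population`, or a dosage matrix with `map` given.
#' @param maf_threshold MAF threshold (proportion).
#' @param ld_threshold Pairwise r2 threshold in `(0, 1]`.
#' @param map Locus map when `population` is a matrix.
#' @param standardize Also scale columns to unit variance.
#' @return An object of class `gs_incidence`: list with `X` (centered lines x
#'   markers matrix), `loci` (tibble locus, chrom, pos_kb, maf), `centers`,
#'   `scales`, and the provenance fields `maf_threshold`, `ld_threshold`.
#' @export
build_incidence_matrix <- function(population, maf_threshold, ld_threshold,
                                   map = NULL, standardize = FALSE) {
  if (inherits(population, "gs_population")) {
    map <- population$map
    geno <- dosage(population)
  } else {
    geno <- population
    if (is.null(map)) abort("A locus `map` is required.")
  }
  stats <- allele_stats(geno, map = map)
  idx <- filter_by_maf(stats, maf_threshold)
  idx <- prune_by_ld(geno, map, idx, ld_threshold)
  if (length(idx) == 0) {
    abort(sprintf(
      "Empty marker selection (MAF >= %.4g, r2 <= %.3g retained no locus).",
      maf_threshold, ld_threshold))
  }
  X <- geno[, idx, drop = FALSE]
  centers <- colMeans(X)
  X <- sweep(X, 2, centers)
  scales <- rep(1, ncol(X))
  if (standardize) {
    scales <- apply(X, 2, sd)
    X <- sweep(X, 2, scales, "/")
  }
  structure(list(
    X = X,
    loci = dplyr::select(stats[idx, ], "locus", dplyr::any_of(c("chrom", "pos_kb")),
                         "maf"),
    centers = centers, scales = scales,
    maf_threshold = maf_threshold, ld_threshold = ld_threshold,
    provenance = "maf_ld"), class = "gs_incidence")
}

#' @export
print.gs_incidence <- function(x, ...) {
  prov <- if (identical(x$provenance, "random")) {
    sprintf("random draw (size %d, replicate %d, seed %d)",
            ncol(x$X), x$replicate %||% NA_integer_, x$seed %||% NA_integer_)
  } else {
    sprintf("MAF >= %.4g, r2 <= %.3g", x$maf_threshold, x$ld_threshold)
  }
  cat(sprintf("<gs_incidence> %d lines x %d markers [%s]%s\n",
              nrow(x$X), ncol(x$X), prov,
              if (any(x$scales != 1)) ", standardized" else ""))
  invisible(x)
}

#' Randomly sampled marker sets
#'
#' For each requested size, draws `replicates` independent uniform marker
#' subsets without replacement and returns the corresponding centered
#' incidence matrices. Per-draw seeds are derived deterministically from the
#' master seed, so the full list is reproducible and any single draw can be
#' regenerated in isolation.
#'
#' @param population A `gs_population` (or dosage matrix with `map`).
#' @param sizes Integer vector of set sizes (e.g. `seq(100, 7200, by = 100)`).
#' @param replicates Draws per size.
#' @param seed Master seed.
#' @param map Locus map when `population` is a matrix.
#' @return List of `gs_incidence` objects of length
#'   `length(sizes) * replicates`, ordered size-major.
#' @export
sample_random_sets <- function(population, sizes, replicates = 10, seed = 1L,
                               map = NULL) {
  if (inherits(population, "gs_population")) {
    map <- population$map
    geno <- dosage(population)
  } else {
    geno <- population
    if (is.null(map)) abort("A locus `map` is required.")
  }
  m <- ncol(geno)
  if (any(sizes > m)) {
    abort(sprintf("Requested size exceeds available loci (%d).", m))
  }
  if (any(sizes < 1)) abort("Sizes must be positive.")
  out <- vector("list", length(sizes) * replicates)
  k <- 0
  for (sz in sizes) {
    for (rep_i in seq_len(replicates)) {
      s <- derive_seed(seed, sprintf("random_set_%d_%d", sz, rep_i))
      set.seed(s)
      idx <- sort(sample.int(m, sz))
      X <- geno[, idx, drop = FALSE]
      centers <- colMeans(X)
      k <- k + 1
      out[[k]] <- structure(list(
        X = sweep(X, 2, centers),
        loci = tibble::tibble(locus = colnames(geno)[idx],
                              chrom = map$chrom[match(colnames(geno)[idx],
                                                      map$locus)],
                              maf = pmin(colMeans(X) / 2,
                                         1 - colMeans(X) / 2)),
        centers = centers, scales = rep(1, sz),
        maf_threshold = NA_real_, ld_threshold = NA_real_,
        size = sz, replicate = rep_i, seed = s,
        provenance = "random"), class = "gs_incidence")
    }
  }
  out
}

#' Marker-set manifest
#'
#' @param incidence A `gs_incidence`.
#' @return Tibble with one row per retained locus plus provenance columns.
#' @export
marker_manifest <- function(incidence) {
  stopifnot(inherits(incidence, "gs_incidence"))
  dplyr::mutate(incidence$loci,
                maf_threshold = incidence$maf_threshold,
                ld_threshold = incidence$ld_threshold,
                provenance = incidence$provenance)
}
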