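# Small, fast fixtures shared across test files. Everything is generated in
# code; nothing is read from disk.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_chrom = 3, loci_per_chrom = 60, chrom_length_kb = 2700,
    chrom_length_cM = 90,
    n_founders = 20, base_size = 30, n_cycles = 4,
    founder_weight_decay = 0.5,
    subpops = tibble::tibble(name = c("A", "B"),
                             n_lines = c(24L, 26L),
                             pool_size = c(12L, 14L),
                             drift_generations = 2L),
    migration_rate = 0.05, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

tiny_population <- function(seed = 1L, ...) {
  simulate_population(tiny_config(seed = seed, ...))
}

# medium panel: 4 subpops, 130 lines, 6 x 120 loci - used where structure or
# prediction accuracy matters but full scale would be slow
medium_config <- function(seed = 1L, ...) {
  args <- list(
    n_chrom = 6, loci_per_chrom = 120, chrom_length_kb = 15000,
    chrom_length_cM = 150,
    n_founders = 40, base_size = 60, n_cycles = 6,
    founder_weight_decay = 0.7,
    subpops = tibble::tibble(name = c("P1", "P2", "P3", "P4"),
                             n_lines = c(33L, 31L, 31L, 35L),
                             pool_size = c(16L, 14L, 24L, 26L),
                             drift_generations = 2L),
    migration_rate = 0.08, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# evenly spaced map for hand-built dosage matrices
toy_map <- function(m, n_chrom = 1, spacing_kb = 50) {
  per <- m %/% n_chrom
  stopifnot(per * n_chrom == m)
  dplyr::bind_rows(lapply(seq_len(n_chrom), function(ch) {
    tibble::tibble(locus = sprintf("c%02d_%04d", ch, seq_len(per)),
                   chrom = ch,
                   pos_kb = seq_len(per) * spacing_kb,
                   pos_cM = seq_len(per) * spacing_kb * 0.005)
  }))
}

# random dosage matrix with independent loci
random_geno <- function(n, m, p = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  g <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  colnames(g) <- toy_map(m)$locus
  g
}

# a minimal gs_population wrapper around explicit haplotypes (for tests that
# need full control over genotypes)
manual_population <- function(hapA, hapB, map, subpop = NULL) {
  n <- nrow(hapA)
  gsrice:::new_population(
    hapA, hapB, map,
    line_id = sprintf("L%03d", seq_len(n)),
    subpop = subpop %||% rep("A", n),
    generation = "S0")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
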