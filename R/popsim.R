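#' Simulation configuration for a recurrent-selection synthetic population
#'
#' Builds the parameter set for the forward-in-time simulator. The defaults
#' describe a rice-like synthetic population: 12 chromosomes of 150 cM
#' (18 Morgans in total) carrying ~8,340 SNPs at an average spacing of ~45 kb,
#' founded by 60 fully inbred accessions whose allele frequencies follow a
#' U-shaped symmetric beta law, recombined through many cycles of random
#' mating at small census size, split into four subpopulations that drift
#' apart under limited migration, and finally advanced by two generations of
#' single seed descent (S0 to S2).
#'
#' The default census sizes, cycle counts and migration rate are calibrated so
#' that the simulated population reproduces the genetic make-up of a real
#' recurrent-selection rice synthetic: mean minor allele frequency around 15%,
#' mean r2 near 0.6 for marker pairs closer than 25 kb, pairwise subpopulation
#' FST of 0.02-0.06, and subpopulation effective sizes of a few tens.
#'
#' @param n_founders Number of fully inbred founder accessions.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_cM,chrom_length_kb Genetic and physical length of each
#'   chromosome (all chromosomes equal).
#' @param loci_per_chrom SNP loci per chromosome; positions are uniform random
#'   along the chromosome so that marker spacing is irregular.
#' @param beta_shape Shape of the symmetric `Beta(beta_shape, beta_shape)`
#'   distribution of founder allele frequencies. Must be positive.
#' @param base_size Census size of the panmictic base population during the
#'   recombination cycles.
#' @param n_cycles Number of random-mating recombination cycles in the shared
#'   base phase.
#' @param founder_weight_decay Geometric decay rate of founder contributions
#'   to the base population: founder i enters with weight proportional to
#'   `(1 - rho)^(i-1)`. A positive value reflects the typical breeding
#'   history in which a handful of elite lines dominate the crossing scheme;
#'   it concentrates local haplotype diversity (high short-range LD) and
#'   produces the low-MAF tail of the U-shaped frequency spectrum. 0 gives
#'   equal contributions.
#' @param subpops Tibble with one row per subpopulation: `name`, `n_lines`
#'   (S0 lines extracted for the study), `pool_size` (census of parents during
#'   the subpopulation drift phase) and `drift_generations`.
#' @param migration_rate Probability that a parent of a subpopulation offspring
#'   is drawn from another subpopulation during the drift phase.
#' @param selfing_generations Generations of single seed descent after line
#'   extraction (2 corresponds to S0 -> S2).
#' @param seed Integer seed; every simulation function that consumes the
#'   config reseeds from it so runs are reproducible.
#'
#' @return An object of class `gs_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(loci_per_chrom = 40, n_chrom = 3)
#' cfg$n_founders
sim_config <- function(n_founders = 60,
                       n_chrom = 12,
                       chrom_length_cM = 150,
                       chrom_length_kb = 31100,
                       loci_per_chrom = 695,
                       beta_shape = 0.56,
                       base_size = 100,
                       n_cycles = 10,
                       founder_weight_decay = 0.775,
                       subpops = tibble::tibble(
                         name = c("P1", "P2", "P3", "P4"),
                         n_lines = c(86L, 83L, 82L, 92L),
                         pool_size = c(32L, 28L, 48L, 53L),
                         drift_generations = 3L
                       ),
                       migration_rate = 0.08,
                       selfing_generations = 2,
                       seed = 1L) {
  stopifnot(is.data.frame(subpops),
            all(c("name", "n_lines", "pool_size", "drift_generations")
                %in% names(subpops)))
  if (!is.numeric(beta_shape) || beta_shape <= 0) {
    abort("`beta_shape` must be a positive real (symmetric beta shape).")
  }
  if (n_founders < 1 || n_chrom < 1 || loci_per_chrom < 2) {
    abort("`n_founders`, `n_chrom` and `loci_per_chrom` must be positive.")
  }
  if (chrom_length_cM < 0 || chrom_length_kb <= 0) {
    abort("Chromosome lengths must be positive (genetic length may be 0).")
  }
  if (any(subpops$n_lines <= 1) || any(subpops$pool_size < 2)) {
    abort("Each subpopulation needs n_lines > 1 and pool_size >= 2.")
  }
  if (migration_rate < 0 || migration_rate > 1) {
    abort("`migration_rate` must lie in [0, 1].")
  }
  if (founder_weight_decay < 0 || founder_weight_decay >= 1) {
    abort("`founder_weight_decay` must lie in [0, 1).")
  }
  structure(list(
    n_founders = as.integer(n_founders),
    n_chrom = as.integer(n_chrom),
    chrom_length_cM = chrom_length_cM,
    chrom_length_kb = chrom_length_kb,
    loci_per_chrom = as.integer(loci_per_chrom),
    beta_shape = beta_shape,
    base_size = as.integer(base_size),
    n_cycles = as.integer(n_cycles),
    founder_weight_decay = founder_weight_decay,
    subpops = tibble::as_tibble(subpops),
    migration_rate = migration_rate,
    selfing_generations = as.integer(selfing_generations),
    seed = as.integer(seed)
  ), class = "gs_sim_config")
}

#' @export
print.gs_sim_config <- function(x, ...) {
  cat("<gs_sim_config>\n")
  cat(sprintf("  %d founders, %d chromosomes x %d loci (%.0f cM / %.0f kb each)\n",
              x$n_founders, x$n_chrom, x$loci_per_chrom,
              x$chrom_length_cM, x$chrom_length_kb))
  cat(sprintf("  base: census %d, %d cycles; %d subpops, migration %.2f\n",
              x$base_size, x$n_cycles, nrow(x$subpops), x$migration_rate))
  cat(sprintf("  founder freq ~ Beta(%.2f, %.2f); %d selfing generations\n",
              x$beta_shape, x$beta_shape, x$selfing_generations))
  invisible(x)
}

# ---- internal helpers --------------------------------------------------------

make_map <- function(config) {
  per_chrom <- lapply(seq_len(config$n_chrom), function(ch) {
    pos_kb <- sort(runif(config$loci_per_chrom, 0, config$chrom_length_kb))
    # collapse coincident positions (strictly increasing within chromosome)
    while (any(diff(pos_kb) <= 0)) {
      pos_kb <- sort(pos_kb + c(0, cumsum(diff(pos_kb) <= 0) * 1e-6))
    }
    tibble::tibble(
      locus = sprintf("c%02d_%04d", ch, seq_len(config$loci_per_chrom)),
      chrom = ch,
      pos_kb = pos_kb,
      pos_cM = pos_kb * config$chrom_length_cM / config$chrom_length_kb
    )
  })
  dplyr::bind_rows(per_chrom)
}

split_map <- function(map) {
  lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
    list(idx = idx, cm = map$pos_cM[idx], len = max(map$pos_cM[idx]))
  })
}

# One meiotic gamete from a parent's two haplotype rows. Crossover counts are
# Poisson(length_cM / 100) per chromosome, placed uniformly on the genetic map,
# with no interference; starting haplotype is random per chromosome.
meiose <- function(hA, hB, msplit) {
  out <- hA
  for (ms in msplit) {
    n_xo <- rpois(1L, ms$len / 100)
    start <- sample.int(2L, 1L) - 1L
    if (n_xo == 0L) {
      if (start == 1L) out[ms$idx] <- hB[ms$idx]
      next
    }
    xo <- sort(runif(n_xo, 0, ms$len))
    use_b <- (findInterval(ms$cm, xo) + start) %% 2L == 1L
    if (any(use_b)) out[ms$idx[use_b]] <- hB[ms$idx[use_b]]
  }
  out
}

# Random-mate one generation within a parent pool (rows of hapA/hapB),
# producing n_off offspring. Parents of each offspring are distinct.
mate_generation <- function(hapA, hapB, n_off, msplit) {
  n_par <- nrow(hapA)
  offA <- matrix(0L, n_off, ncol(hapA))
  offB <- offA
  for (i in seq_len(n_off)) {
    pr <- sample.int(n_par, 2L, replace = n_par < 2L)
    offA[i, ] <- meiose(hapA[pr[1L], ], hapB[pr[1L], ], msplit)
    offB[i, ] <- meiose(hapA[pr[2L], ], hapB[pr[2L], ], msplit)
  }
  list(A = offA, B = offB)
}

new_population <- function(hapA, hapB, map, line_id, subpop, generation,
                           tbv = list()) {
  dimnames(hapA) <- list(line_id, map$locus)
  dimnames(hapB) <- list(line_id, map$locus)
  structure(list(hapA = hapA, hapB = hapB, map = map,
                 line_id = line_id, subpop = subpop,
                 generation = generation, tbv = tbv),
            class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  cat(sprintf("<gs_population> %d lines x %d loci (%d chromosomes), generation %s\n",
              nrow(x$hapA), ncol(x$hapA), length(unique(x$map$chrom)),
              x$generation))
  tb <- table(x$subpop)
  cat("  subpopulations:",
      paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  if (length(x$tbv)) {
    cat("  traits with true breeding values:",
        paste(names(x$tbv), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Allele dosage matrix of a population
#'
#' @param population A `gs_population`.
#' @return Integer matrix (lines x loci) of alternate-allele dosages in
#'   \{0, 1, 2\}, with line and locus dimnames.
#' @export
dosage <- function(population) {
  stopifnot(inherits(population, "gs_population"))
  population$hapA + population$hapB
}

# ---- operations --------------------------------------------------------------

#' Simulate the founder haplotype pool
#'
#' Draws one allele frequency per locus from the symmetric beta law
#' `Beta(beta_shape, beta_shape)` and samples founder alleles independently per
#' locus at those frequencies. Founders are treated as fully inbred, i.e. each
#' founder carries two identical haplotypes.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A `gs_founder_pool`: list with `haplotypes` (founders x loci 0/1
#'   matrix), `freq` (founder allele frequencies) and `map`.
#' @export
simulate_founder_haplotypes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gs_sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  map <- make_map(config)
  m <- nrow(map)
  freq <- rbeta(m, config$beta_shape, config$beta_shape)
  hap <- matrix(rbinom(config$n_founders * m, 1L, rep(freq, each = config$n_founders)),
                nrow = config$n_founders, ncol = m)
  structure(list(haplotypes = hap, freq = freq, map = map, config = config),
            class = "gs_founder_pool")
}

#' Run recurrent random-mating cycles and the subpopulation split
#'
#' Founds a panmictic base population from the founder pool, recombines it
#' through `n_cycles` generations of random mating at census `base_size`
#' (building up linkage disequilibrium by drift), then splits it into the
#' configured subpopulations which drift for a few further generations with
#' limited migration between them (producing small but nonzero FST), and
#' finally extracts `n_lines` S0 individuals per subpopulation.
#'
#' @param pool A `gs_founder_pool` from [simulate_founder_haplotypes()].
#' @param config A [sim_config()]; defaults to the pool's config.
#' @param seed Optional integer seed for the mating phase (defaults to
#'   `config$seed + 1`).
#' @return A `gs_population` of S0 individuals with subpopulation labels.
#' @export
run_recurrent_cycles <- function(pool, config = pool$config, seed = NULL) {
  stopifnot(inherits(pool, "gs_founder_pool"))
  if (nrow(pool$haplotypes) == 0) abort("Founder pool is empty.")
  if (config$base_size < 2) abort("Need at least two parents per generation.")
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  msplit <- split_map(pool$map)

  # base phase: sample founders (with replacement) as the initial census,
  # with geometrically decaying contributions when configured
  w <- (1 - config$founder_weight_decay)^(seq_len(nrow(pool$haplotypes)) - 1)
  idx <- sample.int(nrow(pool$haplotypes), config$base_size, replace = TRUE,
                    prob = w)
  hapA <- pool$haplotypes[idx, , drop = FALSE]
  hapB <- hapA # founders are inbred
  for (cyc in seq_len(config$n_cycles)) {
    off <- mate_generation(hapA, hapB, config$base_size, msplit)
    hapA <- off$A
    hapB <- off$B
  }

  # split phase: per-subpopulation parent pools with migration
  sp <- config$subpops
  pools <- lapply(seq_len(nrow(sp)), function(s) {
    take <- sample.int(nrow(hapA), sp$pool_size[s], replace = TRUE)
    list(A = hapA[take, , drop = FALSE], B = hapB[take, , drop = FALSE])
  })
  max_drift <- max(sp$drift_generations)
  for (g in seq_len(max_drift)) {
    pools <- lapply(seq_len(nrow(sp)), function(s) {
      if (g > sp$drift_generations[s]) return(pools[[s]])
      n_off <- sp$pool_size[s]
      offA <- matrix(0L, n_off, ncol(hapA))
      offB <- offA
      for (i in seq_len(n_off)) {
        par_pools <- lapply(1:2, function(j) {
          if (nrow(sp) > 1 && runif(1) < config$migration_rate) {
            pools[[sample(setdiff(seq_len(nrow(sp)), s), 1L)]]
          } else {
            pools[[s]]
          }
        })
        p1 <- sample.int(nrow(par_pools[[1]]$A), 1L)
        p2 <- sample.int(nrow(par_pools[[2]]$A), 1L)
        offA[i, ] <- meiose(par_pools[[1]]$A[p1, ], par_pools[[1]]$B[p1, ], msplit)
        offB[i, ] <- meiose(par_pools[[2]]$A[p2, ], par_pools[[2]]$B[p2, ], msplit)
      }
      list(A = offA, B = offB)
    })
  }

  # extract S0 lines: random matings within each final subpopulation pool
  outA <- vector("list", nrow(sp))
  outB <- vector("list", nrow(sp))
  for (s in seq_len(nrow(sp))) {
    off <- mate_generation(pools[[s]]$A, pools[[s]]$B, sp$n_lines[s], msplit)
    outA[[s]] <- off$A
    outB[[s]] <- off$B
  }
  hapA <- do.call(rbind, outA)
  hapB <- do.call(rbind, outB)
  subpop <- rep(sp$name, sp$n_lines)
  line_id <- sprintf("%s_%03d", subpop,
                     unlist(lapply(sp$n_lines, seq_len)))
  new_population(hapA, hapB, pool$map, line_id, subpop, "S0")
}

#' Advance lines by single seed descent
#'
#' Each line is selfed independently for `generations` generations, keeping one
#' offspring per generation. Expected heterozygosity halves per generation.
#'
#' @param population A `gs_population`.
#' @param generations Number of selfing generations (>= 0).
#' @param seed Optional integer seed.
#' @return A `gs_population` at generation `S<g>`.
#' @export
advance_ssd <- function(population, generations, seed = NULL) {
  stopifnot(inherits(population, "gs_population"))
  if (generations < 0) abort("`generations` must be >= 0.")
  if (generations == 0) return(population)
  if (!is.null(seed)) set.seed(seed)
  msplit <- split_map(population$map)
  hapA <- population$hapA
  hapB <- population$hapB
  for (g in seq_len(generations)) {
    for (i in seq_len(nrow(hapA))) {
      a <- meiose(hapA[i, ], hapB[i, ], msplit)
      b <- meiose(hapA[i, ], hapB[i, ], msplit)
      hapA[i, ] <- a
      hapB[i, ] <- b
    }
  }
  gen0 <- suppressWarnings(as.integer(sub("^S", "", population$generation)))
  gen <- if (is.na(gen0)) sprintf("S+%d", generations) else
    sprintf("S%d", gen0 + generations)
  new_population(hapA, hapB, population$map, population$line_id,
                 population$subpop, gen, population$tbv)
}

#' Define a trait architecture
#'
#' @param name Trait name.
#' @param n_qtl Number of additive QTLs (sampled uniformly among loci when
#'   `qtl_idx` is `NULL`).
#' @param target_h2 Narrow-sense heritability targeted by the field-trial
#'   simulator, in `[0, 1]`.
#' @param qtl_idx Optional explicit QTL locus indices.
#' @param effects Optional explicit additive effects (recycled to `n_qtl`);
#'   drawn `N(0, 1)` when `NULL`.
#' @param major_locus Optional `list(locus =, effect =)` adding one large-effect
#'   locus, for an oligogenic trait.
#' @return A `gs_trait` list.
#' @export
trait_architecture <- function(name, n_qtl = 300, target_h2 = 0.5,
                               qtl_idx = NULL, effects = NULL,
                               major_locus = NULL) {
  if (target_h2 < 0 || target_h2 > 1) abort("`target_h2` must be in [0, 1].")
  structure(list(name = name, n_qtl = as.integer(n_qtl),
                 target_h2 = target_h2, qtl_idx = qtl_idx,
                 effects = effects, major_locus = major_locus),
            class = "gs_trait")
}

#' Compute true breeding values for a trait
#'
#' Under the strictly additive model, the true breeding value of line i is
#' `sum_q effect_q * dosage_iq` over the trait's QTLs, centered on the
#' population mean. The values are stored on the returned population.
#'
#' @param population A `gs_population`.
#' @param architecture A [trait_architecture()].
#' @param seed Optional integer seed for QTL/effect sampling.
#' @return The population with `tbv[[architecture$name]]` filled in; the
#'   realised architecture (with sampled indices/effects) is attached as
#'   attribute `"architecture"` of that vector.
#' @export
build_trait <- function(population, architecture, seed = NULL) {
  stopifnot(inherits(population, "gs_population"),
            inherits(architecture, "gs_trait"))
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(population$hapA)
  qtl <- architecture$qtl_idx
  if (is.null(qtl)) qtl <- sample.int(m, architecture$n_qtl)
  if (any(qtl < 1 | qtl > m)) abort("QTL indices out of locus range.")
  eff <- architecture$effects
  if (is.null(eff)) eff <- rnorm(length(qtl))
  eff <- rep_len(eff, length(qtl))
  Z <- dosage(population)[, qtl, drop = FALSE]
  tbv <- as.numeric(Z %*% eff)
  if (!is.null(architecture$major_locus)) {
    ml <- architecture$major_locus
    if (ml$locus < 1 || ml$locus > m) abort("Major locus index out of range.")
    tbv <- tbv + dosage(population)[, ml$locus] * ml$effect
  }
  tbv <- tbv - mean(tbv)
  names(tbv) <- population$line_id
  arch <- architecture
  arch$qtl_idx <- qtl
  arch$effects <- eff
  attr(tbv, "architecture") <- arch
  population$tbv[[architecture$name]] <- tbv
  population
}

#' Define the alpha-lattice trial design
#'
#' @param n_replicates Complete replicates (default 2).
#' @param n_blocks Incomplete blocks per replicate (default 21).
#' @param plots_per_block Plots per block (default 17).
#' @param block_var_ratio Block-within-replicate variance as a fraction of the
#'   genetic variance.
#' @param rep_effect_sd_ratio Standard deviation of the fixed replicate
#'   effects, as a fraction of the genetic standard deviation (effects are
#'   centered to sum to zero).
#' @return A `gs_trial_design` list.
#' @export
trial_design <- function(n_replicates = 2, n_blocks = 21, plots_per_block = 17,
                         block_var_ratio = 0.25, rep_effect_sd_ratio = 0.3) {
  if (block_var_ratio < 0) abort("Variance ratios must be >= 0.")
  structure(list(n_replicates = as.integer(n_replicates),
                 n_blocks = as.integer(n_blocks),
                 plots_per_block = as.integer(plots_per_block),
                 block_var_ratio = block_var_ratio,
                 rep_effect_sd_ratio = rep_effect_sd_ratio),
            class = "gs_trial_design")
}

#' Simulate the alpha-lattice field trial
#'
#' Every line is planted once per replicate; within a replicate, lines are
#' randomised into incomplete blocks. Plot values follow
#' `Y = mu + TBV + R_j + b_k(j) + e` with fixed, sum-to-zero replicate effects,
#' normal block-within-replicate effects, and normal residuals whose variance
#' is chosen so that the plot-basis narrow-sense heritability
#' `h2 = s2_g / (s2_g + s2_e)` matches each trait's `target_h2`
#' (`s2_e = s2_g (1 - h2) / h2`, capped at `1e6 * s2_g` as `h2 -> 0`).
#'
#' @param population A `gs_population` carrying true breeding values (see
#'   [build_trait()]).
#' @param design A [trial_design()].
#' @param traits Character vector of trait names (default: all with TBV).
#' @param mu Named numeric of trait intercepts (default 0).
#' @param seed Optional integer seed.
#' @return A tibble of plot records: `line`, `subpop`, `trait`, `replicate`,
#'   `block`, `value`, with the generating variance components in attribute
#'   `"truth"`.
#' @export
simulate_field_trial <- function(population, design = trial_design(),
                                 traits = names(population$tbv), mu = NULL,
                                 seed = NULL) {
  stopifnot(inherits(population, "gs_population"),
            inherits(design, "gs_trial_design"))
  if (!length(traits)) abort("Population carries no true breeding values.")
  n <- length(population$line_id)
  capacity <- design$n_blocks * design$plots_per_block
  if (capacity < n) {
    abort(sprintf("Design capacity (%d plots/replicate) < %d entries.",
                  capacity, n))
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- list()
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    tbv <- population$tbv[[tr]]
    if (is.null(tbv)) abort(sprintf("No TBV for trait '%s'.", tr))
    h2 <- attr(tbv, "architecture")$target_h2
    s2g <- var(as.numeric(tbv))
    s2e <- if (h2 <= 0) 1e6 * s2g else min(s2g * (1 - h2) / h2, 1e6 * s2g)
    s2b <- design$block_var_ratio * s2g
    mu_t <- if (!is.null(mu) && tr %in% names(mu)) mu[[tr]] else 0
    rep_eff <- rnorm(design$n_replicates, 0,
                     sqrt(s2g) * design$rep_effect_sd_ratio)
    rep_eff <- rep_eff - mean(rep_eff)
    recs <- vector("list", design$n_replicates)
    for (r in seq_len(design$n_replicates)) {
      ord <- sample.int(n)
      block <- rep(seq_len(design$n_blocks),
                   each = design$plots_per_block)[seq_len(n)]
      b_eff <- rnorm(design$n_blocks, 0, sqrt(s2b))
      e <- rnorm(n, 0, sqrt(s2e))
      y_plot <- mu_t + as.numeric(tbv[ord]) + rep_eff[r] + b_eff[block] + e
      recs[[r]] <- tibble::tibble(
        line = population$line_id[ord],
        subpop = population$subpop[ord],
        trait = tr,
        replicate = sprintf("R%d", r),
        block = sprintf("B%02d", block),
        value = y_plot
      )
    }
    out[[ti]] <- dplyr::bind_rows(recs)
    truth[[tr]] <- list(mu = mu_t, sigma2_g = s2g, sigma2_b = s2b,
                        sigma2_e = s2e, target_h2 = h2, rep_eff = rep_eff)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- truth
  res
}

#' Default trait set of the simulated study
#'
#' Four additive traits spanning a wide heritability range: an oligogenic
#' early/late flowering-type trait with one major locus (h2 = 0.86) and three
#' polygenic traits (h2 = 0.58, 0.29, 0.10), echoing days-to-flowering, plant
#' height, grain yield and panicle weight.
#'
#' @param n_loci Number of loci in the target population (used to place the
#'   major locus; QTLs themselves are sampled at build time).
#' @return List of [trait_architecture()] objects.
#' @export
default_traits <- function(n_loci) {
  poly <- min(300L, max(5L, n_loci %/% 10L))
  olig <- min(60L, max(2L, n_loci %/% 20L))
  list(
    trait_architecture("FL", n_qtl = olig, target_h2 = 0.86,
                       major_locus = list(locus = max(1L, n_loci %/% 7L),
                                          effect = 6)),
    trait_architecture("PH", n_qtl = poly, target_h2 = 0.58),
    trait_architecture("YLD", n_qtl = poly, target_h2 = 0.29),
    trait_architecture("PW", n_qtl = poly, target_h2 = 0.10)
  )
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_founder_haplotypes()],
#' [run_recurrent_cycles()], [advance_ssd()] and [build_trait()] under a single
#' seed, yielding the S2 line panel with true breeding values.
#'
#' @param config A [sim_config()].
#' @param traits List of [trait_architecture()] objects, or `NULL` for
#'   [default_traits()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A `gs_population` of S2 lines.
#' @export
simulate_population <- function(config = sim_config(), traits = NULL,
                                seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  pool <- simulate_founder_haplotypes(config)
  pop <- run_recurrent_cycles(pool, config)
  pop <- advance_ssd(pop, config$selfing_generations,
                     seed = config$seed + 2L)
  if (is.null(traits)) traits <- default_traits(ncol(pop$hapA))
  set.seed(config$seed + 3L)
  for (tr in traits) pop <- build_trait(pop, tr)
  pop
}
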