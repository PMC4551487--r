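# Readers/writers for the plain-text interchange formats: dosage CSV
# (rows = lines, columns = loci), map CSV, trial CSV and a GT-only VCF v4.2.
# Internal locus indexing is 0-free (R's 1-based columns); VCF positions are
# 1-based integers derived from the kb map.

#' Export a population (and optionally its trial) to plain-text files
#'
#' Writes `dosage.csv`, `map.csv`, `genotypes.vcf` and, when a trial is
#' given, `trial.csv` into `dir`. The files round-trip losslessly through
#' [read_population()] / [read_trial_csv()].
#'
#' @param population A `gs_population`.
#' @param dir Output directory (created if absent).
#' @param trial Optional plot-record tibble from [simulate_field_trial()].
#' @return Invisibly, the written file paths.
#' @export
export_population <- function(population, dir, trial = NULL) {
  stopifnot(inherits(population, "gs_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geno <- dosage(population)
  paths <- c(dosage = file.path(dir, "dosage.csv"),
             map = file.path(dir, "map.csv"),
             vcf = file.path(dir, "genotypes.vcf"))
  dos <- tibble::as_tibble(geno, .name_repair = "minimal") %>%
    dplyr::mutate(line = population$line_id,
                  subpop = population$subpop, .before = 1)
  readr::write_csv(dos, paths["dosage"])
  readr::write_csv(population$map, paths["map"])
  write_vcf(geno, population$map, paths["vcf"])
  if (!is.null(trial)) {
    paths <- c(paths, trial = file.path(dir, "trial.csv"))
    readr::write_csv(trial, paths["trial"])
  }
  invisible(paths)
}

# GT-only VCF v4.2 with synthetic REF/ALT alleles; positions are 1-based
# integers from the kb map (resolution 1 bp = 1/1000 kb).
write_vcf <- function(geno, map, path) {
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsrice",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  pos <- as.integer(round(map$pos_kb * 1000)) + 1L
  body <- vapply(seq_len(nrow(map)), function(i) {
    paste(c(map$chrom[i], pos[i], map$locus[i], "A", "T", ".", ".", ".",
            "GT", gt[geno[, i] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a dosage CSV (plus map) back into a population
#'
#' @param dir Directory holding `dosage.csv` and `map.csv` as written by
#'   [export_population()].
#' @return A `gs_population` (haplotypes are reconstructed arbitrarily from
#'   dosages: heterozygous calls are phased as 0|1).
#' @export
read_population <- function(dir) {
  dos <- readr::read_csv(file.path(dir, "dosage.csv"),
                         show_col_types = FALSE)
  map <- readr::read_csv(file.path(dir, "map.csv"), show_col_types = FALSE)
  line_id <- dos$line
  subpop <- dos$subpop
  geno <- as.matrix(dos[, map$locus])
  storage.mode(geno) <- "integer"
  rownames(geno) <- line_id
  hapA <- (geno >= 1) * 1L
  hapB <- (geno == 2) * 1L
  new_population(hapA, hapB, map, line_id, subpop, "imported")
}

#' Read a GT-only VCF into a dosage matrix
#'
#' Minimal reader for the VCF files written by [export_population()] (and any
#' VCF restricted to a GT field): returns the lines x loci dosage matrix and
#' the map implied by CHROM/POS.
#'
#' @param path VCF file path.
#' @return List with `geno` (dosage matrix) and `map` tibble.
#' @export
read_vcf_dosage <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#CHROM")]
  if (!length(hdr)) abort("Not a VCF: no #CHROM header line.")
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- ln[!startsWith(ln, "#")]
  fields <- strsplit(body, "\t")
  n_alt <- function(x) {
    a <- strsplit(sub(":.*", "", x), "[/|]")[[1]]
    sum(a == "1")
  }
  g <- vapply(fields, function(f) {
    vapply(f[-(1:9)], n_alt, integer(1))
  }, integer(length(samples)))
  geno <- if (length(samples) == 1) matrix(g, nrow = 1) else g
  map <- tibble::tibble(
    locus = vapply(fields, `[`, character(1), 3),
    chrom = as.integer(vapply(fields, `[`, character(1), 1)),
    pos_kb = (as.numeric(vapply(fields, `[`, character(1), 2)) - 1) / 1000)
  map$pos_cM <- NA_real_
  dimnames(geno) <- list(samples, map$locus)
  list(geno = geno, map = map)
}

#' Read a trial CSV
#'
#' @param path Path to a `trial.csv` with columns line, trait, replicate,
#'   block, value.
#' @return Plot-record tibble.
#' @export
read_trial_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
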