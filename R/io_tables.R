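#' The 15 GPCR secondary-structure domain classes
#'
#' In N-to-C topological order: the extracellular N-terminus, seven
#' transmembrane helices (TM1-TM7) interleaved with three intracellular
#' (ICL1-ICL3) and three extracellular (ECL1-ECL3) loops, and the
#' intracellular C-terminus.
#' @export
gpcr_domain_classes <- c(
  "Nterm", "TM1", "ICL1", "TM2", "ECL1", "TM3", "ICL2", "TM4", "ECL2",
  "TM5", "ICL3", "TM6", "ECL3", "TM7", "Cterm")

#' Predictor names accepted by the prediction reader
#' @export
gpcr_predictors <- c("polyphen2", "sift", "evod")

#' Read human secondary-structure domain tables
#'
#' One row per domain interval on the human protein: columns `gene`,
#' `domain`, `start`, `end` (1-based, closed residue coordinates).
#'
#' @param path TSV path.
#' @return Tibble sorted by gene and start, after invariant checks
#'   (legal class labels; non-overlapping intervals within gene).
#' @export
read_domain_table <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", domain = "c", start = "i", end = "i"), progress = FALSE)
  bad <- setdiff(unique(d$domain), gpcr_domain_classes)
  if (length(bad)) {
    stop("schema error: unknown domain class(es): ", paste(bad, collapse = ", "))
  }
  d <- dplyr::arrange(d, .data$gene, .data$start)
  ok <- d |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ok = all(.data$start <= .data$end) &&
                       (dplyr::n() < 2 ||
                        all(.data$start[-1] > .data$end[-dplyr::n()])))
  if (!all(ok$ok)) {
    stop("schema error: overlapping or inverted domain intervals in gene(s): ",
         paste(ok$gene[!ok$ok], collapse = ", "))
  }
  d
}

#' Read a human variant table (dbSNP-style)
#'
#' Columns: `gene`, `aa_pos` (1-based protein position), `aa1` (ancestral),
#' `aa2` (derived), `coords` (genomic coordinates, free text), `dbsnp`,
#' `maf` (alternate-allele frequency in [0, 1]).
#'
#' @param path TSV path.
#' @return Tibble after invariant checks (aa1 != aa2, maf in [0, 1]).
#' @export
read_human_variants <- function(path) {
  h <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", aa_pos = "i", aa1 = "c", aa2 = "c",
    coords = "c", dbsnp = "c", maf = "d"), progress = FALSE)
  if (any(h$aa1 == h$aa2)) stop("schema error: aa1 == aa2 in human variant table")
  if (any(h$maf < 0 | h$maf > 1)) {
    stop("schema error: MAF outside [0, 1] in human variant table")
  }
  h
}

#' Read external functional-prediction calls
#'
#' One row per (variant, predictor): columns `key`, `predictor`, `call`
#' with `call` in `c("damaging", "tolerated")`. Pairs absent from the file
#' are treated as missing by the consensus classifier.
#'
#' @param path TSV path.
#' @param predictors Legal predictor names (default [gpcr_predictors]).
#' @return Tibble `key`, `predictor`, `call`.
#' @export
read_predictions <- function(path, predictors = gpcr_predictors) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    key = "c", predictor = "c", call = "c"), progress = FALSE)
  bad <- setdiff(unique(p$predictor), predictors)
  if (length(bad)) {
    stop("schema error: unknown predictor name(s): ", paste(bad, collapse = ", "))
  }
  if (!all(p$call %in% c("damaging", "tolerated"))) {
    stop("schema error: prediction calls must be damaging/tolerated")
  }
  if (anyDuplicated(p[, c("key", "predictor")])) {
    stop("schema error: duplicate (variant, predictor) rows")
  }
  p
}

#' Read an ortholog pair table
#'
#' Columns: `gene`, `human_id`, `macaque_id` naming the FASTA records of the
#' human and macaque protein sequences for each gene.
#' @param path TSV path.
#' @return Tibble.
#' @export
read_ortholog_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

# ---- curated reference tables (shipped under inst/extdata) ----------------

ref_table <- function(name) {
  path <- system.file("extdata", name, package = "macgpcr")
  if (path == "") stop("reference table not found: ", name)
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Reference singleton/common and population-sharing counts for
#' loss-of-function mutations
#'
#' Curated counts from a published macaque GPCR resequencing survey:
#' frameshift and stop-gain (nonsense) mutations broken down into singleton
#' vs common, and common mutations into the seven population-sharing
#' regions.
#' @return Tibble `row`, `frameshift`, `stop_gain`.
#' @export
lof_sharing_counts <- function() ref_table("lof_sharing_counts.tsv")

#' Reference table of high-frequency frameshift and stop-gain mutations
#'
#' Per-variant rows with position, alleles, gene, consequence and
#' per-population genotyped counts and allele percentages.
#' @return Tibble.
#' @export
high_frequency_lof <- function() ref_table("high_frequency_lof.tsv")

#' Reference table of recurrent human/macaque mutations
#'
#' Amino-acid changes observed at the same aligned residue with the same
#' derived allele in both species.
#' @return Tibble.
#' @export
recurrent_mutation_table <- function() ref_table("recurrent_mutations.tsv")

#' Reference table of shared-position divergent human/macaque mutations
#'
#' Same ancestral residue mutated to different derived alleles in the two
#' species.
#' @return Tibble.
#' @export
shared_position_table <- function() ref_table("shared_position_mutations.tsv")
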