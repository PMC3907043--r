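# Shared fixtures built in code. Simulated cohorts are cached per test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, cfg) {
  if (is.null(.sim_cache[[name]])) {
    .sim_cache[[name]] <- simulate_cohort(cfg)
  }
  .sim_cache[[name]]
}

small_sim <- function() {
  cached_sim("small", sim_config(seed = 7, n_genes = 4,
                                 codons_per_gene = 150))
}

# larger cohort used for parameter-recovery checks
big_sim <- function() {
  cached_sim("big", sim_config(seed = 101, n_genes = 20,
                               codons_per_gene = 300,
                               coding_snv_per_codon = 0.8))
}

# single-population neutral cohort (no skew, no plants, no missingness)
kappa0_sim <- function() {
  cached_sim("kappa0", sim_config(
    seed = 31, n_genes = 40, codons_per_gene = 100,
    coding_snv_per_codon = 0.5,
    scope_probs = c(chinese = 1, indian = 0, cynomolgus = 0, rhesus = 0,
                    all = 0),
    kappa = 0, missing_rate = 0,
    n_recurrent = 0L, n_divergent = 0L, n_cooccur = 0L,
    n_human_background = 0L))
}

# cohort with only planted co-occurrences on the cross-species side
cooc_sim <- function() {
  cached_sim("cooc", sim_config(
    seed = 9, n_genes = 6, codons_per_gene = 120,
    n_recurrent = 0L, n_divergent = 0L, n_cooccur = 4L,
    n_human_background = 0L))
}

# full pipeline result over the big cohort, computed once
big_run <- function() {
  if (is.null(.sim_cache$big_run)) {
    .sim_cache$big_run <- run_pipeline(big_sim(), tempfile("bigrun"))
  }
  .sim_cache$big_run
}

# a three-sample manifest for toy examples
tiny_manifest <- function(n = c(1, 1, 1)) {
  validate_manifest(dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("ch%02d", seq_len(n[1])),
                   population = "chinese_rhesus"),
    tibble::tibble(sample_id = sprintf("in%02d", seq_len(n[2])),
                   population = "indian_rhesus"),
    tibble::tibble(sample_id = sprintf("cy%02d", seq_len(n[3])),
                   population = "cynomolgus")))
}

# single-exon plus-strand gene with the given CDS placed at genomic start
toy_gene <- function(cds, start = 101L, gene_id = "G1", chrom = "chr1",
                     strand = "+", flank = 2000L) {
  len <- nchar(cds)
  cds_tbl <- tibble::tibble(start = start, end = start + len - 1L)
  if (strand == "-") cds_tbl <- cds_tbl  # single interval, same either way
  tibble::tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
    chrom = chrom, strand = strand,
    gene_start = start, gene_end = start + len - 1L,
    flank = flank, cds_len = len, incomplete = (len %% 3L) != 0L,
    exons = list(cds_tbl), cds = list(cds_tbl),
    utr5 = list(cds_tbl[0, ]), utr3 = list(cds_tbl[0, ]))
}

# variant row helper
toy_variant <- function(pos, ref, alt, chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 vclass = variant_class(ref, alt))
}

# write a small VCF text file
write_vcf_text <- function(lines, samples = character()) {
  path <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}
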