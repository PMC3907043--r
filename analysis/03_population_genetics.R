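#!/usr/bin/env Rscript
# Per-population allele counts, site frequency spectra, the three-way
# sharing partition of common variants, loss-of-function summaries and the
# STRUCTURE export.
source(file.path("analysis", "00_common.R"))

files <- get_workdir()
manifest <- read_manifest(files$manifest)
cohort <- read_vcf(files$vcf, manifest)
models <- read_gene_models(files$gff3)
cds_set <- Biostrings::readBStringSet(files$cds)
cds <- setNames(as.character(cds_set), names(cds_set))

counts <- count_alleles(cohort)
fc <- classify_frequency(counts)
sharing <- partition_sharing(counts, fc)
sfs <- dplyr::bind_rows(lapply(gpcr_populations, function(p)
  dplyr::mutate(build_sfs(counts, p), population = p)))
calls <- annotate_variants(cohort, models, cds)
lof <- lof_summary(calls, fc, sharing)
hf <- summarize_high_frequency(calls, counts)

readr::write_tsv(counts, file.path(results_dir, "allele_counts.tsv"))
readr::write_tsv(sfs, file.path(results_dir, "sfs.tsv"))
readr::write_tsv(sharing$venn, file.path(results_dir, "sharing_venn.tsv"))
readr::write_tsv(lof, file.path(results_dir, "lof_summary.tsv"))
readr::write_tsv(hf, file.path(results_dir, "high_frequency_lof.tsv"))
write_structure_input(cohort, file.path(results_dir, "structure_input.txt"))

cat("Common variants by sharing region:\n"); print(sharing$venn)
single <- vapply(gpcr_populations, function(p) {
  s <- build_sfs(counts, p); s$sites[s$alt_count == 1] / sum(s$sites)
}, 0)
cat("\nPer-population singleton share of the spectrum:\n")
print(round(100 * single, 1))
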