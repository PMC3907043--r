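#!/usr/bin/env Rscript
# Annotate every variant with its region and coding effect, classify
# singleton vs common, and build the category table (counts per annotation
# category split by frequency class).
source(file.path("analysis", "00_common.R"))

files <- get_workdir()
manifest <- read_manifest(files$manifest)
cohort <- read_vcf(files$vcf, manifest)
models <- read_gene_models(files$gff3)
cds <- setNames(as.character(Biostrings::readBStringSet(files$cds)), NULL)
names(cds) <- names(Biostrings::readBStringSet(files$cds))

calls <- annotate_variants(cohort, models, cds)
fc <- classify_frequency(cohort)
tab <- tabulate_categories(calls, fc)
readr::write_tsv(calls, file.path(results_dir, "annotation.tsv"))
readr::write_tsv(tab, file.path(results_dir, "category_table.tsv"))
print(tab, n = Inf)
cat("\nSingleton share among synonymous:",
    sprintf("%.1f%%", tab$singleton_pct[tab$category == "synonymous"]),
    "- non-synonymous:",
    sprintf("%.1f%%", tab$singleton_pct[tab$category == "non_synonymous"]),
    "\n")
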