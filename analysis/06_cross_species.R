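#!/usr/bin/env Rscript
# Match common macaque variation against common human variation at aligned
# residues (recurrent vs shared-position-divergent mutations) and count
# gene+domain co-occurrences; then recompute the published worked examples
# from the curated reference tables.
source(file.path("analysis", "00_common.R"))

files <- get_workdir()
res <- run_pipeline(files, file.path(results_dir, "bundle"))
cat("Synthetic cohort:",
    sum(res$matches$class == "recurrent"), "recurrent and",
    sum(res$matches$class == "shared_position_divergent"),
    "shared-position-divergent matches;",
    nrow(res$cooccurrence$instances), "gene+domain co-occurrences over",
    res$cooccurrence$n_genes, "genes.\n")

inp <- reference_cross_species_inputs()
m <- match_positions(filter_human_common(inp$human_rows),
                     inp$macaque_common, inp$alignments)
readr::write_tsv(m, file.path(results_dir, "reference_cross_species.tsv"))
cat("Reference survey recomputation:",
    sum(m$class == "recurrent"), "recurrent,",
    sum(m$class == "shared_position_divergent"), "divergent.\n")
lab <- tolower(gsub(" ", "_", recurrent_mutation_table()$consensus))
f <- damaging_fraction(lab)
cat("Recurrent mutations with damaging consensus:", f$damaging, "of",
    f$total, "\n")
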