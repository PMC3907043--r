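#!/usr/bin/env Rscript
# Generate the synthetic resequencing cohort: 96 macaques in three
# populations (20 Chinese rhesus, 44 Indian rhesus, 32 cynomolgus)
# genotyped over simulated seven-transmembrane receptor genes, with a
# simulated human ortholog set and known truth for every variant.
source(file.path("analysis", "00_common.R"))

files <- get_workdir()
sim <- simulate_cohort(analysis_config)
truth <- sim$truth$variants
cat("Simulated", nrow(sim$cohort$variants), "variants over",
    nrow(sim$models), "genes;",
    sum(truth$effect == "non_synonymous"), "non-synonymous,",
    sum(truth$effect == "synonymous"), "synonymous,",
    sum(truth$effect == "frameshift"), "frameshift,",
    sum(truth$effect == "stop_gain"), "stop gain.\n")
cat("Working directory written under", analysis_dir, "\n")
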