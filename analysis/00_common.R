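# Shared setup for the analysis drivers: a single seeded configuration so
# every script works from the same simulated working directory.
suppressPackageStartupMessages(library(macgpcr))

analysis_dir <- file.path("results", "workdir")
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

analysis_config <- sim_config(seed = 20260926 %% 2^31, n_genes = 12,
                              codons_per_gene = 300,
                              coding_snv_per_codon = 0.5)

# simulate once; later drivers reuse the files on disk
get_workdir <- function() {
  if (!file.exists(file.path(analysis_dir, "cohort.vcf"))) {
    simulate_cohort(analysis_config, analysis_dir)
  }
  list(
    vcf = file.path(analysis_dir, "cohort.vcf"),
    manifest = file.path(analysis_dir, "manifest.tsv"),
    gff3 = file.path(analysis_dir, "genes.gff3"),
    cds = file.path(analysis_dir, "macaque_cds.fa"),
    macaque_protein = file.path(analysis_dir, "macaque_protein.fa"),
    human_cds = file.path(analysis_dir, "human_cds.fa"),
    human_protein = file.path(analysis_dir, "human_protein.fa"),
    domains = file.path(analysis_dir, "human_domains.tsv"),
    human_variants = file.path(analysis_dir, "human_variants.tsv"),
    predictions = file.path(analysis_dir, "predictions.tsv"))
}
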