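#' Table of high-frequency frameshift and stop-gain mutations
#'
#' Selects loss-of-function calls (frameshift, stop gain), ranks them by a
#' declared prominence key — maximum per-population alternate-allele
#' frequency, descending, ties broken by genomic coordinate — and lays out
#' per-population genotyped counts with reference/alternate percentages.
#'
#' @param calls Annotation tibble from [annotate_variants()].
#' @param counts Long counts tibble from [count_alleles()].
#' @param cohort Optional cohort, used to recover allele strings.
#' @return Tibble: `position`, `ref`, `alt`, `gene`, `consequence`, and for
#'   each population `n`, `ref_pct`, `alt_pct`, plus `max_freq`.
#' @export
summarize_high_frequency <- function(calls, counts, cohort = NULL) {
  lof <- calls[calls$effect %in% c("frameshift", "stop_gain"), , drop = FALSE]
  sub <- counts[counts$key %in% lof$key, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(position = character(), ref = character(),
                          alt = character(), gene = character(),
                          consequence = character(), max_freq = double()))
  }
  wide <- sub |>
    tidyr::pivot_wider(id_cols = "key", names_from = "population",
                       values_from = c("n", "f"))
  for (p in gpcr_populations) {
    if (is.null(wide[[paste0("n_", p)]])) wide[[paste0("n_", p)]] <- 0L
    if (is.null(wide[[paste0("f_", p)]])) wide[[paste0("f_", p)]] <- NA_real_
  }
  wide$max_freq <- pmax(wide$f_chinese_rhesus, wide$f_indian_rhesus,
                        wide$f_cynomolgus, na.rm = TRUE)
  parts <- strsplit(wide$key, ":", fixed = TRUE)
  wide$chrom <- vapply(parts, `[`, "", 1)
  wide$pos <- as.integer(vapply(parts, `[`, "", 2))
  wide$ref <- vapply(parts, `[`, "", 3)
  wide$alt <- vapply(parts, `[`, "", 4)
  wide <- dplyr::left_join(wide, lof[, c("key", "gene", "effect")],
                           by = "key")
  wide <- wide[order(-wide$max_freq, wide$chrom, wide$pos), ]
  pct <- function(x) round(100 * x, 1)
  tibble::tibble(
    position = paste0(wide$chrom, ":", wide$pos),
    ref = wide$ref, alt = wide$alt, gene = wide$gene,
    consequence = ifelse(wide$effect == "stop_gain", "Stop gain",
                         "Frameshift"),
    n_chinese = wide$n_chinese_rhesus,
    ref_pct_chinese = pct(1 - wide$f_chinese_rhesus),
    alt_pct_chinese = pct(wide$f_chinese_rhesus),
    n_indian = wide$n_indian_rhesus,
    ref_pct_indian = pct(1 - wide$f_indian_rhesus),
    alt_pct_indian = pct(wide$f_indian_rhesus),
    n_cynomolgus = wide$n_cynomolgus,
    ref_pct_cynomolgus = pct(1 - wide$f_cynomolgus),
    alt_pct_cynomolgus = pct(wide$f_cynomolgus),
    max_freq = wide$max_freq)
}

#' Singleton/common and sharing summary for loss-of-function mutations
#'
#' @param calls Annotation tibble.
#' @param freq_classes From [classify_frequency()].
#' @param sharing From [partition_sharing()].
#' @return Tibble with one row per summary line (`Singleton`, `Common`,
#'   then the seven sharing regions of common variants) and one column per
#'   effect (`frameshift`, `stop_gain`).
#' @export
lof_summary <- function(calls, freq_classes, sharing) {
  effects <- c("frameshift", "stop_gain")
  rows <- c("Singleton", "Common", "Chinese", "Indian", "Cynomolgus",
            "Chinese-Indian", "Chinese-Cynomolgus", "Indian-Cynomolgus",
            "All")
  out <- tibble::tibble(row = rows)
  for (e in effects) {
    keys <- calls$key[calls$effect == e]
    fc <- freq_classes[freq_classes$key %in% keys, , drop = FALSE]
    asg <- sharing$assignments
    asg <- asg[asg$key %in% keys, , drop = FALSE]
    out[[e]] <- unname(
      c(sum(fc$class == "singleton"), sum(fc$class == "common"),
        vapply(rows[-(1:2)], function(r) sum(asg$region == r),
               integer(1))))
  }
  names(out) <- c("row", effects)
  out
}

#' Run the full comparative polymorphism analysis
#'
#' Executes every stage over a simulated (or externally supplied) working
#' directory and writes the report bundle: per-variant annotation,
#' category table, allele counts, per-population frequency spectra,
#' sharing partitions, loss-of-function summaries, high-frequency table,
#' per-domain density tables, prediction-consensus tables, cross-species
#' recurrent/divergent and co-occurrence reports, a STRUCTURE export and a
#' JSON run manifest. Re-running on identical inputs reproduces identical
#' files.
#'
#' @param inputs Either the list returned by [simulate_cohort()] or a list
#'   of file paths with names `vcf`, `manifest`, `gff3`, `cds`,
#'   `macaque_protein`, `human_protein`, `human_cds`, `domains`,
#'   `human_variants`, `predictions`.
#' @param out_dir Output directory for the report bundle.
#' @param flank Flank length used when reading gene models from GFF3.
#' @param human_maf_threshold Human common-variant threshold (default
#'   0.005, strict inequality).
#' @param include_ambiguous Denominator convention for damaging fractions.
#' @return Invisibly, a list of the computed tables (same content as the
#'   files).
#' @export
run_pipeline <- function(inputs, out_dir, flank = 2000L,
                         human_maf_threshold = 0.005,
                         include_ambiguous = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  if (!is.null(inputs$cohort)) {
    sim <- inputs
    cohort <- sim$cohort; models <- sim$models
    cds <- unlist(sim$cds); mac_prot <- unlist(sim$macaque_prot)
    hum_prot <- unlist(sim$human_prot); hum_cds <- unlist(sim$human_cds)
    domains <- sim$domains; human_variants <- sim$human_variants
    predictions <- sim$predictions
  } else {
    manifest <- read_manifest(inputs$manifest)
    cohort <- read_vcf(inputs$vcf, manifest)
    models <- read_gene_models(inputs$gff3, flank = flank)
    rd <- function(f) {
      x <- Biostrings::readBStringSet(f)
      setNames(as.character(x), names(x))
    }
    cds <- rd(inputs$cds); mac_prot <- rd(inputs$macaque_protein)
    hum_prot <- rd(inputs$human_protein); hum_cds <- rd(inputs$human_cds)
    domains <- read_domain_table(inputs$domains)
    human_variants <- read_human_variants(inputs$human_variants)
    predictions <- read_predictions(inputs$predictions)
  }

  # annotation + population genetics
  calls <- annotate_variants(cohort, models, cds)
  counts <- count_alleles(cohort)
  fc <- classify_frequency(counts)
  cat_tab <- tabulate_categories(calls, fc)
  sharing <- partition_sharing(counts, fc)
  sfs <- dplyr::bind_rows(lapply(
    intersect(gpcr_populations, unique(cohort$manifest$population)),
    function(p) dplyr::mutate(build_sfs(counts, p), population = p)))
  lof <- lof_summary(calls, fc, sharing)
  hf <- summarize_high_frequency(calls, counts)

  # ortholog alignment, domain transfer, divergence, densities
  alignments <- align_ortholog_set(hum_prot, mac_prot)
  mac_domains <- dplyr::bind_rows(lapply(names(alignments), function(g)
    transfer_domains(alignments[[g]],
                     domains[domains$gene == g, , drop = FALSE])))
  poly <- dplyr::left_join(calls, fc[, c("key", "class")], by = "key")
  coding <- poly[poly$region == "CDS" & !is.na(poly$codon_index) &
                 poly$class != "monomorphic", , drop = FALSE]
  coding$macaque_pos <- coding$codon_index
  strata <- list(
    singleton_synonymous = quote(effect == "synonymous" &
                                 class == "singleton"),
    common_synonymous = quote(effect == "synonymous" & class == "common"),
    singleton_nonsyn = quote(effect == "non_synonymous" &
                             class == "singleton"),
    common_nonsyn = quote(effect == "non_synonymous" & class == "common"))
  dens <- dplyr::bind_rows(lapply(names(strata), function(s) {
    ev <- coding[eval(strata[[s]], coding), c("gene", "macaque_pos")]
    domain_density(ev, mac_domains, s)
  }))
  divergence <- dplyr::bind_rows(lapply(names(alignments), function(g) {
    polyc <- unique(coding$codon_index[coding$gene == g])
    cons <- refine_consensus(cds[[g]], models[models$gene_id == g, ],
                             cohort, calls[calls$gene == g, ])
    if (!cons$frame_ok) return(NULL)
    fixed_differences(cons$cds, hum_cds[[g]], alignments[[g]],
                      polymorphic_codons = polyc, gene = g)
  }))
  if (nrow(divergence)) {
    for (kind in c("synonymous", "non_synonymous")) {
      ev <- divergence[divergence$kind == kind, , drop = FALSE]
      ev <- tibble::tibble(gene = ev$gene, macaque_pos = ev$macaque_codon)
      dens <- dplyr::bind_rows(dens,
        domain_density(ev, mac_domains, paste0("divergence_", kind)))
    }
  }

  # prediction consensus
  nonsyn <- poly[poly$effect == "non_synonymous", , drop = FALSE]
  eligible <- vapply(seq_len(nrow(nonsyn)), function(i) {
    aln <- alignments[[nonsyn$gene[i]]]
    !is.null(aln) && check_eligibility(nonsyn$codon_index[i],
                                       nonsyn$ref_aa[i], aln)
  }, logical(1))
  cons_tab <- consensus_table(nonsyn$key, eligible, predictions)
  cons_tab$class <- nonsyn$class[match(cons_tab$key, nonsyn$key)]
  dmg <- damaging_by_stratum(cons_tab$category, cons_tab$class,
                             include_ambiguous = include_ambiguous)

  # cross-species
  hum_common <- filter_human_common(human_variants, human_maf_threshold)
  mac_common <- nonsyn[nonsyn$class == "common", , drop = FALSE]
  mac_common$macaque_pos <- mac_common$codon_index
  matches <- match_positions(hum_common, mac_common, alignments)
  freq_wide <- counts |>
    tidyr::pivot_wider(id_cols = "key", names_from = "population",
                       values_from = "f")
  matches <- dplyr::left_join(matches, freq_wide, by = "key")
  hum_common$domain <- NA_character_
  for (i in seq_len(nrow(hum_common))) {
    d <- domains[domains$gene == hum_common$gene[i], , drop = FALSE]
    hit <- which(d$start <= hum_common$aa_pos[i] &
                 d$end >= hum_common$aa_pos[i])
    if (length(hit)) hum_common$domain[i] <- d$domain[hit[1]]
  }
  mac_common$domain <- domain_of_position_by_gene(mac_common, mac_domains)
  cooc <- domain_cooccurrence(hum_common, mac_common)

  # write the bundle
  wr <- function(x, f) readr::write_tsv(x, fp(f), progress = FALSE)
  wr(calls, "annotation.tsv")
  wr(cat_tab, "category_table.tsv")
  wr(counts, "allele_counts.tsv")
  wr(sfs, "sfs.tsv")
  wr(sharing$venn, "sharing_venn.tsv")
  wr(sharing$rhesus_venn, "sharing_rhesus_venn.tsv")
  wr(lof, "lof_summary.tsv")
  wr(hf, "high_frequency_lof.tsv")
  wr(dens, "domain_density.tsv")
  wr(cons_tab[, setdiff(names(cons_tab), "class")], "consensus.tsv")
  wr(dmg, "damaging_fractions.tsv")
  wr(matches[matches$class == "recurrent", , drop = FALSE],
     "recurrent_matches.tsv")
  wr(matches[matches$class == "shared_position_divergent", , drop = FALSE],
     "divergent_matches.tsv")
  wr(dplyr::select(cooc$instances, -"human_variants", -"macaque_variants"),
     "domain_cooccurrence.tsv")
  wr(cooc$by_domain, "cooccurrence_by_domain.tsv")
  write_structure_input(cohort, fp("structure_input.txt"))
  manifest_json <- list(
    package = "macgpcr",
    version = as.character(utils::packageVersion("macgpcr")),
    n_variants = nrow(cohort$variants),
    n_samples = nrow(cohort$manifest),
    n_genes = nrow(models),
    n_common = sum(fc$class == "common"),
    n_singleton = sum(fc$class == "singleton"),
    n_recurrent = sum(matches$class == "recurrent"),
    n_divergent = sum(matches$class == "shared_position_divergent"),
    n_cooccurrence = nrow(cooc$instances))
  jsonlite::write_json(manifest_json, fp("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, counts = counts, freq_classes = fc,
                 category_table = cat_tab, sharing = sharing, sfs = sfs,
                 lof_summary = lof, high_frequency = hf,
                 alignments = alignments, macaque_domains = mac_domains,
                 densities = dens, divergence = divergence,
                 consensus = cons_tab, damaging = dmg, matches = matches,
                 cooccurrence = cooc))
}

# domain of each (gene, macaque_pos) row against transferred domains
domain_of_position_by_gene <- function(df, mac_domains) {
  vapply(seq_len(nrow(df)), function(i) {
    sub <- mac_domains[mac_domains$gene == df$gene[i] & mac_domains$mapped, ,
                       drop = FALSE]
    hit <- which(sub$start <= df$macaque_pos[i] &
                 sub$end >= df$macaque_pos[i])
    if (length(hit)) sub$domain[hit[1]] else NA_character_
  }, character(1))
}
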