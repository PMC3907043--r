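#' Reconstruct a loss-of-function cohort from the reference summary counts
#'
#' Expands the curated singleton/common and population-sharing counts of
#' frameshift and stop-gain mutations (see [lof_sharing_counts()]) back
#' into an explicit cohort: one synthetic variant per counted mutation,
#' with carriers placed to realise the recorded sharing pattern
#' (singletons one carrier; private common variants two carriers in the
#' population; two- and three-way shared variants one carrier per
#' population). The annotation and population-genetics stages can then be
#' run on it and must recover the printed summary.
#'
#' @param counts Tibble in the shape of [lof_sharing_counts()].
#' @param manifest Optional manifest; defaults to the study design of 20
#'   Chinese rhesus, 44 Indian rhesus and 32 cynomolgus animals.
#' @return List: `cohort` (a `gpcr_cohort`) and `calls` (annotation tibble
#'   with `effect` filled in).
#' @export
reconstruct_reference_lof <- function(counts = lof_sharing_counts(),
                                      manifest = default_manifest()) {
  region_pops <- list(
    Chinese = "chinese_rhesus", Indian = "indian_rhesus",
    Cynomolgus = "cynomolgus",
    `Chinese-Indian` = c("chinese_rhesus", "indian_rhesus"),
    `Chinese-Cynomolgus` = c("chinese_rhesus", "cynomolgus"),
    `Indian-Cynomolgus` = c("indian_rhesus", "cynomolgus"),
    All = gpcr_populations)
  ids_of <- split(manifest$sample_id, manifest$population)
  vrows <- list(); grows <- list(); erows <- character()
  pos <- 0L
  add <- function(effect, carriers) {
    pos <<- pos + 10L
    ref <- if (effect == "frameshift") "AT" else "C"
    alt <- if (effect == "frameshift") "A" else "T"
    gt <- setNames(rep("0/0", nrow(manifest)), manifest$sample_id)
    gt[carriers] <- "0/1"
    vrows[[length(vrows) + 1L]] <<- tibble::tibble(
      chrom = "chrR", pos = pos, id = ".", ref = ref, alt = alt)
    grows[[length(grows) + 1L]] <<- gt
    erows <<- c(erows, effect)
  }
  for (effect in c("frameshift", "stop_gain")) {
    n_single <- counts[[effect]][counts$row == "Singleton"]
    # spread singleton carriers across the cohort round-robin
    for (k in seq_len(n_single)) {
      add(effect, manifest$sample_id[(k - 1L) %% nrow(manifest) + 1L])
    }
    for (r in names(region_pops)) {
      n_r <- counts[[effect]][counts$row == r]
      pops <- region_pops[[r]]
      for (k in seq_len(n_r)) {
        carriers <- if (length(pops) == 1L) {
          ids_of[[pops]][c(2L * k - 1L, 2L * k)]
        } else {
          vapply(pops, function(p) ids_of[[p]][k], character(1))
        }
        add(effect, carriers)
      }
    }
  }
  variants <- dplyr::bind_rows(vrows)
  cohort <- new_cohort(variants, do.call(rbind, grows), manifest)
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  calls <- tibble::tibble(key = keys, gene = "LOF", region = "CDS",
                          effect = erows, codon_index = NA_integer_,
                          ref_aa = NA_character_, alt_aa = NA_character_)
  calls <- calls[match(cohort$variants$key, calls$key), ]
  list(cohort = cohort, calls = calls)
}

#' Reconstruct the high-frequency loss-of-function cohort from the
#' reference per-variant table
#'
#' Inverts the printed per-population genotyped counts and allele
#' percentages of [high_frequency_lof()] into explicit genotypes: in each
#' population, `n` of the population's animals are called (the rest
#' missing) and `round(pct/100 * 2n)` alternate alleles are assigned as
#' heterozygous carriers. Indel alleles printed as `-` are converted to
#' anchor-base VCF style.
#'
#' @param tab Tibble in the shape of [high_frequency_lof()].
#' @param manifest Optional manifest. By default one is sized from the
#'   table itself (the largest genotyped count printed per population),
#'   since the printed per-variant counts, not the nominal cohort size,
#'   determine how many callable animals each population must offer.
#' @return List: `cohort`, `calls`.
#' @export
reconstruct_reference_hf <- function(tab = high_frequency_lof(),
                                     manifest = NULL) {
  if (is.null(manifest)) {
    sizes <- c(chinese_rhesus = max(20L, max(tab$n_chinese)),
               indian_rhesus = max(44L, max(tab$n_indian)),
               cynomolgus = max(32L, max(tab$n_cynomolgus)))
    prefix <- c(chinese_rhesus = "ch", indian_rhesus = "in",
                cynomolgus = "cy")
    manifest <- validate_manifest(dplyr::bind_rows(lapply(
      names(sizes), function(p)
        tibble::tibble(sample_id = sprintf("%s%03d", prefix[[p]],
                                           seq_len(sizes[[p]])),
                       population = p))))
  }
  ids_of <- split(manifest$sample_id, manifest$population)
  pop_cols <- c(chinese_rhesus = "chinese", indian_rhesus = "indian",
                cynomolgus = "cynomolgus")
  vrows <- list(); grows <- list()
  for (i in seq_len(nrow(tab))) {
    parts <- strsplit(tab$position[i], ":", fixed = TRUE)[[1]]
    if (tab$reference[i] == "-") {        # insertion of allele_y
      ref <- "A"; alt <- paste0("A", toupper(tab$allele_y[i]))
    } else if (tab$allele_y[i] == "-") {  # deletion of the reference base
      ref <- paste0("A", toupper(tab$reference[i])); alt <- "A"
    } else {
      ref <- toupper(tab$reference[i]); alt <- toupper(tab$allele_y[i])
    }
    gt <- setNames(rep("./.", nrow(manifest)), manifest$sample_id)
    for (p in names(pop_cols)) {
      n <- tab[[paste0("n_", pop_cols[[p]])]][i]
      pct <- tab[[paste0("y_pct_", pop_cols[[p]])]][i]
      a <- round(pct / 100 * 2 * n)
      called <- ids_of[[p]][seq_len(n)]
      gt[called] <- "0/0"
      if (a > 0) gt[called[seq_len(a)]] <- "0/1"
    }
    vrows[[length(vrows) + 1L]] <- tibble::tibble(
      chrom = parts[1], pos = as.integer(parts[2]), id = ".",
      ref = ref, alt = alt, gene = tab$gene[i],
      consequence = tab$consequence[i])
    grows[[length(grows) + 1L]] <- gt
  }
  variants <- dplyr::bind_rows(vrows)
  cohort <- new_cohort(variants[, c("chrom", "pos", "id", "ref", "alt")],
                       do.call(rbind, grows), manifest)
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  calls <- tibble::tibble(
    key = keys, gene = variants$gene, region = "CDS",
    effect = ifelse(variants$consequence == "Stop gain", "stop_gain",
                    "frameshift"),
    codon_index = NA_integer_, ref_aa = NA_character_,
    alt_aa = NA_character_)
  calls <- calls[match(cohort$variants$key, calls$key), ]
  list(cohort = cohort, calls = calls)
}

#' Cross-species inputs rebuilt from the reference mutation tables
#'
#' Constructs, for every gene in the curated recurrent and shared-position
#' mutation tables, a synthetic ortholog protein pair (identical in the
#' two species, carrying the recorded ancestral residue at each recorded
#' position; clearly a stand-in, since the true sequences are not
#' shipped), the corresponding alignments, the macaque common
#' non-synonymous variants and the human variant rows. Running
#' [match_positions()] on these inputs must recover the printed recurrent
#' and shared-position-divergent sets.
#'
#' @param recurrent Tibble in the shape of [recurrent_mutation_table()].
#' @param divergent Tibble in the shape of [shared_position_table()].
#' @return List: `alignments`, `macaque_common`, `human_rows`.
#' @export
reference_cross_species_inputs <- function(
    recurrent = recurrent_mutation_table(),
    divergent = shared_position_table()) {
  sites <- dplyr::bind_rows(
    tibble::tibble(gene = recurrent$gene, aa_pos = recurrent$aa_pos,
                   aa1 = recurrent$aa1, human_aa2 = recurrent$aa2,
                   macaque_aa2 = recurrent$aa2, maf = recurrent$human_maf),
    tibble::tibble(gene = divergent$gene, aa_pos = divergent$aa_pos,
                   aa1 = divergent$aa1, human_aa2 = divergent$human_aa2,
                   macaque_aa2 = divergent$macaque_aa2,
                   maf = divergent$human_maf))
  alignments <- list()
  for (g in unique(sites$gene)) {
    sub <- sites[sites$gene == g, ]
    len <- max(sub$aa_pos) + 10L
    prot <- strrep("G", len)
    for (j in seq_len(nrow(sub))) {
      substr(prot, sub$aa_pos[j], sub$aa_pos[j]) <- sub$aa1[j]
    }
    alignments[[g]] <- align_proteins(prot, prot, gene = g)
  }
  macaque_common <- tibble::tibble(
    key = paste0("mac:", sites$gene, ":", sites$aa_pos),
    gene = sites$gene, macaque_pos = sites$aa_pos,
    ref_aa = sites$aa1, alt_aa = sites$macaque_aa2)
  human_rows <- tibble::tibble(
    gene = sites$gene, aa_pos = sites$aa_pos, aa1 = sites$aa1,
    aa2 = sites$human_aa2, coords = ".", dbsnp = ".", maf = sites$maf)
  list(alignments = alignments, macaque_common = macaque_common,
       human_rows = human_rows)
}

#' The study's default sample manifest
#'
#' 20 Chinese-origin rhesus, 44 Indian-origin rhesus and 32 cynomolgus
#' macaques.
#' @return Manifest tibble.
#' @export
default_manifest <- function() {
  validate_manifest(dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("ch%03d", 1:20),
                   population = "chinese_rhesus"),
    tibble::tibble(sample_id = sprintf("in%03d", 1:44),
                   population = "indian_rhesus"),
    tibble::tibble(sample_id = sprintf("cy%03d", 1:32),
                   population = "cynomolgus")))
}
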