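#' Match common human and macaque variants at aligned residues
#'
#' For every gene with an alignment, pairs each common human variant
#' (allele frequency above threshold, pre-filtered) with each common
#' macaque non-synonymous variant at the same aligned residue. A match
#' requires a gapless alignment column whose ancestral amino acid is the
#' same in both species; it is *recurrent* when the derived amino acids
#' also agree and *shared_position_divergent* otherwise. Positions are
#' numbered on the human protein.
#'
#' @param human_common Tibble from [filter_human_common()] (`gene`,
#'   `aa_pos`, `aa1`, `aa2`, `maf`, ...).
#' @param macaque_common Tibble of common non-synonymous macaque variants:
#'   `key`, `gene`, `macaque_pos`, `ref_aa`, `alt_aa`, and optionally
#'   per-population frequency columns.
#' @param alignments Named list of `protein_alignment`s by gene.
#' @return Tibble of matches: `gene`, `aa_pos` (human), `macaque_pos`,
#'   `aa1`, `human_aa2`, `macaque_aa2`, `class`, `human_maf`, `key`.
#' @export
match_positions <- function(human_common, macaque_common, alignments) {
  out <- list()
  for (g in unique(macaque_common$gene)) {
    aln <- alignments[[g]]
    if (is.null(aln)) next  # no alignment for this gene: skipped
    mp <- aln$map
    mac <- macaque_common[macaque_common$gene == g, , drop = FALSE]
    hum <- human_common[human_common$gene == g, , drop = FALSE]
    if (!nrow(hum)) next
    for (i in seq_len(nrow(mac))) {
      idx <- match(mac$macaque_pos[i], mp$macaque_pos)
      if (is.na(idx)) next  # macaque residue opposite a gap
      hpos <- mp$human_pos[idx]
      hits <- hum[hum$aa_pos == hpos, , drop = FALSE]
      for (j in seq_len(nrow(hits))) {
        if (hits$aa1[j] != mac$ref_aa[i]) next  # ancestral residue differs
        cls <- if (hits$aa2[j] == mac$alt_aa[i]) "recurrent"
               else "shared_position_divergent"
        out[[length(out) + 1L]] <- tibble::tibble(
          gene = g, aa_pos = hpos, macaque_pos = mac$macaque_pos[i],
          aa1 = hits$aa1[j], human_aa2 = hits$aa2[j],
          macaque_aa2 = mac$alt_aa[i], class = cls,
          human_maf = hits$maf[j], key = mac$key[i])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(gene = character(), aa_pos = integer(),
                          macaque_pos = integer(), aa1 = character(),
                          human_aa2 = character(), macaque_aa2 = character(),
                          class = character(), human_maf = double(),
                          key = character()))
  }
  dplyr::bind_rows(out)
}

#' Gene + domain co-occurrence of common variation in the two species
#'
#' One record per (gene, domain class) containing at least one common
#' non-synonymous human variant and at least one common non-synonymous
#' macaque variant, with the variant lists and summary counts.
#'
#' @param human_common Human common variants with a `domain` column (human
#'   domain of `aa_pos`).
#' @param macaque_common Macaque common non-synonymous variants with a
#'   `domain` column (transferred macaque domain of `macaque_pos`).
#' @return List: `instances` (tibble `gene`, `domain`, `human_variants`,
#'   `macaque_variants` list-columns, `n_human`, `n_macaque`),
#'   `by_domain` (tibble `domain`, `instances`, `share`), `n_genes`.
#' @export
domain_cooccurrence <- function(human_common, macaque_common) {
  hk <- human_common[!is.na(human_common$domain), , drop = FALSE]
  mk <- macaque_common[!is.na(macaque_common$domain), , drop = FALSE]
  hg <- dplyr::distinct(hk, .data$gene, .data$domain)
  mg <- dplyr::distinct(mk, .data$gene, .data$domain)
  both <- dplyr::inner_join(hg, mg, by = c("gene", "domain"))
  instances <- lapply(seq_len(nrow(both)), function(i) {
    g <- both$gene[i]; d <- both$domain[i]
    hv <- hk[hk$gene == g & hk$domain == d, , drop = FALSE]
    mv <- mk[mk$gene == g & mk$domain == d, , drop = FALSE]
    tibble::tibble(gene = g, domain = d,
                   human_variants = list(hv), macaque_variants = list(mv),
                   n_human = nrow(hv), n_macaque = nrow(mv))
  })
  instances <- if (length(instances)) dplyr::bind_rows(instances) else
    tibble::tibble(gene = character(), domain = character(),
                   human_variants = list(), macaque_variants = list(),
                   n_human = integer(), n_macaque = integer())
  by_domain <- tibble::tibble(
    domain = gpcr_domain_classes,
    instances = vapply(gpcr_domain_classes, function(d)
      sum(instances$domain == d), integer(1)))
  by_domain$share <- if (nrow(instances))
    by_domain$instances / nrow(instances) else NA_real_
  list(instances = instances, by_domain = by_domain,
       n_genes = length(unique(instances$gene)))
}
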