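#' Transfer human domain intervals onto the macaque protein
#'
#' Each human interval is transliterated to the span `[min, max]` of the
#' macaque positions of its aligned residues. Boundary residues opposite
#' gaps shrink the transferred interval inward; intervals aligned entirely
#' to gaps are flagged unmapped.
#'
#' @param alignment A `protein_alignment` (human vs macaque).
#' @param human_domains Tibble `gene`, `domain`, `start`, `end` for one
#'   gene (human residue coordinates).
#' @return Tibble: `gene`, `domain`, `start`, `end` (macaque coordinates;
#'   NA when unmapped), `mapped`, `residues`.
#' @export
transfer_domains <- function(alignment, human_domains) {
  mp <- alignment$map
  out <- lapply(seq_len(nrow(human_domains)), function(i) {
    d <- human_domains[i, ]
    hits <- mp$macaque_pos[mp$human_pos >= d$start & mp$human_pos <= d$end]
    if (length(hits) == 0L) {
      tibble::tibble(gene = d$gene, domain = d$domain,
                     start = NA_integer_, end = NA_integer_,
                     mapped = FALSE, residues = 0L)
    } else {
      tibble::tibble(gene = d$gene, domain = d$domain,
                     start = min(hits), end = max(hits), mapped = TRUE,
                     residues = max(hits) - min(hits) + 1L)
    }
  })
  res <- dplyr::bind_rows(out)
  mapped <- res[res$mapped, , drop = FALSE]
  if (nrow(mapped) > 1) {
    mapped <- mapped[order(mapped$start), ]
    if (any(mapped$start[-1] <= mapped$end[-nrow(mapped)])) {
      stop("transfer error: transferred domain intervals overlap")
    }
  }
  res
}

# domain class of macaque residue positions given a transferred annotation
domain_of_position <- function(positions, macaque_domains) {
  md <- macaque_domains[macaque_domains$mapped, , drop = FALSE]
  vapply(positions, function(p) {
    hit <- which(md$start <= p & md$end >= p)
    if (length(hit)) md$domain[hit[1]] else NA_character_
  }, character(1))
}

#' Substitute fixed alternate alleles into a reference CDS
#'
#' Builds the macaque consensus coding sequence: wherever a variant's
#' alternate allele is fixed — frequency 1.0 among called genotypes in
#' every population with data (missing genotypes do not block fixation) —
#' the alternate replaces the reference. Polymorphic sites keep the
#' reference allele. A fixed indel that breaks the reading frame flags the
#' gene for exclusion from divergence.
#'
#' @param reference_cds Coding-strand CDS sequence of the gene.
#' @param gene One row of a gene-model tibble.
#' @param cohort A `gpcr_cohort` (for genotypes).
#' @param calls Annotation tibble restricted to this gene's CDS variants.
#' @return List: `cds`, `protein`, `frame_ok`, `fixed_keys`.
#' @export
refine_consensus <- function(reference_cds, gene, cohort, calls) {
  counts <- count_alleles(cohort)
  fixed_tbl <- counts |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      fixed = sum(.data$n) > 0 &&
        all(.data$a[.data$n > 0] == 2 * .data$n[.data$n > 0]),
      .groups = "drop")
  keys <- intersect(calls$key[calls$region == "CDS"],
                    fixed_tbl$key[fixed_tbl$fixed])
  v <- cohort$variants[cohort$variants$key %in% keys, , drop = FALSE]
  frame_ok <- TRUE
  if (any(v$vclass != "SNV")) {
    shift <- sum((nchar(v$alt) - nchar(v$ref))[v$vclass != "SNV"])
    if (shift %% 3L != 0L) frame_ok <- FALSE
    v <- v[v$vclass == "SNV", , drop = FALSE]  # substitutions only below
  }
  cds <- reference_cds
  if (nrow(v)) {
    cmap <- cds_coordinate_map(gene)
    for (i in seq_len(nrow(v))) {
      cpos <- cmap[as.character(v$pos[i])]
      alt <- if (gene$strand == "-") revcomp(v$alt[i]) else v$alt[i]
      substr(cds, cpos, cpos) <- alt
    }
  }
  prot <- sub("\\*$", "", translate_dna(cds))
  list(cds = cds, protein = prot, frame_ok = frame_ok, fixed_keys = keys)
}

#' Fixed coding differences between the macaque consensus and the human
#' ortholog
#'
#' Walks the aligned residues of the two proteins; at every aligned codon
#' pair that differs in nucleotide sequence and is monomorphic in the
#' macaque cohort, emits a fixed difference classified synonymous (same
#' amino acid) or non-synonymous.
#'
#' @param consensus_cds Macaque consensus CDS (coding strand).
#' @param human_cds Human CDS.
#' @param alignment `protein_alignment` of the two proteins (human first).
#' @param polymorphic_codons Integer vector of macaque codon indices
#'   carrying any polymorphism (excluded from divergence).
#' @param gene Gene id carried on the result.
#' @return Tibble: `gene`, `macaque_codon`, `human_codon_seq`,
#'   `macaque_codon_seq`, `kind`.
#' @export
fixed_differences <- function(consensus_cds, human_cds, alignment,
                              polymorphic_codons = integer(),
                              gene = NA_character_) {
  mp <- alignment$map
  n_mac <- nchar(consensus_cds) %/% 3L
  n_hum <- nchar(human_cds) %/% 3L
  out <- list()
  for (i in seq_len(nrow(mp))) {
    m <- mp$macaque_pos[i]; h <- mp$human_pos[i]
    if (m > n_mac || h > n_hum) next
    if (m %in% polymorphic_codons) next
    mc <- substr(consensus_cds, 3L * m - 2L, 3L * m)
    hc <- substr(human_cds, 3L * h - 2L, 3L * h)
    if (mc == hc) next
    kind <- if (codon_aa(mc) == codon_aa(hc)) "synonymous" else "non_synonymous"
    out[[length(out) + 1L]] <- tibble::tibble(
      gene = gene, macaque_codon = m, human_codon_seq = hc,
      macaque_codon_seq = mc, kind = kind)
  }
  dplyr::bind_rows(out) |>
    (\(d) if (nrow(d)) d else tibble::tibble(
      gene = character(), macaque_codon = integer(),
      human_codon_seq = character(), macaque_codon_seq = character(),
      kind = character()))()
}

#' Per-domain event counts and per-residue densities
#'
#' Pools events (polymorphisms or fixed differences, already restricted to
#' one stratum) over all genes and divides per-class counts by the total
#' residues annotated to each class. Events at macaque positions covered by
#' no mapped domain are tallied under class `"unassigned"` with NA density.
#'
#' @param events Tibble with columns `gene`, `macaque_pos`.
#' @param macaque_domains Tibble of transferred domains over all genes
#'   (rows from [transfer_domains()]).
#' @param stratum Label carried on the output (e.g. "singleton_nonsyn").
#' @return Tibble: `stratum`, `domain`, `residues`, `events`, `density`.
#' @export
domain_density <- function(events, macaque_domains, stratum = NA_character_) {
  md <- macaque_domains[macaque_domains$mapped, , drop = FALSE]
  residues <- vapply(gpcr_domain_classes, function(cl)
    sum(md$residues[md$domain == cl]), integer(1))
  cls <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    sub <- md[md$gene == events$gene[i], , drop = FALSE]
    hit <- which(sub$start <= events$macaque_pos[i] &
                 sub$end >= events$macaque_pos[i])
    cls[i] <- if (length(hit)) sub$domain[hit[1]] else "unassigned"
  }
  counts <- vapply(gpcr_domain_classes, function(cl) sum(cls == cl),
                   integer(1))
  out <- tibble::tibble(
    stratum = stratum, domain = gpcr_domain_classes,
    residues = unname(residues), events = unname(counts),
    density = unname(ifelse(residues > 0, counts / residues, NA_real_)))
  if (any(cls == "unassigned")) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      stratum = stratum, domain = "unassigned", residues = NA_integer_,
      events = sum(cls == "unassigned"), density = NA_real_))
  }
  out
}

#' Build a human domain table from layout fractions
#'
#' Converts per-class length fractions (in topological order, summing to 1)
#' into contiguous 1-based residue intervals over a protein of the given
#' length. Used by the simulator and handy for toy examples.
#'
#' @param gene Gene id.
#' @param protein_length Protein length in residues.
#' @param fractions Named numeric vector over [gpcr_domain_classes].
#' @return Tibble `gene`, `domain`, `start`, `end`.
#' @export
layout_domains <- function(gene, protein_length,
                           fractions = default_domain_fractions()) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            setequal(names(fractions), gpcr_domain_classes))
  fractions <- fractions[gpcr_domain_classes]
  ends <- round(cumsum(fractions) * protein_length)
  starts <- c(1L, head(ends, -1) + 1L)
  keep <- ends >= starts
  tibble::tibble(gene = gene, domain = gpcr_domain_classes[keep],
                 start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

#' Default GPCR domain-length fractions
#'
#' A generic seven-transmembrane layout: long N- and C-termini, seven
#' transmembrane helices of ~6% each, a long third intracellular loop and
#' short remaining loops.
#' @return Named numeric vector over [gpcr_domain_classes], summing to 1.
#' @export
default_domain_fractions <- function() {
  c(Nterm = 0.15, TM1 = 0.06, ICL1 = 0.02, TM2 = 0.06, ECL1 = 0.02,
    TM3 = 0.06, ICL2 = 0.02, TM4 = 0.06, ECL2 = 0.04, TM5 = 0.06,
    ICL3 = 0.10, TM6 = 0.06, ECL3 = 0.02, TM7 = 0.06, Cterm = 0.21)
}
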