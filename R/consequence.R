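#' Map a genomic position range onto a gene model's region classes
#'
#' Region precedence within the gene span is CDS > UTR > intron; positions
#' outside the exon span but within `flank` bp are upstream or downstream
#' according to strand. Indels are located by the span of their reference
#' allele and classified CDS if any overlap with a CDS interval exists.
#'
#' @param pos 1-based start of the variant's reference allele.
#' @param ref Reference allele string (its width defines the span).
#' @param gene One row of a gene-model tibble (see [read_gene_models()]).
#' @return One of `"CDS"`, `"5'UTR"`, `"3'UTR"`, `"intron"`, `"upstream"`,
#'   `"downstream"`, or `NA` if the variant lies outside gene +/- flank.
#' @export
map_to_region <- function(pos, ref, gene) {
  lo <- pos
  hi <- pos + max(nchar(ref) - 1L, 0L)
  overlaps <- function(tbl) {
    tbl <- tbl[[1]]
    !is.null(tbl) && nrow(tbl) > 0 && any(lo <= tbl$end & hi >= tbl$start)
  }
  gs <- gene$gene_start; ge <- gene$gene_end
  if (hi >= gs && lo <= ge) {
    if (overlaps(gene$cds)) return("CDS")
    if (overlaps(gene$utr5)) return("5'UTR")
    if (overlaps(gene$utr3)) return("3'UTR")
    if (overlaps(gene$exons)) {
      # exonic but not CDS/UTR-annotated: fall back on side of the CDS
      cds <- gene$cds[[1]]
      if (nrow(cds) == 0) return("intron")
      before <- hi < min(cds$start)
      return(if ((gene$strand == "+") == before) "5'UTR" else "3'UTR")
    }
    return("intron")
  }
  fl <- gene$flank
  if (hi >= gs - fl && lo < gs) {
    return(if (gene$strand == "+") "upstream" else "downstream")
  }
  if (lo <= ge + fl && hi > ge) {
    return(if (gene$strand == "+") "downstream" else "upstream")
  }
  NA_character_
}

# genomic position -> CDS coordinate map (named int vector: genomic -> cds)
cds_coordinate_map <- function(gene) {
  cds <- gene$cds[[1]]
  if (gene$strand == "+") {
    genomic <- unlist(lapply(seq_len(nrow(cds)),
                             function(j) cds$start[j]:cds$end[j]))
  } else {
    genomic <- unlist(lapply(seq_len(nrow(cds)),
                             function(j) cds$end[j]:cds$start[j]))
  }
  setNames(seq_along(genomic), genomic)
}

#' Annotate the coding effect of a variant inside a CDS
#'
#' SNVs are evaluated on the coding strand (alleles reverse-complemented
#' for minus-strand genes): the reference and alternate codons are
#' translated with the standard genetic code; identical amino acids are
#' synonymous, an alternate stop is a stop gain, a lost reference stop is a
#' stop loss, anything else non-synonymous. Indels are frameshifts when the
#' length difference is not a multiple of 3, in-frame indels otherwise.
#'
#' @param variant One-row tibble (or list) with `pos`, `ref`, `alt`,
#'   `vclass`.
#' @param gene One row of a gene-model tibble.
#' @param cds_sequence Spliced coding-strand CDS sequence of the gene.
#' @return A list with `effect`, `codon_index`, `ref_aa`, `alt_aa`.
#' @export
annotate_coding <- function(variant, gene, cds_sequence) {
  if (variant$vclass != "SNV") {
    eff <- if (abs(nchar(variant$ref) - nchar(variant$alt)) %% 3L != 0L) {
      "frameshift"
    } else "inframe_indel"
    return(list(effect = eff, codon_index = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  }
  cmap <- cds_coordinate_map(gene)
  cpos <- unname(cmap[as.character(variant$pos)])
  if (is.na(cpos)) {
    stop("variant position ", variant$pos, " not in CDS of ", gene$gene_id)
  }
  ref <- variant$ref; alt <- variant$alt
  if (gene$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  if (substr(cds_sequence, cpos, cpos) != ref) {
    stop("reference mismatch at CDS position ", cpos, " of ", gene$gene_id,
         ": CDS has '", substr(cds_sequence, cpos, cpos),
         "', variant ref is '", ref, "'")
  }
  ci <- (cpos - 1L) %/% 3L + 1L
  off <- (cpos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_sequence, 3L * ci - 2L, 3L * ci)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt
  ref_aa <- codon_aa(ref_codon)
  alt_aa <- codon_aa(alt_codon)
  effect <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "non_synonymous"
  list(effect = effect, codon_index = ci, ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Annotate every variant of a cohort against a set of gene models
#'
#' Assigns each variant the region of the gene model on its chromosome and,
#' for CDS variants, the coding effect. Variants outside every gene +/-
#' flank are skipped (absent from the output).
#'
#' @param cohort A `gpcr_cohort`.
#' @param models Gene-model tibble (one canonical transcript per gene).
#' @param cds_seqs Named character vector of spliced coding-strand CDS
#'   sequences, names = gene ids.
#' @return Tibble: `key`, `gene`, `region`, `effect`, `codon_index`,
#'   `ref_aa`, `alt_aa`.
#' @export
annotate_variants <- function(cohort, models, cds_seqs) {
  v <- cohort$variants
  out <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    genes <- models[models$chrom == v$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      region <- map_to_region(v$pos[i], v$ref[i], g)
      if (is.na(region)) next
      if (region == "CDS") {
        cc <- annotate_coding(v[i, ], g, cds_seqs[[g$gene_id]])
      } else {
        cc <- list(effect = "none", codon_index = NA_integer_,
                   ref_aa = NA_character_, alt_aa = NA_character_)
      }
      out[[i]] <- tibble::tibble(
        key = v$key[i], gene = g$gene_id, region = region,
        effect = cc$effect, codon_index = cc$codon_index,
        ref_aa = cc$ref_aa, alt_aa = cc$alt_aa)
      break
    }
  }
  empty <- tibble::tibble(key = character(), gene = character(),
                          region = character(), effect = character(),
                          codon_index = integer(), ref_aa = character(),
                          alt_aa = character())
  dplyr::bind_rows(c(list(empty), out))
}

#' Tabulate annotation categories split by singleton/common status
#'
#' Crosses each annotated, polymorphic variant's category (non-coding
#' region name, or the coding effect for CDS variants) with its frequency
#' class, and reports the singleton percentage per category. Monomorphic
#' variants are excluded.
#'
#' @param calls Annotation tibble from [annotate_variants()].
#' @param freq_classes Tibble `key`, `class` from [classify_frequency()].
#' @return Tibble: `category`, `singleton`, `common`, `total`,
#'   `singleton_pct`.
#' @export
tabulate_categories <- function(calls, freq_classes) {
  lv <- c("upstream", "5'UTR", "synonymous", "non_synonymous", "stop_gain",
          "stop_loss", "frameshift", "inframe_indel", "intron", "3'UTR",
          "downstream")
  if (nrow(calls) == 0L) {
    return(tibble::tibble(category = character(), singleton = integer(),
                          common = integer(), total = integer(),
                          singleton_pct = double()))
  }
  missing <- setdiff(calls$key, freq_classes$key)
  if (length(missing)) {
    stop("consistency error: variants lack a frequency class: ",
         paste(head(missing, 5), collapse = ", "))
  }
  df <- dplyr::inner_join(calls, freq_classes, by = "key") |>
    dplyr::filter(.data$class != "monomorphic") |>
    dplyr::mutate(category = ifelse(.data$region == "CDS", .data$effect,
                                    .data$region))
  df |>
    dplyr::count(.data$category, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (is.null(d$singleton)) d$singleton <- 0L
      if (is.null(d$common)) d$common <- 0L
      d
    })() |>
    dplyr::mutate(total = .data$singleton + .data$common,
                  singleton_pct = 100 * .data$singleton / .data$total) |>
    dplyr::arrange(match(.data$category, lv)) |>
    dplyr::select("category", "singleton", "common", "total", "singleton_pct")
}
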