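#' Global pairwise alignment of a human and a macaque ortholog protein
#'
#' End-to-end (Needleman-Wunsch) alignment under BLOSUM62 with affine gap
#' penalties; a gap of length L costs `gap_open + L * gap_extend`. The
#' residue map pairs human and macaque positions at match/mismatch columns
#' only and is strictly increasing in both coordinates.
#'
#' @param human_seq,macaque_seq Ungapped amino-acid sequences.
#' @param gene Optional gene id carried on the result.
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 0.5).
#' @return An object of class `protein_alignment`: list with `gene`,
#'   `human_gapped`, `macaque_gapped`, `score`, and `map` (tibble
#'   `human_pos`, `macaque_pos`, `human_aa`, `macaque_aa`).
#' @export
align_proteins <- function(human_seq, macaque_seq, gene = NA_character_,
                           gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(human_seq) || !nzchar(macaque_seq)) {
    stop("input error: empty protein sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(human_seq), Biostrings::AAString(macaque_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  hg <- as.character(Biostrings::alignedPattern(aln))
  mg <- as.character(Biostrings::alignedSubject(aln))
  out <- structure(
    list(gene = gene, human_gapped = hg, macaque_gapped = mg,
         score = Biostrings::score(aln),
         map = residue_map(hg, mg)),
    class = "protein_alignment")
  validate_alignment(out, human_seq, macaque_seq)
  out
}

# build the residue map from two gapped strings
residue_map <- function(human_gapped, macaque_gapped) {
  h <- strsplit(human_gapped, "")[[1]]
  m <- strsplit(macaque_gapped, "")[[1]]
  stopifnot(length(h) == length(m))
  hp <- cumsum(h != "-")
  mp <- cumsum(m != "-")
  keep <- h != "-" & m != "-"
  tibble::tibble(human_pos = hp[keep], macaque_pos = mp[keep],
                 human_aa = h[keep], macaque_aa = m[keep])
}

validate_alignment <- function(aln, human_seq, macaque_seq) {
  stopifnot(gsub("-", "", aln$human_gapped, fixed = TRUE) == human_seq,
            gsub("-", "", aln$macaque_gapped, fixed = TRUE) == macaque_seq)
  mp <- aln$map
  if (nrow(mp) > 1) {
    stopifnot(all(diff(mp$human_pos) > 0), all(diff(mp$macaque_pos) > 0))
  }
  stopifnot(!anyDuplicated(mp$human_pos), !anyDuplicated(mp$macaque_pos))
  invisible(aln)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment>", if (!is.na(x$gene)) x$gene else "",
      " score=", x$score, " columns=", nchar(x$human_gapped),
      " mapped=", nrow(x$map), "\n", sep = "")
  invisible(x)
}

#' Align all ortholog pairs of a study
#'
#' @param human_prot,macaque_prot Named character vectors of protein
#'   sequences (names = gene ids).
#' @param genes Gene ids to align (default: intersection of names).
#' @param ... Passed to [align_proteins()].
#' @return Named list of `protein_alignment` objects.
#' @export
align_ortholog_set <- function(human_prot, macaque_prot,
                               genes = intersect(names(human_prot),
                                                 names(macaque_prot)),
                               ...) {
  setNames(lapply(genes, function(g)
    align_proteins(human_prot[[g]], macaque_prot[[g]], gene = g, ...)),
    genes)
}
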