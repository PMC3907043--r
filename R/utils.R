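#' Canonical key identifying a biallelic variant
#'
#' Variants are identified throughout the pipeline by the string
#' `chrom:pos:ref:alt`. Every table that refers to a variant carries this key.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the reference-anchor base.
#' @param ref Reference allele string.
#' @param alt Alternate allele string.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Classify an allele pair as SNV, insertion or deletion
#'
#' @param ref,alt Allele strings (one alternate allele).
#' @return Character vector in `c("SNV", "insertion", "deletion")`.
#' @export
variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(alt) > nchar(ref) ~ "insertion",
    TRUE ~ "deletion"
  )
}

# reverse complement for plain character DNA
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate a DNA string (multiple of 3) to amino acids, "*" for stop
translate_dna <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) %% 3L != 0L) stop("sequence length not a multiple of 3")
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }, character(1), USE.NAMES = FALSE)
}

# single-codon translation via the standard code
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
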