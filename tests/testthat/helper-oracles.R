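# Independent oracles used to cross-check the implementation.

# translate a DNA string codon-by-codon via the standard code table
oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# effect of a coding SNV by retranslating the *entire* mutated CDS and
# diffing the two protein sequences (independent of the per-codon shortcut)
oracle_snv_effect <- function(cds, cds_idx, alt_base) {
  mut <- cds
  substr(mut, cds_idx, cds_idx) <- alt_base
  p_ref <- oracle_translate(cds)
  p_mut <- oracle_translate(mut)
  if (p_ref == p_mut) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_mut, "")[[1]])[1]
  ref_aa <- substr(p_ref, d, d)
  mut_aa <- substr(p_mut, d, d)
  if (mut_aa == "*") "stop_gain" else if (ref_aa == "*") "stop_loss"
  else "non_synonymous"
}

# Gotoh dynamic-programming oracle for global affine-gap alignment score,
# with the same convention as the implementation: a gap of length L costs
# open + L * extend.
oracle_align_score <- function(a, b, open = 10, ext = 0.5) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  mat <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (A residue over gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_protein <- function(len) {
  paste(sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ""),
               len, replace = TRUE), collapse = "")
}

random_sense_cds <- function(n_codons, terminal_stop = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste0(paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         if (terminal_stop) "TAA" else "")
}
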