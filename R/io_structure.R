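#' Export genotypes in STRUCTURE two-rows-per-individual format
#'
#' Each individual contributes two rows (one chromosome per row): sample id,
#' a numeric population code, then one allele per locus coded 1 (reference)
#' or 2 (alternate); missing genotypes are coded -9 on both rows. Locus
#' order follows the cohort's variant order; a sidecar `<path>.loci` file
#' lists the locus (variant) keys, one per line.
#'
#' @param cohort A `gpcr_cohort`.
#' @param path Output path for the STRUCTURE input file.
#' @return `path`, invisibly.
#' @export
write_structure_input <- function(cohort, path) {
  gt <- cohort$genotypes
  man <- cohort$manifest
  pop_code <- match(man$population, gpcr_populations)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(man))) {
    g <- gt[, i]
    a1 <- ifelse(g == "./.", -9L, ifelse(g == "1/1", 2L, 1L))
    a2 <- ifelse(g == "./.", -9L, ifelse(g == "0/0", 1L, 2L))
    if (nrow(gt) == 0L) { a1 <- integer(0); a2 <- integer(0) }
    writeLines(paste(c(man$sample_id[i], pop_code[i], a1), collapse = " "), con)
    writeLines(paste(c(man$sample_id[i], pop_code[i], a2), collapse = " "), con)
  }
  writeLines(rownames(gt) %||% character(0), paste0(path, ".loci"))
  invisible(path)
}
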