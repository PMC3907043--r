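#' Construct a cohort object from a variant table and genotype matrix
#'
#' A cohort bundles the biallelic variant records with the per-sample
#' genotype matrix. Genotypes are diploid strings in
#' `c("0/0", "0/1", "1/1", "./.")`; rows are variants (named by
#' [variant_key()]), columns are samples in manifest order.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (and optionally `vclass`, `key`; recomputed if absent).
#' @param genotypes Character matrix, one row per variant, one column per
#'   manifest sample.
#' @param manifest Sample manifest (see [validate_manifest()]).
#' @return An object of class `gpcr_cohort`.
#' @export
new_cohort <- function(variants, genotypes, manifest) {
  manifest <- validate_manifest(manifest)
  variants <- tibble::as_tibble(variants)
  if (!("id" %in% names(variants))) variants$id <- "."
  variants$vclass <- variant_class(variants$ref, variants$alt)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (any(variants$ref == variants$alt)) stop("ref == alt in variant table")
  if (any(variants$pos < 1L)) stop("variant pos < 1")
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(genotypes) == nrow(variants))
  if (is.null(colnames(genotypes))) colnames(genotypes) <- manifest$sample_id
  missing_samples <- setdiff(manifest$sample_id, colnames(genotypes))
  if (length(missing_samples)) {
    pad <- matrix("./.", nrow(genotypes), length(missing_samples),
                  dimnames = list(NULL, missing_samples))
    genotypes <- cbind(genotypes, pad)
  }
  genotypes <- genotypes[, manifest$sample_id, drop = FALSE]
  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]
  rownames(genotypes) <- variants$key
  structure(list(variants = variants, genotypes = genotypes,
                 manifest = manifest),
            class = "gpcr_cohort")
}

#' @export
print.gpcr_cohort <- function(x, ...) {
  cat("<gpcr_cohort> ", nrow(x$variants), " variants x ",
      nrow(x$manifest), " samples (",
      paste(sprintf("%s: %d", names(table(x$manifest$population)),
                    as.integer(table(x$manifest$population))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# normalise a raw GT field: strip phase, keep a/b
normalise_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[is.na(gt) | gt %in% c(".", "./.", ".|.")] <- "./."
  gt
}

#' Read a multi-sample VCF into a cohort
#'
#' Multiallelic sites are decomposed into one biallelic record per alternate
#' allele: a sample carrying alternate *k* is heterozygous (or homozygous)
#' for record *k* and `0/0` for the site's other records. Records are sorted
#' by (chrom, pos) and genotype columns aligned to manifest order; manifest
#' samples absent from the VCF receive missing genotypes.
#'
#' @param path Path to a VCF 4.x file.
#' @param manifest Sample manifest; VCF sample columns must be a subset of
#'   its `sample_id`s.
#' @return A `gpcr_cohort`.
#' @export
read_vcf <- function(path, manifest) {
  manifest <- validate_manifest(manifest)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in '", path, "': ",
                             conditionMessage(e))
  )
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) {  # single-record VCFs drop to a vector
    fix_mat <- matrix(fix_mat, nrow = 1,
                      dimnames = list(NULL, names(fix_mat)))
  }
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(new_cohort(
      tibble::tibble(chrom = character(), pos = integer(), id = character(),
                     ref = character(), alt = character()),
      matrix(character(), 0, nrow(manifest),
             dimnames = list(NULL, manifest$sample_id)),
      manifest))
  }
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  extra <- setdiff(samples, manifest$sample_id)
  if (length(extra)) {
    stop("manifest error: VCF sample(s) not in manifest: ",
         paste(extra, collapse = ", "))
  }
  gt <- apply(gt_raw[, -1, drop = FALSE], 2, normalise_gt)
  gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, samples))

  rec_chrom <- character(); rec_pos <- integer(); rec_id <- character()
  rec_ref <- character(); rec_alt <- character()
  rec_gt <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    row_gt <- gt[i, ]
    al <- strsplit(row_gt, "/", fixed = TRUE)
    for (k in seq_along(alts)) {
      gk <- vapply(al, function(ab) {
        if (length(ab) != 2L || any(ab == ".")) return("./.")
        n_alt <- sum(ab == as.character(k))
        c("0/0", "0/1", "1/1")[n_alt + 1L]
      }, character(1))
      rec_chrom <- c(rec_chrom, fix$CHROM[i])
      rec_pos <- c(rec_pos, as.integer(fix$POS[i]))
      rec_id <- c(rec_id, fix$ID[i] %||% ".")
      rec_ref <- c(rec_ref, fix$REF[i])
      rec_alt <- c(rec_alt, alts[k])
      rec_gt[[length(rec_gt) + 1L]] <- gk
    }
  }
  gmat <- do.call(rbind, rec_gt)
  colnames(gmat) <- samples
  new_cohort(
    tibble::tibble(chrom = rec_chrom, pos = rec_pos,
                   id = ifelse(is.na(rec_id), ".", rec_id),
                   ref = rec_ref, alt = rec_alt),
    gmat, manifest)
}

#' Write a cohort to a plain-text VCF 4.2 file
#'
#' Emits one biallelic record per variant with GT-only genotype columns, so
#' that writing and re-reading a cohort reproduces it exactly.
#'
#' @param cohort A `gpcr_cohort`.
#' @param path Output path.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=macgpcr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cohort$genotypes)), collapse = "\t")), con)
  if (nrow(v)) {
    body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                  "GT", cohort$genotypes)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}
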