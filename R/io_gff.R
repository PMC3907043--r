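#' Read gene models from a GFF3 file
#'
#' Builds one gene model per transcript from gene/mRNA/exon/CDS (and
#' optionally five_prime_UTR/three_prime_UTR) features. Coordinates are kept
#' 1-based and closed. Exon and CDS interval tables are ordered 5'->3' in
#' transcript space, i.e. reversed relative to genomic order on the minus
#' strand. When a gene carries several transcripts the one with the longest
#' CDS is taken as canonical.
#'
#' @param path Path to a GFF3 file.
#' @param flank Upstream/downstream flank length in bp used by region
#'   classification (default 2000).
#' @return A tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `flank`, `cds_len`, `incomplete` (CDS length not a
#'   multiple of 3), and list-columns `exons`, `cds`, `utr5`, `utr3`
#'   (tibbles of `start`, `end` in transcript 5'->3' order).
#' @export
read_gene_models <- function(path, flank = 2000L) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (!nrow(mrna)) stop("structure error: no mRNA/transcript features in ", path)
  models <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    gid <- mrna$Parent[i] %||% tid
    if (is.na(gid)) gid <- tid
    kids <- df[!is.na(df$Parent) & df$Parent == tid, , drop = FALSE]
    strand <- as.character(mrna$strand[i])
    pick <- function(types) {
      k <- kids[kids$type %in% types, c("start", "end"), drop = FALSE]
      k <- k[order(k$start), , drop = FALSE]
      if (strand == "-") k <- k[rev(seq_len(nrow(k))), , drop = FALSE]
      tibble::as_tibble(k)
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    utr5 <- pick("five_prime_UTR")
    utr3 <- pick("three_prime_UTR")
    if (nrow(exons) == 0L) exons <- cds
    # CDS must be contained in exons
    if (nrow(cds)) {
      inside <- vapply(seq_len(nrow(cds)), function(j)
        any(cds$start[j] >= exons$start & cds$end[j] <= exons$end),
        logical(1))
      if (!all(inside)) {
        stop("structure error: CDS outside exon bounds for transcript ", tid)
      }
    }
    cds_len <- sum(cds$end - cds$start + 1L)
    tibble::tibble(
      gene_id = gid, transcript_id = tid,
      chrom = as.character(mrna$seqnames[i]), strand = strand,
      gene_start = min(exons$start), gene_end = max(exons$end),
      flank = as.integer(flank),
      cds_len = cds_len, incomplete = (cds_len %% 3L) != 0L,
      exons = list(exons), cds = list(cds), utr5 = list(utr5),
      utr3 = list(utr3))
  })
  out <- dplyr::bind_rows(models)
  # canonical transcript per gene: longest CDS, ties by transcript id
  out <- out[order(out$gene_id, -out$cds_len, out$transcript_id), ]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()] for the fields the pipeline uses
#' (gene/mRNA/exon/CDS/UTR features); used by the cohort simulator.
#'
#' @param models Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  rows <- list()
  add <- function(chrom, start, end, strand, type, id, parent = NA) {
    attrs <- if (is.na(parent)) paste0("ID=", id)
             else paste0("ID=", id, ";Parent=", parent)
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = chrom, source = "macgpcr", type = type,
      start = start, end = end, score = ".", strand = strand,
      phase = ".", attributes = attrs, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    add(g$chrom, g$gene_start, g$gene_end, g$strand, "gene", g$gene_id)
    add(g$chrom, g$gene_start, g$gene_end, g$strand, "mRNA",
        g$transcript_id, g$gene_id)
    feat <- function(tbl, type, tag) {
      tbl <- tbl[[1]]
      if (!is.null(tbl) && nrow(tbl)) {
        for (j in seq_len(nrow(tbl))) {
          add(g$chrom, tbl$start[j], tbl$end[j], g$strand, type,
              paste0(g$transcript_id, ".", tag, j), g$transcript_id)
        }
      }
    }
    feat(g$exons, "exon", "exon")
    feat(g$cds, "CDS", "cds")
    feat(g$utr5, "five_prime_UTR", "utr5")
    feat(g$utr3, "three_prime_UTR", "utr3")
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
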