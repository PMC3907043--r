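test_that("genomic positions map to the expected region classes", {
  # gene with 5'UTR, two CDS exons, intron, 3'UTR on the plus strand
  gene <- tibble::tibble(
    gene_id = "g", transcript_id = "g.t1", chrom = "chr1", strand = "+",
    gene_start = 1001L, gene_end = 1500L, flank = 2000L, cds_len = 300L,
    incomplete = FALSE,
    exons = list(tibble::tibble(start = c(1001L, 1301L),
                                end = c(1200L, 1500L))),
    cds = list(tibble::tibble(start = c(1051L, 1301L),
                              end = c(1200L, 1450L))),
    utr5 = list(tibble::tibble(start = 1001L, end = 1050L)),
    utr3 = list(tibble::tibble(start = 1451L, end = 1500L)))
  expect_equal(map_to_region(1100L, "A", gene), "CDS")
  expect_equal(map_to_region(1250L, "A", gene), "intron")
  expect_equal(map_to_region(1010L, "A", gene), "5'UTR")
  expect_equal(map_to_region(1460L, "A", gene), "3'UTR")
  expect_equal(map_to_region(501L, "A", gene), "upstream")   # 500 bp 5' of TSS
  expect_equal(map_to_region(1600L, "A", gene), "downstream")
  expect_true(is.na(map_to_region(5000L, "A", gene)))
  # minus strand swaps the flank labels
  gene$strand <- "-"
  expect_equal(map_to_region(501L, "A", gene), "downstream")
  expect_equal(map_to_region(1600L, "A", gene), "upstream")
})

test_that("coding SNVs are classified through the codon table", {
  # CDS: ATG CGA CTG TAA ; codon 2 = CGA (Arg)
  cds <- "ATGCGACTGTAA"
  gene <- toy_gene(cds, start = 101L)
  # C->T at codon-2 position 1 creates TGA: stop gain
  v <- toy_variant(104, "C", "T")
  cc <- annotate_coding(v, gene, cds)
  expect_equal(cc$effect, "stop_gain")
  expect_equal(cc$alt_aa, "*")
  # CTG -> CTA, both Leu: synonymous
  v <- toy_variant(109, "G", "A")
  cc <- annotate_coding(v, gene, cds)
  expect_equal(cc$effect, "synonymous")
  expect_equal(cc$codon_index, 3L)
  # 1-bp insertion: frameshift
  v <- toy_variant(105, "G", "GG")
  expect_equal(annotate_coding(v, gene, cds)$effect, "frameshift")
  # 3-bp deletion: in-frame
  v <- toy_variant(104, "CGAC", "C")
  expect_equal(annotate_coding(v, gene, cds)$effect, "inframe_indel")
  # reference mismatch is an error
  v <- toy_variant(104, "G", "T")
  expect_error(annotate_coding(v, gene, cds), "mismatch")
})

test_that("per-codon shortcut agrees with full-CDS retranslation for every
           SNV of a 30-codon gene", {
  withr::with_seed(11, {
    cds <- random_sense_cds(29)  # 29 codons + stop = 30 codons
    gene <- toy_gene(cds, start = 201L)
    n_checked <- 0L
    for (idx in seq_len(nchar(cds))) {
      ref <- substr(cds, idx, idx)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- toy_variant(200L + idx, ref, alt)
        got <- annotate_coding(v, gene, cds)$effect
        expect_identical(got, oracle_snv_effect(cds, idx, alt))
        n_checked <- n_checked + 1L
      }
    }
    expect_equal(n_checked, 270L)
  })
})

test_that("shortcut matches the retranslation oracle on random genes and
           strands", {
  withr::with_seed(12, {
    for (rep in 1:10) {
      cds <- random_sense_cds(15)
      strand <- sample(c("+", "-"), 1)
      gene <- toy_gene(cds, start = 301L, strand = strand)
      cmap <- macgpcr:::cds_coordinate_map(gene)
      for (idx in sample(nchar(cds), 12)) {
        ref_coding <- substr(cds, idx, idx)
        alt_coding <- sample(setdiff(c("A", "C", "G", "T"), ref_coding), 1)
        gpos <- as.integer(names(cmap))[idx]
        if (strand == "+") {
          v <- toy_variant(gpos, ref_coding, alt_coding)
        } else {
          rc <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
          v <- toy_variant(gpos, rc(ref_coding), rc(alt_coding))
        }
        expect_identical(annotate_coding(v, gene, cds)$effect,
                         oracle_snv_effect(cds, idx, alt_coding))
      }
    }
  })
})

test_that("a gene and its reverse-complement mirror give identical calls", {
  withr::with_seed(13, {
    cds <- random_sense_cds(20)
    gplus <- toy_gene(cds, start = 501L, strand = "+")
    gminus <- toy_gene(cds, start = 501L, strand = "-")
    L <- nchar(cds)
    rc <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
    for (idx in sample(L, 20)) {
      ref <- substr(cds, idx, idx)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      vp <- toy_variant(500L + idx, ref, alt)
      # mirrored variant: genomic position counted from the other end
      vm <- toy_variant(501L + L - idx, rc(ref), rc(alt))
      ep <- annotate_coding(vp, gplus, cds)
      em <- annotate_coding(vm, gminus, cds)
      expect_identical(ep$effect, em$effect)
      expect_identical(ep$codon_index, em$codon_index)
    }
  })
})

test_that("category table is a partition of polymorphic annotated variants", {
  sim <- small_sim()
  calls <- annotate_variants(sim$cohort, sim$models, sim$cds)
  fc <- classify_frequency(sim$cohort)
  tab <- tabulate_categories(calls, fc)
  n_poly <- sum(fc$class != "monomorphic" & fc$key %in% calls$key)
  expect_equal(sum(tab$total), n_poly)
  expect_true(all(tab$singleton + tab$common == tab$total))
  # empty input gives an empty table
  expect_equal(nrow(tabulate_categories(calls[0, ], fc)), 0L)
  # missing frequency class is a consistency error
  expect_error(tabulate_categories(calls, fc[-1, ]), "consistency")
})

test_that("annotation recovers the generator's true regions and effects", {
  sim <- small_sim()
  calls <- annotate_variants(sim$cohort, sim$models, sim$cds)
  truth <- sim$truth$variants
  j <- dplyr::inner_join(calls, truth, by = "key",
                         suffix = c("_est", "_true"))
  expect_equal(nrow(j), nrow(truth))
  expect_identical(j$region_est, j$region_true)
  coding <- !is.na(j$effect_true) & j$effect_true != "none"
  expect_identical(j$effect_est[coding], j$effect_true[coding])
})
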