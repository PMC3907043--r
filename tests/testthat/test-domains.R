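test_that("domain transfer maps, shrinks and flags intervals correctly", {
  # identity alignment: intervals transfer unchanged
  s <- random_protein(60)
  aln <- align_proteins(s, s)
  hd <- tibble::tibble(gene = "g", domain = c("Nterm", "TM1"),
                       start = c(1L, 10L), end = c(9L, 30L))
  td <- transfer_domains(aln, hd)
  expect_equal(td$start, c(1L, 10L))
  expect_equal(td$end, c(9L, 30L))
  expect_true(all(td$mapped))

  # a 2-residue macaque deletion inside a domain shrinks it by 2
  hum <- random_protein(60)
  mac <- paste0(substr(hum, 1, 19), substr(hum, 22, 60))  # drop 20-21
  aln2 <- align_proteins(hum, mac)
  hd2 <- tibble::tibble(gene = "g", domain = "TM3", start = 15L, end = 30L)
  td2 <- transfer_domains(aln2, hd2)
  expect_equal(td2$residues, 14L)

  # a domain aligned entirely to a gap is unmapped
  core1 <- random_protein(30)
  core2 <- random_protein(30)
  hum3 <- paste0(core1, "WWWWWWWW", core2)   # inserted human-only segment
  mac3 <- paste0(core1, core2)
  aln3 <- align_proteins(hum3, mac3)
  hd3 <- tibble::tibble(gene = "g", domain = "ECL2", start = 31L, end = 38L)
  td3 <- transfer_domains(aln3, hd3)
  expect_false(td3$mapped)
  expect_equal(td3$residues, 0L)
})

test_that("consensus refinement substitutes only fixed alternates", {
  man <- tiny_manifest(c(2, 2, 2))
  cds <- "ATGAAACCCGGGTAA"
  gene <- toy_gene(cds, start = 101L)
  v <- dplyr::bind_rows(
    toy_variant(104, "A", "G"),   # fixed in all populations
    toy_variant(107, "C", "T"))   # polymorphic (frequency < 1)
  gt <- rbind(rep("1/1", 6),
              c("0/1", "1/1", "1/1", "1/1", "1/1", "1/1"))
  colnames(gt) <- man$sample_id
  co <- new_cohort(v[, c("chrom", "pos", "ref", "alt")], gt, man)
  calls <- annotate_variants(co, gene, setNames(cds, "G1"))
  cons <- refine_consensus(cds, gene, co, calls)
  expect_equal(cons$cds, "ATGGAACCCGGGTAA")
  expect_true(cons$frame_ok)
  # no fixed alternates: consensus equals the reference
  gt0 <- matrix("0/1", 2, 6, dimnames = list(NULL, man$sample_id))
  co0 <- new_cohort(v[, c("chrom", "pos", "ref", "alt")], gt0, man)
  cons0 <- refine_consensus(cds, gene, co0, calls)
  expect_equal(cons0$cds, cds)
  # missing genotypes do not block fixation
  gtm <- rbind(c("1/1", "./.", "1/1", "1/1", "./.", "1/1"), rep("0/0", 6))
  colnames(gtm) <- man$sample_id
  com <- new_cohort(v[, c("chrom", "pos", "ref", "alt")], gtm, man)
  consm <- refine_consensus(cds, gene, com, calls)
  expect_equal(consm$cds, "ATGGAACCCGGGTAA")
})

test_that("fixed differences are classified by the codon table", {
  mac <- "ATGCGAAAATAA"   # M R K *
  hum <- "ATGCGGAGATAA"   # M R(syn CGA->CGG) R(nonsyn AAA->AGA) *
  aln <- align_proteins(sub("\\*$", "", oracle_translate(hum)),
                        sub("\\*$", "", oracle_translate(mac)))
  fd <- fixed_differences(mac, hum, aln, gene = "g")
  expect_equal(nrow(fd), 2L)
  expect_equal(fd$kind[fd$macaque_codon == 2], "synonymous")
  expect_equal(fd$kind[fd$macaque_codon == 3], "non_synonymous")
  # identical sequences give none; polymorphic codons are excluded
  expect_equal(nrow(fixed_differences(mac, mac, aln)), 0L)
  fd2 <- fixed_differences(mac, hum, aln, polymorphic_codons = 3L)
  expect_equal(fd2$kind, "synonymous")
})

test_that("domain densities count per residue and conserve events", {
  md <- tibble::tibble(gene = "g", domain = c("Nterm", "TM1"),
                       start = c(1L, 101L), end = c(100L, 130L),
                       mapped = TRUE, residues = c(100L, 30L))
  ev <- tibble::tibble(gene = "g", macaque_pos = as.integer(c(1:10, 250)))
  dd <- domain_density(ev, md, "test")
  expect_equal(dd$density[dd$domain == "Nterm"], 0.10)
  expect_equal(sum(dd$events[dd$domain %in% gpcr_domain_classes]), 10L)
  expect_equal(dd$events[dd$domain == "unassigned"], 1L)
  # event conservation across classes
  expect_equal(sum(dd$events), nrow(ev))
})

test_that("domain layouts tile the protein without overlap", {
  d <- layout_domains("g", 300)
  expect_equal(d$start[1], 1L)
  expect_equal(d$end[nrow(d)], 300L)
  expect_true(all(d$start[-1] == d$end[-nrow(d)] + 1L))
  expect_setequal(d$domain, gpcr_domain_classes)
})
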