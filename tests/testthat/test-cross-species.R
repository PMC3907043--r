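test_that("matches classify recurrent vs shared-position-divergent", {
  prot <- paste0(strrep("G", 9), "A", strrep("G", 10))   # A at position 10
  aln <- list(g1 = align_proteins(prot, prot))
  mac <- tibble::tibble(key = "k1", gene = "g1", macaque_pos = 10L,
                        ref_aa = "A", alt_aa = "E")
  hum_rec <- tibble::tibble(gene = "g1", aa_pos = 10L, aa1 = "A", aa2 = "E",
                            maf = 0.02)
  m <- match_positions(hum_rec, mac, aln)
  expect_equal(m$class, "recurrent")
  hum_div <- tibble::tibble(gene = "g1", aa_pos = 10L, aa1 = "A", aa2 = "T",
                            maf = 0.02)
  m2 <- match_positions(hum_div, mac, aln)
  expect_equal(m2$class, "shared_position_divergent")
  # ancestral residue mismatch produces no match
  hum_bad <- tibble::tibble(gene = "g1", aa_pos = 10L, aa1 = "S", aa2 = "E",
                            maf = 0.02)
  expect_equal(nrow(match_positions(hum_bad, mac, aln)), 0L)
  # gene without an alignment is skipped
  mac2 <- mac; mac2$gene <- "g9"
  expect_equal(nrow(match_positions(hum_rec, mac2, aln)), 0L)
})

test_that("recurrent classification is symmetric in the species labels", {
  prot <- paste0("MKT", strrep("L", 5), "RW")
  aln <- list(g = align_proteins(prot, prot))
  mac <- tibble::tibble(key = c("a", "b"), gene = "g",
                        macaque_pos = c(2L, 9L), ref_aa = c("K", "R"),
                        alt_aa = c("N", "H"))
  hum <- tibble::tibble(gene = "g", aa_pos = c(2L, 9L), aa1 = c("K", "R"),
                        aa2 = c("N", "C"), maf = 0.1)
  fwd <- match_positions(hum, mac, aln)
  # swap roles: macaque variants as the "human" table and vice versa
  hum_sw <- tibble::tibble(gene = "g", aa_pos = mac$macaque_pos,
                           aa1 = mac$ref_aa, aa2 = mac$alt_aa, maf = 0.1)
  mac_sw <- tibble::tibble(key = c("x", "y"), gene = "g",
                           macaque_pos = hum$aa_pos, ref_aa = hum$aa1,
                           alt_aa = hum$aa2)
  rev <- match_positions(hum_sw, mac_sw, aln)
  pick <- function(m) sort(paste(m$gene, m$aa_pos, m$class))
  expect_identical(pick(fwd), pick(rev))
  expect_equal(sum(fwd$class == "recurrent"), 1L)
})

test_that("domain co-occurrence requires both species in the same domain", {
  hum <- tibble::tibble(gene = "g", aa_pos = 5L, aa1 = "A", aa2 = "V",
                        maf = 0.05, domain = "Nterm")
  mac_same <- tibble::tibble(key = "k", gene = "g", macaque_pos = 8L,
                             ref_aa = "L", alt_aa = "P", domain = "Nterm")
  mac_diff <- dplyr::mutate(mac_same, domain = "Cterm")
  expect_equal(nrow(domain_cooccurrence(hum, mac_same)$instances), 1L)
  expect_equal(nrow(domain_cooccurrence(hum, mac_diff)$instances), 0L)
  # instance lists are restricted to the matching gene and domain
  inst <- domain_cooccurrence(hum, mac_same)$instances
  expect_equal(inst$n_human, 1L)
  expect_equal(inst$n_macaque, 1L)
})
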