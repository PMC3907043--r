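test_that("the consensus rule is pinned on all 27 call combinations", {
  lv <- c("damaging", "tolerated", "missing")
  grid <- expand.grid(p1 = lv, p2 = lv, p3 = lv,
                      stringsAsFactors = FALSE)
  expected <- c(
    "deleterious", "likely_deleterious", "likely_deleterious",
    "likely_deleterious", "likely_neutral", "ambiguous",
    "likely_deleterious", "ambiguous", "ambiguous",
    "likely_deleterious", "likely_neutral", "ambiguous",
    "likely_neutral", "neutral", "likely_neutral",
    "ambiguous", "likely_neutral", "ambiguous",
    "likely_deleterious", "ambiguous", "ambiguous",
    "ambiguous", "likely_neutral", "ambiguous",
    "ambiguous", "ambiguous", "ambiguous")
  got <- consensus_classify(as.matrix(grid))
  expect_identical(unname(got), expected)
  # matrix and single-vector interfaces agree
  expect_identical(consensus_classify(c("damaging", "tolerated", "missing")),
                   "ambiguous")
})

test_that("eligibility requires a conserved human residue", {
  aln <- align_proteins("MAST", "MAST")
  expect_true(check_eligibility(2L, "A", aln))
  expect_false(check_eligibility(2L, "S", aln))   # residue differs
  # macaque residue opposite a gap is ineligible
  aln2 <- align_proteins("MT", "MKT")             # macaque K unaligned
  expect_false(check_eligibility(2L, "K", aln2))
  expect_true(check_eligibility(3L, "T", aln2))
  # never passes when the aligned human residue differs from macaque ref
  aln3 <- align_proteins("MASTLLK", "MGSTLLK")
  expect_false(check_eligibility(2L, "G", aln3))
})

test_that("damaging fractions count deleterious categories", {
  cats <- c("deleterious", "likely_deleterious", "neutral", "ambiguous",
            NA)
  f <- damaging_fraction(cats)
  expect_equal(f$damaging, 2L)
  expect_equal(f$total, 4L)
  f2 <- damaging_fraction(cats, include_ambiguous = FALSE)
  expect_equal(f2$total, 3L)
  expect_equal(damaging_fraction(rep("neutral", 5))$fraction, 0)
  expect_true(is.na(damaging_fraction(character())$fraction))
})

test_that("stratified damaging fractions are homogeneous when calls are
           frequency-independent", {
  sim <- big_sim()
  truth <- sim$truth$variants
  nonsyn <- truth[truth$effect == "non_synonymous" &
                  truth$freq_class %in% c("singleton", "common"), ]
  aln <- align_ortholog_set(sim$human_prot, sim$macaque_prot)
  eligible <- vapply(seq_len(nrow(nonsyn)), function(i)
    check_eligibility(nonsyn$codon_index[i], nonsyn$ref_aa[i],
                      aln[[nonsyn$gene[i]]]), logical(1))
  tab <- consensus_table(nonsyn$key, eligible, sim$predictions)
  strat <- damaging_by_stratum(tab$category, nonsyn$freq_class)
  strat <- strat[!is.na(strat$fraction), ]
  # two-proportion test: singleton vs common damaging shares equal
  m <- as.matrix(strat[, c("damaging", "total")])
  pt <- prop.test(m[, 1], m[, 2])
  expect_gt(pt$p.value, 0.01)
  # both near the generating rate; wide Monte-Carlo margin
  expect_true(all(abs(strat$fraction - 0.55) < 0.10))
})
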