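test_that("identical sequences align to the identity with diagonal score", {
  s <- "MARNDCEQGH"
  aln <- align_proteins(s, s)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aa <- strsplit(s, "")[[1]]
  expect_equal(aln$score, sum(diag(BLOSUM62[aa, aa])))
  expect_equal(aln$map$human_pos, 1:10)
  expect_equal(aln$map$macaque_pos, 1:10)
})

test_that("a single-residue deletion yields the expected residue map", {
  aln <- align_proteins("MKT", "MT")
  expect_equal(aln$map$human_pos, c(1L, 3L))
  expect_equal(aln$map$macaque_pos, c(1L, 2L))
  expect_error(align_proteins("", "MT"), "empty")
})

test_that("alignment scores equal the exhaustive DP oracle on short pairs", {
  withr::with_seed(21, {
    for (rep in 1:40) {
      a <- random_protein(sample(1:10, 1))
      b <- random_protein(sample(1:10, 1))
      aln <- align_proteins(a, b)
      expect_equal(aln$score, oracle_align_score(a, b), tolerance = 1e-9,
                   label = paste("score for", a, "vs", b))
    }
  })
})

test_that("residue maps are monotone and cover most of near-identical pairs", {
  withr::with_seed(22, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:5) {
      mac <- random_protein(200)
      hum <- strsplit(mac, "")[[1]]
      flip <- sample(200, 10)   # 95% identity
      hum[flip] <- vapply(hum[flip],
                          function(x) sample(setdiff(aas, x), 1), "")
      aln <- align_proteins(paste(hum, collapse = ""), mac)
      expect_true(all(diff(aln$map$human_pos) > 0))
      expect_true(all(diff(aln$map$macaque_pos) > 0))
      expect_gte(nrow(aln$map), 0.9 * 200)
    }
  })
})
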