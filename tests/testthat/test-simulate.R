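test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(seed = 42, n_genes = 2, codons_per_gene = 80,
                    n_recurrent = 2L, n_divergent = 1L, n_cooccur = 1L,
                    n_human_background = 5L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$variants, s2$cohort$variants)
  expect_identical(s1$cohort$genotypes, s2$cohort$genotypes)
  expect_identical(s1$human_variants, s2$human_variants)
  expect_identical(s1$cds, s2$cds)
  # byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(cfg, d1); simulate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every emitted variant has exactly one truth record", {
  sim <- small_sim()
  truth <- sim$truth$variants
  expect_setequal(truth$key, sim$cohort$variants$key)
  expect_equal(anyDuplicated(truth$key), 0L)
  # truth frequency class matches an independent recount
  fc <- classify_frequency(sim$cohort)
  j <- dplyr::inner_join(truth, fc, by = "key")
  expect_identical(j$freq_class, j$class)
})

test_that("reference alleles in the VCF agree with the emitted genome", {
  sim <- small_sim()
  v <- sim$cohort$variants
  for (i in sample(nrow(v), 40)) {
    chrom_seq <- sim$genome[[v$chrom[i]]]
    expect_identical(substr(chrom_seq, v$pos[i],
                            v$pos[i] + nchar(v$ref[i]) - 1L), v$ref[i])
  }
})

test_that("planted cross-species events are recovered exactly and
           independent placement yields no spurious matches", {
  cfg <- sim_config(seed = 5, n_genes = 5, codons_per_gene = 120,
                    n_recurrent = 3L, n_divergent = 2L, n_cooccur = 0L,
                    n_human_background = 12L)
  sim <- simulate_cohort(cfg)
  aln <- align_ortholog_set(sim$human_prot, sim$macaque_prot)
  truth <- sim$truth$variants
  fc <- classify_frequency(sim$cohort)
  common <- fc$key[fc$class == "common"]
  mac <- truth[truth$effect == "non_synonymous" & truth$key %in% common, ]
  mac <- dplyr::mutate(mac, macaque_pos = codon_index)
  hum <- filter_human_common(sim$human_variants)
  m <- match_positions(hum, mac, aln)
  expect_equal(sum(m$class == "recurrent"), 3L)
  expect_equal(sum(m$class == "shared_position_divergent"), 2L)
  # with no plants at all, independently placed variation never matches
  cfg0 <- sim_config(seed = 6, n_genes = 4, codons_per_gene = 100,
                     n_recurrent = 0L, n_divergent = 0L, n_cooccur = 0L,
                     n_human_background = 25L)
  sim0 <- simulate_cohort(cfg0)
  aln0 <- align_ortholog_set(sim0$human_prot, sim0$macaque_prot)
  truth0 <- sim0$truth$variants
  fc0 <- classify_frequency(sim0$cohort)
  mac0 <- truth0[truth0$effect == "non_synonymous" &
                 truth0$key %in% fc0$key[fc0$class == "common"], ]
  mac0 <- dplyr::mutate(mac0, macaque_pos = codon_index)
  m0 <- match_positions(filter_human_common(sim0$human_variants), mac0, aln0)
  expect_equal(nrow(m0), 0L)
})

test_that("planted domain co-occurrences are recovered exactly", {
  sim <- cooc_sim()
  aln <- align_ortholog_set(sim$human_prot, sim$macaque_prot)
  mac_domains <- dplyr::bind_rows(lapply(names(aln), function(g)
    transfer_domains(aln[[g]], sim$domains[sim$domains$gene == g, ])))
  truth <- sim$truth$variants
  fc <- classify_frequency(sim$cohort)
  mac <- truth[truth$effect == "non_synonymous" &
               truth$key %in% fc$key[fc$class == "common"], ]
  mac$macaque_pos <- mac$codon_index
  mac$domain <- macgpcr:::domain_of_position_by_gene(mac, mac_domains)
  hum <- filter_human_common(sim$human_variants)
  hum$domain <- vapply(seq_len(nrow(hum)), function(i) {
    d <- sim$domains[sim$domains$gene == hum$gene[i], ]
    d$domain[d$start <= hum$aa_pos[i] & d$end >= hum$aa_pos[i]][1]
  }, "")
  cooc <- domain_cooccurrence(hum, mac)
  planted <- dplyr::distinct(sim$truth$cooccur, gene, domain)
  expect_equal(nrow(cooc$instances), nrow(planted))
  expect_setequal(paste(cooc$instances$gene, cooc$instances$domain),
                  paste(planted$gene, planted$domain))
})

test_that("with no skew the singleton share follows the neutral closed form", {
  # single population, kappa = 0, no planting, no missingness
  sim <- kappa0_sim()
  counts <- count_alleles(sim$cohort)
  ch <- counts[counts$population == "chinese_rhesus" & counts$a > 0 &
               counts$a < 2 * counts$n, ]
  n_sites <- nrow(ch)
  expect_gt(n_sites, 2000)
  p_hat <- mean(ch$a == 1)
  n2 <- 2L * sim$config$pop_sizes[["chinese_rhesus"]]
  p_exp <- 1 / sum(1 / seq_len(n2 - 1L))
  se <- sqrt(p_exp * (1 - p_exp) / n_sites)
  expect_lt(abs(p_hat - p_exp), 3 * se)
})
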