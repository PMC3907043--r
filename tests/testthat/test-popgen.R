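test_that("allele counting matches hand-computed frequencies", {
  # 21 genotyped Chinese animals, 10 of 42 chromosomes alternate: 23.8%
  man <- validate_manifest(dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("ch%03d", 1:21),
                   population = "chinese_rhesus"),
    tibble::tibble(sample_id = sprintf("in%03d", 1:44),
                   population = "indian_rhesus"),
    tibble::tibble(sample_id = sprintf("cy%03d", 1:32),
                   population = "cynomolgus")))
  gt <- setNames(rep("0/0", nrow(man)), man$sample_id)
  chinese <- man$sample_id[man$population == "chinese_rhesus"]
  gt[chinese[1:10]] <- "0/1"
  co <- new_cohort(toy_variant(100, "A", "G")[, c("chrom", "pos", "ref", "alt")],
                   matrix(gt, 1, dimnames = list(NULL, man$sample_id)), man)
  counts <- count_alleles(co)
  ch <- counts[counts$population == "chinese_rhesus", ]
  expect_equal(ch$n, 21L)
  expect_equal(ch$a, 10L)
  expect_equal(round(100 * ch$f, 1), 23.8)
  # all homozygous reference
  gt0 <- setNames(rep("0/0", nrow(man)), man$sample_id)
  co0 <- new_cohort(toy_variant(100, "A", "G")[, c("chrom", "pos", "ref", "alt")],
                    matrix(gt0, 1, dimnames = list(NULL, man$sample_id)), man)
  expect_true(all(count_alleles(co0)$a == 0))
  # one 1/1 among five called: a = 2, c = 1, f = 0.2
  gt2 <- setNames(rep("./.", nrow(man)), man$sample_id)
  gt2[chinese[1:5]] <- "0/0"
  gt2[chinese[1]] <- "1/1"
  co2 <- new_cohort(toy_variant(100, "A", "G")[, c("chrom", "pos", "ref", "alt")],
                    matrix(gt2, 1, dimnames = list(NULL, man$sample_id)), man)
  ch2 <- count_alleles(co2)[count_alleles(co2)$population == "chinese_rhesus", ]
  expect_equal(c(ch2$n, ch2$a, ch2$c), c(5L, 2L, 1L))
  expect_equal(ch2$f, 0.2)
})

test_that("singletons are defined by carrier individuals cohort-wide", {
  man <- default_manifest()
  mk <- function(gts) {
    gt <- setNames(rep("0/0", nrow(man)), man$sample_id)
    gt[names(gts)] <- gts
    co <- new_cohort(toy_variant(100, "A", "G")[, c("chrom", "pos", "ref", "alt")],
                     matrix(gt, 1, dimnames = list(NULL, man$sample_id)), man)
    classify_frequency(co)$class
  }
  expect_equal(mk(c(ch001 = "0/1")), "singleton")
  expect_equal(mk(c(ch001 = "1/1")), "singleton")   # homozygous, one carrier
  expect_equal(mk(c(ch001 = "0/1", cy001 = "0/1")), "common")
  expect_equal(mk(character()), "monomorphic")
})

test_that("the SFS conserves segregating sites and excludes monomorphs", {
  man <- tiny_manifest(c(3, 1, 1))
  v <- dplyr::bind_rows(lapply(1:4, function(i) toy_variant(i * 10, "A", "G")))
  gt <- rbind(
    c("0/1", "0/0", "0/0", "0/0", "0/0"),  # chinese count 1
    c("0/1", "0/0", "0/0", "0/0", "0/0"),  # chinese count 1
    c("1/1", "0/0", "0/0", "0/0", "0/0"),  # chinese count 2
    c("0/0", "0/0", "0/0", "0/0", "0/0"))  # monomorphic
  colnames(gt) <- man$sample_id
  co <- new_cohort(v[, c("chrom", "pos", "ref", "alt")], gt, man)
  sfs <- build_sfs(co, "chinese_rhesus")
  expect_equal(sfs$sites[sfs$alt_count == 1], 2L)
  expect_equal(sfs$sites[sfs$alt_count == 2], 1L)
  expect_equal(sum(sfs$sites), 3L)
  # conservation on a simulated cohort
  sim <- small_sim()
  counts <- count_alleles(sim$cohort)
  for (p in gpcr_populations) {
    seg <- sum(counts$population == p & counts$a > 0 &
               counts$a < 2 * counts$n)
    expect_equal(sum(build_sfs(counts, p)$sites), seg)
  }
})

test_that("sharing partition assigns each common variant exactly one region", {
  man <- tiny_manifest(c(2, 2, 2))
  v <- dplyr::bind_rows(lapply(1:3, function(i) toy_variant(i * 10, "A", "G")))
  gt <- rbind(
    c("0/0", "0/0", "0/1", "0/1", "0/0", "0/0"),  # Indian private
    c("0/1", "0/0", "0/1", "0/0", "0/0", "0/0"),  # Chinese-Indian
    c("0/1", "0/0", "0/1", "0/0", "0/1", "0/0"))  # All
  colnames(gt) <- man$sample_id
  co <- new_cohort(v[, c("chrom", "pos", "ref", "alt")], gt, man)
  sh <- partition_sharing(count_alleles(co))
  expect_setequal(sh$assignments$region, c("Indian", "Chinese-Indian", "All"))
  expect_equal(sum(sh$venn$sites), 3L)
  # Venn completeness on a simulated cohort
  sim <- small_sim()
  counts <- count_alleles(sim$cohort)
  fc <- classify_frequency(counts)
  sh2 <- partition_sharing(counts, fc)
  expect_equal(sum(sh2$venn$sites), sum(fc$class == "common"))
  expect_equal(nrow(sh2$assignments), sum(fc$class == "common"))
})

test_that("human common filter applies a strict 0.5% threshold", {
  h <- tibble::tibble(gene = c("FZD6", "X", "GPR153"),
                      aa_pos = 1:3, aa1 = "A", aa2 = "V", coords = ".",
                      dbsnp = ".", maf = c(0.02, 0.005, 0.31))
  kept <- filter_human_common(h)
  expect_setequal(kept$gene, c("FZD6", "GPR153"))  # exactly 0.005 excluded
  h$maf[1] <- 1.5
  expect_error(filter_human_common(h), "MAF")
})

test_that("expansion skew strictly increases the expected singleton share", {
  p1 <- vapply(c(0, 0.5, 1, 2), function(k) sfs_probs(191, k)[1], 0)
  expect_true(all(diff(p1) > 0))
  # and the law is a probability vector
  expect_equal(sum(sfs_probs(39, 0.7)), 1)
})
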