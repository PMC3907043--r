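#' Per-population allele counts for every variant
#'
#' For each variant and population: `n` = individuals with a called
#' genotype, `a` = alternate-allele count (0..2n), `c` = carrier count
#' (individuals with at least one alternate allele), `f` = a / 2n. Missing
#' genotypes reduce `n`; they are never imputed.
#'
#' @param cohort A `gpcr_cohort`.
#' @return Long tibble: `key`, `population`, `n`, `a`, `c`, `f`.
#' @export
count_alleles <- function(cohort) {
  gt <- cohort$genotypes
  man <- cohort$manifest
  pops <- intersect(gpcr_populations, unique(man$population))
  res <- lapply(pops, function(p) {
    cols <- man$sample_id[man$population == p]
    sub <- gt[, cols, drop = FALSE]
    called <- sub != "./."
    n <- rowSums(called)
    a <- rowSums((sub == "0/1") + 2L * (sub == "1/1"))
    cc <- rowSums(sub == "0/1" | sub == "1/1")
    tibble::tibble(key = cohort$variants$key, population = p,
                   n = as.integer(n), a = as.integer(a), c = as.integer(cc),
                   f = ifelse(n > 0, a / (2 * n), NA_real_))
  })
  dplyr::bind_rows(res)
}

# cohort-wide carrier / allele totals from a count_alleles() table
cohort_totals <- function(counts) {
  counts |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n = sum(.data$n), a = sum(.data$a), c = sum(.data$c),
                     .groups = "drop")
}

#' Classify variants as monomorphic, singleton or common
#'
#' A singleton is a variant whose alternate allele is observed in exactly
#' one individual cohort-wide (a single homozygous carrier is still a
#' singleton); common variants are carried by two or more individuals.
#'
#' @param counts Long counts tibble from [count_alleles()], or a cohort.
#' @return Tibble: `key`, `carriers`, `class`.
#' @export
classify_frequency <- function(counts) {
  if (inherits(counts, "gpcr_cohort")) counts <- count_alleles(counts)
  tot <- cohort_totals(counts)
  if (any(tot$c == 0 & tot$a > 0)) {
    stop("internal inconsistency: alternate alleles without carriers")
  }
  tibble::tibble(
    key = tot$key, carriers = tot$c,
    class = dplyr::case_when(tot$c == 0 ~ "monomorphic",
                             tot$c == 1 ~ "singleton",
                             TRUE ~ "common"))
}

#' Unfolded site frequency spectrum of one population
#'
#' Histogram of segregating sites over the alternate-allele count
#' (alternate relative to the macaque reference). Sites monomorphic in the
#' population (count 0 or 2n) are excluded, so the spectrum mass equals the
#' population's segregating-site count. A normalised version over relative
#' frequency is included.
#'
#' @param counts Long counts tibble from [count_alleles()], or a cohort.
#' @param population Population label.
#' @return Tibble: `alt_count`, `sites`, `prop`, `freq` (midpoint a/2n,
#'   using the modal n of the population).
#' @export
build_sfs <- function(counts, population) {
  if (inherits(counts, "gpcr_cohort")) counts <- count_alleles(counts)
  if (!(population %in% gpcr_populations)) {
    stop("unknown population: ", population)
  }
  sub <- counts[counts$population == population, , drop = FALSE]
  seg <- sub[sub$a > 0 & sub$a < 2 * sub$n, , drop = FALSE]
  if (nrow(seg) == 0L) {
    return(tibble::tibble(alt_count = integer(), sites = integer(),
                          prop = double(), freq = double()))
  }
  n_modal <- as.integer(names(sort(table(seg$n), decreasing = TRUE))[1])
  lv <- seq_len(max(seg$a))
  tab <- table(factor(seg$a, levels = lv))
  out <- tibble::tibble(alt_count = as.integer(lv), sites = as.integer(tab))
  out$prop <- out$sites / sum(out$sites)
  out$freq <- out$alt_count / (2 * n_modal)
  out
}

#' Partition common variants by the set of populations carrying them
#'
#' Presence means at least one carrier in a population; each common variant
#' falls in exactly one of the seven regions of the three-population Venn
#' diagram. The two-way rhesus-only partition (Chinese / Indian / both,
#' ignoring cynomolgus carriers) is also returned.
#'
#' @param counts Long counts tibble from [count_alleles()], or a cohort.
#' @param freq_classes Optional tibble from [classify_frequency()]
#'   (computed if missing); only common variants are partitioned.
#' @return List with `assignments` (tibble `key`, `region`,
#'   `rhesus_region`), `venn` (tibble `region`, `sites`) and
#'   `rhesus_venn`.
#' @export
partition_sharing <- function(counts, freq_classes = NULL) {
  if (inherits(counts, "gpcr_cohort")) counts <- count_alleles(counts)
  if (is.null(freq_classes)) freq_classes <- classify_frequency(counts)
  common <- freq_classes$key[freq_classes$class == "common"]
  wide <- counts |>
    dplyr::filter(.data$key %in% common) |>
    tidyr::pivot_wider(id_cols = "key", names_from = "population",
                       values_from = "c", values_fill = 0L)
  for (p in gpcr_populations) if (is.null(wide[[p]])) wide[[p]] <- 0L
  if (nrow(wide) && any(wide$chinese_rhesus + wide$indian_rhesus +
                        wide$cynomolgus == 0)) {
    stop("sharing error: common variant with zero carriers")
  }
  region_names <- c("Chinese", "Indian", "Cynomolgus", "Chinese-Indian",
                    "Chinese-Cynomolgus", "Indian-Cynomolgus", "All")
  lab <- function(ch, ind, cy) {
    present <- c("Chinese", "Indian", "Cynomolgus")[c(ch, ind, cy) > 0]
    if (length(present) == 3) "All" else paste(present, collapse = "-")
  }
  assignments <- tibble::tibble(
    key = wide$key,
    region = mapply(lab, wide$chinese_rhesus, wide$indian_rhesus,
                    wide$cynomolgus),
    rhesus_region = dplyr::case_when(
      wide$chinese_rhesus > 0 & wide$indian_rhesus > 0 ~ "Chinese-Indian",
      wide$chinese_rhesus > 0 ~ "Chinese",
      wide$indian_rhesus > 0 ~ "Indian",
      TRUE ~ NA_character_))
  venn <- tibble::tibble(
    region = region_names,
    sites = vapply(region_names,
                   function(r) sum(assignments$region == r), integer(1)))
  rr <- c("Chinese", "Indian", "Chinese-Indian")
  rhesus_venn <- tibble::tibble(
    region = rr,
    sites = vapply(rr, function(r)
      sum(assignments$rhesus_region == r, na.rm = TRUE), integer(1)))
  list(assignments = assignments, venn = venn, rhesus_venn = rhesus_venn)
}

#' Filter a human variant table to common polymorphisms
#'
#' Keeps rows whose allele frequency is strictly greater than the
#' threshold, one-half of one percent by default.
#'
#' @param human_rows Tibble from [read_human_variants()].
#' @param threshold Frequency threshold (default 0.005).
#' @return The filtered tibble.
#' @export
filter_human_common <- function(human_rows, threshold = 0.005) {
  if (any(human_rows$maf < 0 | human_rows$maf > 1)) {
    stop("schema error: MAF outside [0, 1]")
  }
  human_rows[human_rows$maf > threshold, , drop = FALSE]
}
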