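#' Eligibility of a macaque variant for functional prediction
#'
#' Predictions are only meaningful where the mutated macaque residue is
#' unambiguously present and conserved in the human ortholog: the macaque
#' position must align to a non-gap human residue equal to the macaque
#' reference amino acid.
#'
#' @param macaque_pos Macaque protein position(s) of the variant(s).
#' @param ref_aa Macaque reference amino acid(s).
#' @param alignment A `protein_alignment` for the gene.
#' @return Logical vector.
#' @export
check_eligibility <- function(macaque_pos, ref_aa, alignment) {
  mp <- alignment$map
  idx <- match(macaque_pos, mp$macaque_pos)
  !is.na(idx) & mp$human_aa[idx] == ref_aa
}

#' Five-category consensus of three predictor calls
#'
#' With all three predictors available, the damaging-vote count maps 3 ->
#' deleterious, 2 -> likely_deleterious, 1 -> likely_neutral, 0 -> neutral.
#' With exactly two available, unanimity decides (2 damaging ->
#' likely_deleterious, 0 -> likely_neutral) and a split vote is ambiguous.
#' With fewer than two calls the variant is ambiguous.
#'
#' @param calls Character vector (length 3, one per predictor) in
#'   `c("damaging", "tolerated", "missing")`, or a 3-column matrix /
#'   data.frame of such calls (one row per variant).
#' @return Character vector of categories.
#' @export
consensus_classify <- function(calls) {
  if (is.matrix(calls) || is.data.frame(calls)) {
    calls <- as.matrix(calls)
    if (nrow(calls) == 0L) return(character(0))
    return(apply(calls, 1, consensus_classify))
  }
  stopifnot(length(calls) == 3,
            all(calls %in% c("damaging", "tolerated", "missing")))
  avail <- sum(calls != "missing")
  dmg <- sum(calls == "damaging")
  if (avail == 3) {
    c("neutral", "likely_neutral", "likely_deleterious", "deleterious")[dmg + 1L]
  } else if (avail == 2) {
    if (dmg == 2) "likely_deleterious"
    else if (dmg == 0) "likely_neutral"
    else "ambiguous"
  } else {
    "ambiguous"
  }
}

#' Consensus categories for a set of variants
#'
#' Joins predictor calls onto eligible variants and applies
#' [consensus_classify()]; ineligible variants receive no category.
#'
#' @param keys Variant keys.
#' @param eligible Logical vector parallel to `keys`.
#' @param predictions Tibble from [read_predictions()].
#' @param predictors Predictor names defining the vote order.
#' @return Tibble: `key`, `eligible`, one column per predictor, `category`
#'   (NA when ineligible).
#' @export
consensus_table <- function(keys, eligible, predictions,
                            predictors = gpcr_predictors) {
  wide <- tibble::tibble(key = keys, eligible = eligible)
  for (p in predictors) {
    sub <- predictions[predictions$predictor == p, c("key", "call")]
    wide[[p]] <- sub$call[match(wide$key, sub$key)]
    wide[[p]][is.na(wide[[p]])] <- "missing"
  }
  cat_all <- consensus_classify(as.matrix(wide[, predictors]))
  wide$category <- ifelse(wide$eligible, cat_all, NA_character_)
  wide
}

#' Fraction of variants with a damaging consensus
#'
#' Counts categories `deleterious` and `likely_deleterious` among
#' classified variants of a stratum. Ambiguous calls sit in the denominator
#' by default; set `include_ambiguous = FALSE` to drop them.
#'
#' @param categories Character vector of consensus categories (NAs are
#'   ineligible and always dropped).
#' @param include_ambiguous Keep ambiguous calls in the denominator?
#' @return List: `damaging`, `total`, `fraction` (NA for an empty stratum).
#' @export
damaging_fraction <- function(categories, include_ambiguous = TRUE) {
  categories <- categories[!is.na(categories)]
  if (!include_ambiguous) categories <- categories[categories != "ambiguous"]
  total <- length(categories)
  dmg <- sum(categories %in% c("deleterious", "likely_deleterious"))
  list(damaging = dmg, total = total,
       fraction = if (total > 0) dmg / total else NA_real_)
}

#' Damaging fractions stratified by a grouping label
#'
#' @param categories Consensus categories.
#' @param stratum Parallel vector of stratum labels.
#' @param include_ambiguous Passed to [damaging_fraction()].
#' @return Tibble: `stratum`, `damaging`, `total`, `fraction`.
#' @export
damaging_by_stratum <- function(categories, stratum,
                                include_ambiguous = TRUE) {
  dplyr::bind_rows(lapply(unique(stratum), function(s) {
    f <- damaging_fraction(categories[stratum == s], include_ambiguous)
    tibble::tibble(stratum = s, damaging = f$damaging, total = f$total,
                   fraction = f$fraction)
  }))
}
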