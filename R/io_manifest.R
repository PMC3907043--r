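#' Population labels recognised by the pipeline
#'
#' The cohort comprises Chinese-origin rhesus, Indian-origin rhesus
#' (*Macaca mulatta*) and cynomolgus (*M. fascicularis*) macaques.
#' @export
gpcr_populations <- c("chinese_rhesus", "indian_rhesus", "cynomolgus")

#' Species of each population
#' @export
population_species <- c(
  chinese_rhesus = "M. mulatta",
  indian_rhesus  = "M. mulatta",
  cynomolgus     = "M. fascicularis"
)

#' Read a sample manifest
#'
#' The manifest is a TSV with columns `sample_id` and `population` mapping
#' each animal to one of the three study populations.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `population`, `species`.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  validate_manifest(tibble::as_tibble(m))
}

#' Validate (and complete) a sample manifest tibble
#'
#' @param manifest Tibble with columns `sample_id`, `population`.
#' @return The manifest with a `species` column, after invariant checks.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(all(c("sample_id", "population") %in% names(manifest)))
  if (anyDuplicated(manifest$sample_id)) {
    stop("manifest error: duplicated sample ids: ",
         paste(unique(manifest$sample_id[duplicated(manifest$sample_id)]),
               collapse = ", "))
  }
  bad <- setdiff(unique(manifest$population), gpcr_populations)
  if (length(bad)) {
    stop("manifest error: unknown population label(s): ",
         paste(bad, collapse = ", "))
  }
  manifest$species <- unname(population_species[manifest$population])
  tibble::as_tibble(manifest)
}

#' Write a sample manifest TSV
#' @param manifest Manifest tibble.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest[, c("sample_id", "population")], path,
                   progress = FALSE)
  invisible(path)
}
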