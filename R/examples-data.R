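#' Curated examples of suspect RefSeq assemblies
#'
#' Five published cases of RefSeq chloroplast records flagged as genus-level
#' length outliers for which an alternative GenBank record of the same
#' species lies much closer to the genus median — e.g. *Angelica sinensis*:
#' genus median 146,962 bp, flagged record 142,485 bp (4,477 bp away),
#' alternative 146,952 bp (10 bp away). Useful as a reference input for
#' [is_alternative_closer()] and as a sanity check of the closer-to-median
#' verdict.
#'
#' @return A tibble with columns `species`, `genus_median`,
#'   `refseq_accession`, `refseq_length`, `refseq_published`,
#'   `alt_accession`, `alt_length`, `alt_published`.
#' @examples
#' ex <- suspect_assembly_examples()
#' is_alternative_closer(ex$genus_median, ex$refseq_length, ex$alt_length)
#' @export
suspect_assembly_examples <- function() {
  path <- system.file("extdata", "suspect_assembly_examples.tsv",
                      package = "lenqc", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    genus_median = readr::col_integer(),
    refseq_accession = readr::col_character(),
    refseq_length = readr::col_integer(),
    refseq_published = readr::col_date(),
    alt_accession = readr::col_character(),
    alt_length = readr::col_integer(),
    alt_published = readr::col_date()
  ), progress = FALSE)
}
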