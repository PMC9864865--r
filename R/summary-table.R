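#' @title Sequence summary tables
#' @description
#' The central data structure of lenqc is the *summary table*: a tibble with
#' one row per database record carrying the metadata fields a RefSeq/GenBank
#' "sequence summary" provides, optionally extended with resolved lineage
#' columns. No nucleotide sequence is ever read; the whole pipeline operates
#' on length metadata.
#'
#' Mandatory columns: `accession` (versioned, e.g. `"NC_042826.1"`; a missing
#' version suffix is tolerated), `organism` (binomial/trinomial name),
#' `taxid` (positive integer or `NA`), `length_bp` (positive integer, base
#' pairs), `published` (`Date`), `source_db` (`"refseq"` or `"genbank"`).
#' Optional lineage columns: `genus`, `family`, `clade`.
#' @name summary-table
NULL

summary_cols <- c("accession", "organism", "taxid", "length_bp",
                  "published", "source_db")
lineage_cols <- c("genus", "family", "clade")
source_dbs <- c("refseq", "genbank")

#' Strip the version suffix from an accession
#'
#' Record uniqueness is enforced on the unversioned stem within a source
#' database, so that re-versioning (`.1` -> `.2`) cannot create phantom
#' duplicates.
#'
#' @param accession Character vector of (possibly versioned) accessions.
#' @return Character vector of accession stems.
#' @examples
#' accession_stem(c("NC_042826.1", "MW820164"))
#' @export
accession_stem <- function(accession) {
  sub("\\.[0-9]+$", "", accession)
}

#' Parse summary publication dates
#'
#' Accepts both the ISO dialect (`"2019-06-25"`) and the long-form dialect
#' used in database summary listings (`"25 June 2019"`). Unparseable strings
#' yield `NA`.
#'
#' @param x Character vector of dates (or a `Date`, returned as is).
#' @return A `Date` vector.
#' @export
parse_summary_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  out <- withr::with_locale(c(LC_TIME = "C"), {
    iso <- as.Date(x, format = "%Y-%m-%d")
    long <- as.Date(x, format = "%d %B %Y")
    ifelse(is.na(iso), long, iso)
  })
  as.Date(out, origin = "1970-01-01")
}

new_summary_table <- function(n = 0) {
  tibble::tibble(
    accession = character(n), organism = character(n),
    taxid = integer(n), length_bp = integer(n),
    published = as.Date(character(n)), source_db = character(n),
    genus = character(n), family = character(n), clade = character(n)
  )
}

#' Coerce a data frame of raw records into a summary table
#'
#' Normalizes column names (case-insensitive), parses dates and integer
#' fields, fills absent lineage columns with `NA`, rejects invalid rows with
#' per-row diagnostics, and enforces accession-stem uniqueness per source
#' database.
#'
#' @param df A data frame with at least the six mandatory summary columns.
#' @param provenance Free-text description of where the records came from.
#' @return A validated summary tibble (invalid rows dropped with a warning).
#' @export
as_summary_table <- function(df, provenance = NULL) {
  df <- tibble::as_tibble(df)
  names(df) <- tolower(names(df))
  missing <- setdiff(summary_cols, names(df))
  if (length(missing) > 0) {
    lenqc_abort(
      paste0("summary table is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      class = "schema_error"
    )
  }
  for (col in lineage_cols) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  out <- tibble::tibble(
    accession = trimws(as.character(df$accession)),
    organism = trimws(as.character(df$organism)),
    taxid = suppressWarnings(as.integer(df$taxid)),
    length_bp = suppressWarnings(as.integer(round(as.numeric(df$length_bp)))),
    published = parse_summary_date(df$published),
    source_db = tolower(trimws(as.character(df$source_db))),
    genus = as.character(df$genus),
    family = as.character(df$family),
    clade = as.character(df$clade)
  )

  bad <- character(0)
  flag <- function(cond, why) {
    idx <- which(cond)
    if (length(idx) > 0) {
      bad <<- c(bad, sprintf("row %d (%s): %s", idx,
                             ifelse(is.na(out$accession[idx]) |
                                      out$accession[idx] == "",
                                    "<no accession>", out$accession[idx]),
                             why))
    }
    cond
  }
  drop <- flag(is.na(out$accession) | out$accession == "", "empty accession")
  drop <- drop | flag(is.na(out$length_bp) | out$length_bp <= 0,
                      "length_bp is not a positive integer")
  drop <- drop | flag(!out$source_db %in% source_dbs,
                      "source_db is not 'refseq' or 'genbank'")
  if (any(drop)) {
    warn(c("dropping invalid summary rows:", bad),
         class = "lenqc_row_rejected")
    out <- out[!drop, , drop = FALSE]
  }

  stem <- accession_stem(out$accession)
  key <- paste(stem, out$source_db)
  if (anyDuplicated(key) > 0) {
    dups <- unique(stem[duplicated(key)])
    lenqc_abort(
      paste0("duplicate accession stem(s) within one source database: ",
             paste(dups, collapse = ", ")),
      class = "validation_error"
    )
  }
  attr(out, "provenance") <- provenance %||%
    "in-memory records (as_summary_table)"
  out
}

#' Read a summary table from TSV or CSV
#'
#' The header must name the six mandatory summary columns
#' (case-insensitively); the lineage columns `genus`, `family`, `clade` are
#' optional. Rows with a missing or non-positive `length_bp` (or other
#' invariant violations) are rejected with a per-row diagnostic warning;
#' remaining rows are kept in file order.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A summary tibble; its `"provenance"` attribute records the path
#'   and retrieval date.
#' @export
read_summary_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    lenqc_abort(paste0("summary file does not exist: ", path),
                class = "io_error")
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  as_summary_table(raw, provenance = paste0(path, " (read ", Sys.Date(), ")"))
}

#' Write a summary table to TSV or CSV
#'
#' Dates are serialized in ISO form so that
#' `read_summary_table(write_summary_table(t))` is the identity.
#'
#' @param table A summary tibble.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  table <- as_summary_table(table)
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  tryCatch(writer(table, path, progress = FALSE),
           error = function(e) {
             lenqc_abort(paste0("cannot write summary table to ", path, ": ",
                                conditionMessage(e)),
                        class = "io_error", parent = e)
           })
  invisible(path)
}
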