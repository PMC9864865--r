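#' @title Summary sources
#' @description
#' Data acquisition is pluggable: a *summary source* is any function of
#' `(query, db)` returning a data frame of raw summary records, where
#' `query` is a taxon name (or `""` for everything the source holds) and
#' `db` is `"refseq"` or `"genbank"`. Two implementations ship with the
#' package: an offline fixture backend serving TSV files from a directory
#' (used throughout the tests), and a minimal NCBI E-utilities backend with
#' rate limiting and retry for interactive use.
#' @name summary-sources
NULL

#' Offline fixture summary source
#'
#' Serves records from `refseq.tsv` and `genbank.tsv` in a directory (the
#' layout written by [write_fixture()]). Matching is by exact organism name,
#' organism-name prefix (`"Cuscuta"` matches `"Cuscuta europaea"`), genus or
#' family; an empty query returns every record of the requested database.
#' The backend is referentially transparent: the same query always yields
#' the same table.
#'
#' @param dir Directory containing `refseq.tsv` (and optionally
#'   `genbank.tsv`).
#' @return A summary-source function `(query, db)`.
#' @export
fixture_source <- function(dir) {
  refseq_path <- file.path(dir, "refseq.tsv")
  if (!file.exists(refseq_path)) {
    lenqc_abort(paste0("fixture directory has no refseq.tsv: ", dir),
                class = "io_error")
  }
  genbank_path <- file.path(dir, "genbank.tsv")
  tables <- list(
    refseq = read_summary_table(refseq_path),
    genbank = if (file.exists(genbank_path)) {
      read_summary_table(genbank_path)
    } else {
      new_summary_table()
    }
  )
  function(query, db = c("refseq", "genbank")) {
    db <- match.arg(db)
    tab <- tables[[db]]
    if (is.null(query) || identical(query, "")) return(tab)
    hit <- tab$organism == query |
      startsWith(tab$organism, paste0(query, " ")) |
      (!is.na(tab$genus) & tab$genus == query) |
      (!is.na(tab$family) & tab$family == query)
    tab[which(hit), , drop = FALSE]
  }
}

#' NCBI E-utilities summary source
#'
#' A minimal remote backend for interactive use: esearch on the nucleotide
#' database for complete chloroplast genomes of the queried taxon
#' (restricted to RefSeq when `db = "refseq"`), then esummary for the
#' matching UIDs. Calls are rate limited and retried. Not used by the test
#' suite, which runs entirely against [fixture_source()] fixtures.
#'
#' @param api_key Optional NCBI API key.
#' @param delay Seconds to sleep between requests.
#' @param retries Number of attempts per request.
#' @return A summary-source function `(query, db)`.
#' @export
ncbi_source <- function(api_key = NULL, delay = 0.4, retries = 3) {
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  get_json <- function(url) {
    for (k in seq_len(retries)) {
      Sys.sleep(delay)
      out <- tryCatch(jsonlite::fromJSON(url), error = function(e) e)
      if (!inherits(out, "error")) return(out)
      if (k == retries) {
        lenqc_abort(paste0("NCBI request failed after ", retries,
                           " attempts: ", conditionMessage(out)),
                    class = "transport_error", parent = out)
      }
    }
  }
  function(query, db = c("refseq", "genbank")) {
    db <- match.arg(db)
    term <- paste0(utils::URLencode(query, reserved = TRUE),
                   "[Organism]+AND+chloroplast[Title]+AND+",
                   "complete+genome[Title]")
    if (db == "refseq") term <- paste0(term, "+AND+refseq[filter]")
    key <- if (is.null(api_key)) "" else paste0("&api_key=", api_key)
    es <- get_json(paste0(base, "/esearch.fcgi?db=nuccore&retmax=10000",
                          "&retmode=json&term=", term, key))
    ids <- es$esearchresult$idlist
    if (length(ids) == 0) return(new_summary_table())
    recs <- list()
    for (chunk in split(ids, ceiling(seq_along(ids) / 200))) {
      sm <- get_json(paste0(base, "/esummary.fcgi?db=nuccore&retmode=json",
                            "&id=", paste(chunk, collapse = ","), key))
      docs <- sm$result[setdiff(names(sm$result), "uids")]
      recs <- c(recs, lapply(docs, function(d) {
        tibble::tibble(
          accession = d$accessionversion %||% d$caption,
          organism = d$organism %||% sub(" chloroplast.*$", "", d$title),
          taxid = d$taxid %||% NA_integer_,
          length_bp = d$slen,
          published = d$createdate %||% NA_character_,
          source_db = db
        )
      }))
    }
    dplyr::bind_rows(recs)
  }
}

#' Fetch summaries through a source
#'
#' Normalizes whatever the source yields into a validated summary table. A
#' source failure is re-raised as a transport error carrying the source's
#' message; zero records is an empty table, not an error.
#'
#' @param query Taxon name (or `""` for all records of a fixture source).
#' @param source A summary-source function (see [fixture_source()]).
#' @param db `"refseq"` or `"genbank"`.
#' @return A summary tibble.
#' @export
fetch_summaries <- function(query, source, db = c("refseq", "genbank")) {
  db <- match.arg(db)
  raw <- tryCatch(source(query, db), error = function(e) {
    if (inherits(e, "lenqc_transport_error")) stop(e)
    lenqc_abort(paste0("summary source failed for query '", query, "' (",
                       db, "): ", conditionMessage(e)),
                class = "transport_error", parent = e)
  })
  if (is.null(raw) || nrow(raw) == 0) return(new_summary_table())
  as_summary_table(raw, provenance = paste0("source query '", query,
                                            "' [", db, "]"))
}
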