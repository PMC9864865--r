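#' @title Pipeline orchestration
#' @description
#' The full analysis runs in four stages: (1) *acquisition* of RefSeq-side
#' summaries through the configured source, (2) *assessment* of length
#' distributions at family and genus rank subject to the minimum-count
#' rules, (3) *wide filtering* by the IQR/median thresholds with family
#' decomposition, and (4) *outlier detection* in the genus distributions
#' followed by the alternative-sequence check against the GenBank side of
#' the source. Every stage logs one structured line with in/out counts.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults follow the reference analysis: at least 20 sequences per
#' family and 10 per genus, wideness thresholds of 10% (family) and 1%
#' (genus), whisker multiplier 1.5.
#'
#' @param source A summary-source function ([fixture_source()] or
#'   [ncbi_source()]).
#' @param taxa Character vector of taxon queries; empty means every record
#'   the source holds (fixture mode).
#' @param min_family_n,min_genus_n Minimum records per family / genus.
#' @param wide_family_pct,wide_genus_pct Width thresholds in percent.
#' @param whisker_k Whisker multiplier.
#' @param max_genera Genera kept per wide-family breakdown.
#' @param output_dir Where `lenqc run` writes the report, or `NULL`.
#' @param seed Optional integer seed (recorded in the manifest; fixture
#'   generation is seeded separately).
#' @param verbose Emit per-stage log messages.
#' @return A `lenqc_config` list.
#' @export
pipeline_config <- function(source, taxa = character(),
                            min_family_n = 20, min_genus_n = 10,
                            wide_family_pct = 10, wide_genus_pct = 1,
                            whisker_k = 1.5, max_genera = 6,
                            output_dir = NULL, seed = NULL,
                            verbose = TRUE) {
  stopifnot(is.function(source), min_family_n >= 1, min_genus_n >= 1,
            wide_family_pct > 0, wide_genus_pct > 0, whisker_k > 0)
  structure(list(source = source, taxa = taxa,
                 min_family_n = min_family_n, min_genus_n = min_genus_n,
                 wide_family_pct = wide_family_pct,
                 wide_genus_pct = wide_genus_pct, whisker_k = whisker_k,
                 max_genera = max_genera, output_dir = output_dir,
                 seed = seed, verbose = verbose),
            class = "lenqc_config")
}

#' Run the four-stage pipeline
#'
#' @param config A [pipeline_config()].
#' @return A `lenqc_result` list: `table` (acquired summaries),
#'   `dist_family`, `dist_genus`, `wide_all`, `wide_families`,
#'   `wide_genera`, `outliers`, `alternatives`, `skipped`, `log` (tibble
#'   of per-stage in/out counts), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lenqc_config"))
  log <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, detail = detail
    )
    if (config$verbose) {
      inform(sprintf("[lenqc] %s: %d in, %d out%s", stage, n_in, n_out,
                     if (nzchar(detail)) paste0(" (", detail, ")") else ""))
    }
  }

  # stage 1 — acquisition
  queries <- if (length(config$taxa) == 0) "" else config$taxa
  parts <- lapply(queries, fetch_summaries, source = config$source,
                  db = "refseq")
  raw <- dplyr::bind_rows(parts)
  dup <- duplicated(paste(accession_stem(raw$accession), raw$source_db))
  table <- as_summary_table(raw[!dup, , drop = FALSE],
                            provenance = paste0("pipeline acquisition (",
                                                length(queries),
                                                " queries)"))
  note("acquisition", length(queries), nrow(table),
       paste0(sum(dup), " duplicate records collapsed"))

  # stage 2 — distribution assessment at both ranks
  dist_family <- assess_distributions(table, "family",
                                      min_n = config$min_family_n,
                                      whisker_k = config$whisker_k)
  dist_genus <- assess_distributions(table, "genus",
                                     min_n = config$min_genus_n,
                                     whisker_k = config$whisker_k)
  skipped <- list(family = attr(dist_family, "skipped"),
                  genus = attr(dist_genus, "skipped"))
  note("assessment", nrow(table), nrow(dist_family) + nrow(dist_genus),
       sprintf("%d family + %d genus distributions; skipped taxa: %d/%d",
               nrow(dist_family), nrow(dist_genus),
               skipped$family$taxa_below_min_n,
               skipped$genus$taxa_below_min_n))

  # stage 3 — wide filtering
  wide <- build_wide_reports(table, dist_family, dist_genus,
                             wide_family_pct = config$wide_family_pct,
                             wide_genus_pct = config$wide_genus_pct,
                             max_genera = config$max_genera)
  note("wide_filter", nrow(dist_family) + nrow(dist_genus),
       nrow(wide$wide_all))

  # stage 4 — outlier detection + alternatives (genus rank only)
  outliers <- detect_outliers(dist_genus, table)
  dist_genus <- set_outliers(dist_genus, outliers)
  alternatives <- assess_all_alternatives(outliers, config$source)
  note("outlier_qc", nrow(dist_genus), nrow(outliers),
       paste0(sum(alternatives$closer, na.rm = TRUE),
              " with a closer alternative"))

  structure(list(
    table = table, dist_family = dist_family, dist_genus = dist_genus,
    wide_all = wide$wide_all, wide_families = wide$wide_families,
    wide_genera = wide$wide_genera, outliers = outliers,
    alternatives = alternatives, skipped = skipped,
    log = dplyr::bind_rows(log), config = config
  ), class = "lenqc_result")
}

#' @export
print.lenqc_result <- function(x, ...) {
  cat("lenqc pipeline result\n")
  cat(sprintf("  records:            %d\n", nrow(x$table)))
  cat(sprintf("  family distributions: %d (%d wide at %g%%)\n",
              nrow(x$dist_family),
              sum(x$wide_all$rank == "family"), x$config$wide_family_pct))
  cat(sprintf("  genus distributions:  %d (%d wide at %g%%)\n",
              nrow(x$dist_genus),
              sum(x$wide_all$rank == "genus"), x$config$wide_genus_pct))
  cat(sprintf("  genus-level outliers: %d (%d with closer alternative)\n",
              nrow(x$outliers), sum(x$alternatives$closer, na.rm = TRUE)))
  invisible(x)
}

#' Write the pipeline result as TSV mirrors
#'
#' One TSV per report table, named `<stem>_<Sheet>.tsv` next to `stem`.
#' List-columns are flattened to comma-separated strings. Output is
#' byte-stable: the same result always serializes identically.
#'
#' @param result A `lenqc_result`.
#' @param stem Path stem, e.g. `"out/report"`.
#' @return Named character vector of the files written.
#' @export
write_result_tsvs <- function(result, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  sheets <- result_sheets(result)
  paths <- character(0)
  for (nm in names(sheets)) {
    p <- paste0(stem, "_", nm, ".tsv")
    readr::write_tsv(sheets[[nm]], p, progress = FALSE)
    paths[nm] <- p
  }
  paths
}

# The seven report tables in workbook order, list-columns flattened.
result_sheets <- function(result) {
  flatten <- function(d) {
    for (col in names(d)) {
      if (is.list(d[[col]])) {
        d[[col]] <- vapply(d[[col]], paste, "", collapse = ",")
      }
    }
    d
  }
  list(
    RefSeq = result$table,
    Distributions = flatten(dplyr::bind_rows(result$dist_family,
                                             result$dist_genus)),
    WideAll = flatten(result$wide_all),
    WideFamilies = flatten(result$wide_families),
    WideGenera = flatten(result$wide_genera),
    Outliers = result$outliers,
    Alternatives = result$alternatives
  )
}
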