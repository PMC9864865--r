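#' @title Wide-distribution filtering
#' @description
#' A taxon's distribution is *wide* when its IQR/median ratio exceeds a
#' threshold: 1% for genera and 10% for families by default. The boundary
#' rule is strictly greater-than, so a ratio exactly at the threshold is
#' not wide. Wide families are decomposed into their largest genera so the
#' source of the width can be inspected.
#' @name wide-filter
NULL

#' Filter wide distributions
#'
#' Keeps exactly the entries whose `ratio_pct` is strictly greater than the
#' threshold, preserving the incoming (descending `ratio_pct`) order. The
#' result is monotone in the threshold: lowering it can only add entries.
#'
#' @param dists A distributions tibble from [assess_distributions()].
#' @param threshold_pct Width threshold in percent, `> 0`.
#' @return The filtered tibble, with attribute `"threshold_pct"`.
#' @export
filter_wide <- function(dists, threshold_pct) {
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1 ||
      threshold_pct <= 0) {
    lenqc_abort("threshold_pct must be a single positive percentage",
                class = "domain_error")
  }
  out <- dists[dists$ratio_pct > threshold_pct, , drop = FALSE]
  stopifnot(all(out$ratio_pct > threshold_pct))
  attr(out, "threshold_pct") <- threshold_pct
  out
}

#' Decompose a family into its largest genera
#'
#' Lists the genera of a family with more than one sequence, sorted by
#' descending size (ties by name) and truncated to `max_genera`, each with
#' its boxplot descriptors. The per-genus minimum-count rule of
#' [assess_distributions()] deliberately does not apply here: any genus
#' with at least two sequences is informative about the family's spread.
#'
#' @param table A summary tibble with lineage columns filled.
#' @param family Family name present in the table.
#' @param max_genera Maximum number of genera returned (default 6).
#' @param whisker_k Whisker multiplier (default 1.5).
#' @return A tibble with `genus`, `n` and the boxplot descriptor columns.
#' @export
decompose_family <- function(table, family, max_genera = 6,
                             whisker_k = 1.5) {
  table <- as_summary_table(table)
  fam_rows <- table[!is.na(table$family) & table$family == family, ,
                    drop = FALSE]
  if (nrow(fam_rows) == 0) {
    lenqc_abort(paste0("family not present in table: ", family),
                class = "lookup_error")
  }
  fam_rows <- fam_rows[!is.na(fam_rows$genus), , drop = FALSE]
  counts <- table(fam_rows$genus)
  counts <- counts[counts > 1]
  if (length(counts) == 0) {
    return(tibble::tibble(genus = character(), n = integer(),
                          median = numeric(), q1 = numeric(), q3 = numeric(),
                          iqr = numeric(), lower_fence = numeric(),
                          upper_fence = numeric(), ratio_pct = numeric()))
  }
  ord <- order(-as.integer(counts), names(counts))
  keep <- head(names(counts)[ord], max_genera)
  dplyr::bind_rows(lapply(keep, function(g) {
    stats <- compute_boxplot_stats(
      fam_rows$length_bp[fam_rows$genus == g], whisker_k = whisker_k
    )
    dplyr::bind_cols(tibble::tibble(genus = g), stats)
  }))
}

#' Build the wide-distribution reports
#'
#' Produces the three report tables: `wide_all` (wide families and genera
#' together), `wide_families` (one row per wide family and member genus,
#' family columns alongside the genus breakdown) and `wide_genera`.
#'
#' @param table A summary tibble with lineage columns filled.
#' @param dist_family,dist_genus Distribution tibbles from
#'   [assess_distributions()].
#' @param wide_family_pct,wide_genus_pct Width thresholds in percent
#'   (defaults 10 and 1).
#' @param max_genera Genera retained per family breakdown (default 6).
#' @return A list with elements `wide_all`, `wide_families`, `wide_genera`.
#' @export
build_wide_reports <- function(table, dist_family, dist_genus,
                               wide_family_pct = 10, wide_genus_pct = 1,
                               max_genera = 6) {
  stat_cols <- c("rank", "taxon", "n", "median", "q1", "q3", "iqr",
                 "lower_fence", "upper_fence", "ratio_pct")
  wf <- filter_wide(dist_family, wide_family_pct)
  wg <- filter_wide(dist_genus, wide_genus_pct)
  wide_all <- dplyr::arrange(
    dplyr::bind_rows(wf[stat_cols], wg[stat_cols]),
    dplyr::desc(.data$ratio_pct), .data$taxon
  )
  wide_all$threshold_pct <- ifelse(wide_all$rank == "family",
                                   wide_family_pct, wide_genus_pct)

  fam_rows <- lapply(seq_len(nrow(wf)), function(i) {
    breakdown <- decompose_family(table, wf$taxon[i],
                                  max_genera = max_genera)
    fam <- wf[i, stat_cols]
    names(fam) <- paste0("family_", names(fam))
    fam$family_rank <- NULL
    names(fam)[names(fam) == "family_taxon"] <- "family"
    if (nrow(breakdown) == 0) {
      return(dplyr::bind_cols(fam, tibble::tibble(genus = NA_character_)))
    }
    names(breakdown)[-1] <- paste0("genus_", names(breakdown)[-1])
    dplyr::bind_cols(fam[rep(1, nrow(breakdown)), ], breakdown)
  })
  wide_families <- if (length(fam_rows) == 0) {
    tibble::tibble(family = character())
  } else {
    dplyr::bind_rows(fam_rows)
  }

  list(wide_all = wide_all,
       wide_families = wide_families,
       wide_genera = wg[c(stat_cols)])
}
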