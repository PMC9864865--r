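#' @title Boxplot descriptors and the IQR/median width statistic
#' @description
#' A taxon's length distribution is summarized by the classic five-number
#' boxplot descriptors: median, first and third quartile, and the Tukey
#' whisker fences at `q1 - k*IQR` and `q3 + k*IQR` with `k = 1.5` by
#' default. The single width descriptor is the IQR/median ratio expressed
#' as a percentage, `100 * IQR / median`: being scale-free it is comparable
#' across taxa whose typical plastome lengths differ.
#' @name boxplot-stats
NULL

#' Quantile of a length sample
#'
#' Linear interpolation between the closest order statistics at position
#' `p * (n - 1)` on the sorted sample (R's default type-7 estimator);
#' `p = 0` gives the minimum and `p = 1` the maximum. This is the
#' convention of the matplotlib/numpy plotting stack, and the one all
#' worked examples in the package are computed under. Alternative
#' interpolation rules can be selected with `type` (passed to
#' [stats::quantile()]); do not change it silently mid-analysis.
#'
#' @param values Numeric vector of lengths (bp), non-empty, no `NA`.
#' @param p Probability (vectorized) in `[0, 1]`.
#' @param type Quantile interpolation rule, 1--9; default 7.
#' @return Numeric vector of quantiles, one per `p`.
#' @examples
#' length_quantile(1:11, c(0.25, 0.5, 0.75))
#' @export
length_quantile <- function(values, p, type = 7) {
  if (length(values) == 0 || anyNA(values)) {
    lenqc_abort("quantile requires a non-empty sample without NA",
                class = "domain_error")
  }
  if (any(p < 0 | p > 1)) {
    lenqc_abort("quantile probabilities must lie in [0, 1]",
                class = "domain_error")
  }
  unname(stats::quantile(values, probs = p, type = type, names = FALSE))
}

#' Boxplot descriptors for a length sample
#'
#' Fences are the pure arithmetic Tukey values `q1 - k*IQR` and
#' `q3 + k*IQR`; they are *not* snapped to the most extreme in-fence
#' observation, since only fence placement (not whisker drawing) affects
#' outlier calls. With zero spread (IQR = 0) both fences collapse onto the
#' common value and the ratio is 0.
#'
#' @param lengths Numeric vector of sequence lengths in bp, all positive.
#' @param whisker_k Whisker multiplier `k` (default 1.5).
#' @param type Quantile interpolation rule (see [length_quantile()]).
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `lower_fence`, `upper_fence`, `ratio_pct`.
#' @examples
#' compute_boxplot_stats(c(140000, 150000, 160000))
#' @export
compute_boxplot_stats <- function(lengths, whisker_k = 1.5, type = 7) {
  if (length(lengths) == 0) {
    lenqc_abort("boxplot statistics require a non-empty sample",
                class = "domain_error")
  }
  if (anyNA(lengths) || any(lengths <= 0)) {
    lenqc_abort("all lengths must be positive and non-missing",
                class = "validation_error")
  }
  q <- length_quantile(lengths, c(0.25, 0.5, 0.75), type = type)
  iqr <- q[3] - q[1]
  tibble::tibble(
    n = length(lengths),
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    lower_fence = q[1] - whisker_k * iqr,
    upper_fence = q[3] + whisker_k * iqr,
    ratio_pct = 100 * iqr / q[2]
  )
}

#' Assess length distributions per family or genus
#'
#' Groups the table's records by the requested rank, drops taxa with fewer
#' than `min_n` records (tallied, not errored) as well as records whose
#' lineage lacks the rank, and computes boxplot descriptors per taxon.
#' Default minimum counts are 10 sequences per genus and 20 per family.
#'
#' @param table A summary tibble with lineage columns filled.
#' @param rank `"genus"` or `"family"`.
#' @param min_n Minimum number of records for a taxon to be assessed;
#'   defaults to 10 for genus and 20 for family.
#' @param whisker_k Whisker multiplier (default 1.5).
#' @return A tibble with one row per assessed taxon — columns `rank`,
#'   `taxon`, the [compute_boxplot_stats()] fields, plus list-columns
#'   `members` (accessions, input order) and `outliers` (filled by
#'   [detect_outliers()]) — sorted by descending `ratio_pct`, ties broken
#'   by taxon name. Attribute `"skipped"` reports the number of records
#'   without the rank and of taxa below `min_n`.
#' @export
assess_distributions <- function(table, rank = c("genus", "family"),
                                 min_n = NULL, whisker_k = 1.5) {
  rank <- tryCatch(match.arg(rank), error = function(e) {
    lenqc_abort("rank must be 'genus' or 'family'", class = "domain_error")
  })
  min_n <- min_n %||% if (rank == "genus") 10L else 20L
  stopifnot(min_n >= 1)
  table <- as_summary_table(table)
  labels <- table[[rank]]
  no_rank <- is.na(labels) | labels == ""
  eligible <- table[!no_rank, , drop = FALSE]
  counts <- table(eligible[[rank]])
  keep_taxa <- names(counts)[counts >= min_n]

  rows <- lapply(keep_taxa, function(tx) {
    sub <- eligible[eligible[[rank]] == tx, , drop = FALSE]
    stats <- compute_boxplot_stats(sub$length_bp, whisker_k = whisker_k)
    dplyr::bind_cols(
      tibble::tibble(rank = rank, taxon = tx),
      stats,
      tibble::tibble(members = list(sub$accession),
                     outliers = list(character(0)))
    )
  })
  out <- if (length(rows) == 0) {
    tibble::tibble(rank = character(), taxon = character(),
                   n = integer(), median = numeric(), q1 = numeric(),
                   q3 = numeric(), iqr = numeric(), lower_fence = numeric(),
                   upper_fence = numeric(), ratio_pct = numeric(),
                   members = list(), outliers = list())
  } else {
    dplyr::bind_rows(rows)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$ratio_pct), .data$taxon)
  attr(out, "skipped") <- list(
    records_without_rank = sum(no_rank),
    taxa_below_min_n = length(counts) - length(keep_taxa)
  )
  attr(out, "whisker_k") <- whisker_k
  out
}
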