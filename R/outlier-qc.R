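#' @title Outlier detection and the alternative-sequence check
#' @description
#' A record is an *outlier* in its genus when its length lies strictly
#' outside the Tukey fences of the genus distribution; a point exactly on a
#' fence is not an outlier. For each outlier species the GenBank archive is
#' then queried for other records of the same species; after removing
#' duplicates of the flagged record itself, any remaining *alternative*
#' whose length is strictly closer to the genus median suggests the flagged
#' assembly — not the species — is what is anomalous.
#' @name outlier-qc
NULL

outlier_cols <- function(n = 0) {
  tibble::tibble(rank = character(n), taxon = character(n),
                 accession = character(n), organism = character(n),
                 length_bp = integer(n),
                 published = as.Date(character(n)),
                 taxon_median = numeric(n), distance = numeric(n),
                 side = character(n))
}

#' Detect outlier records in assessed distributions
#'
#' For every distribution row, flags the member records whose length is
#' strictly below the lower fence or strictly above the upper fence.
#' Results are sorted by descending distance from the taxon median.
#'
#' @param dists A distributions tibble from [assess_distributions()] (one
#'   or more rows).
#' @param table The summary tibble the distributions were computed from.
#' @return A tibble with one row per outlier: `rank`, `taxon`, `accession`,
#'   `organism`, `length_bp`, `published`, `taxon_median`, `distance`
#'   (absolute bp distance to the median), `side` (`"low"`/`"high"`).
#' @export
detect_outliers <- function(dists, table) {
  table <- as_summary_table(table)
  rows <- lapply(seq_len(nrow(dists)), function(i) {
    members <- dists$members[[i]]
    idx <- match(members, table$accession)
    if (anyNA(idx)) {
      lenqc_abort(paste0("distribution members missing from table: ",
                         paste(members[is.na(idx)], collapse = ", ")),
                  class = "consistency_error")
    }
    sub <- table[idx, , drop = FALSE]
    out <- sub$length_bp < dists$lower_fence[i] |
      sub$length_bp > dists$upper_fence[i]
    if (!any(out)) return(NULL)
    sub <- sub[out, , drop = FALSE]
    tibble::tibble(
      rank = dists$rank[i], taxon = dists$taxon[i],
      accession = sub$accession, organism = sub$organism,
      length_bp = sub$length_bp, published = sub$published,
      taxon_median = dists$median[i],
      distance = abs(sub$length_bp - dists$median[i]),
      side = ifelse(sub$length_bp < dists$lower_fence[i], "low", "high")
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(outlier_cols())
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$distance), .data$accession)
}

#' Attach detected outliers to a distributions tibble
#'
#' Fills each distribution row's `outliers` list-column with the accessions
#' [detect_outliers()] flagged for that taxon.
#'
#' @param dists A distributions tibble.
#' @param outliers The tibble returned by [detect_outliers()].
#' @return `dists` with the `outliers` column populated.
#' @export
set_outliers <- function(dists, outliers) {
  dists$outliers <- lapply(seq_len(nrow(dists)), function(i) {
    outliers$accession[outliers$rank == dists$rank[i] &
                         outliers$taxon == dists$taxon[i]]
  })
  dists
}

#' Remove records identical to a flagged RefSeq record
#'
#' RefSeq is drawn from GenBank, so a species-level GenBank query returns
#' (at least) the flagged record itself and its pre-RefSeq submission.
#' Without downloading sequences, two desk-scale proxies identify these:
#' a shared accession stem, and exact length equality (treated as the same
#' assembly submitted twice). What remains are the genuinely *alternative*
#' records. The number of records removed is reported in the
#' `"n_identical"` attribute so users can audit the proxy.
#'
#' @param refseq_rec One-row summary tibble (the flagged record).
#' @param genbank_recs Summary tibble of same-species GenBank records.
#' @return The alternative records (possibly zero rows).
#' @export
dedupe_identical <- function(refseq_rec, genbank_recs) {
  if (nrow(genbank_recs) == 0) {
    out <- genbank_recs
    attr(out, "n_identical") <- 0L
    return(out)
  }
  same_stem <- accession_stem(genbank_recs$accession) ==
    accession_stem(refseq_rec$accession)
  same_len <- genbank_recs$length_bp == refseq_rec$length_bp
  out <- genbank_recs[!(same_stem | same_len), , drop = FALSE]
  attr(out, "n_identical") <- sum(same_stem | same_len)
  out
}

#' Is an alternative record closer to the genus median?
#'
#' Strict comparison of absolute distances: equal distance is not closer.
#'
#' @param genus_median Genus median length (bp).
#' @param refseq_len Flagged RefSeq record length (bp).
#' @param alt_len Alternative record length (bp). Vectorized.
#' @return Logical.
#' @examples
#' is_alternative_closer(146962, 142485, 146952)  # TRUE: 10 bp vs 4477 bp
#' @export
is_alternative_closer <- function(genus_median, refseq_len, alt_len) {
  abs(alt_len - genus_median) < abs(refseq_len - genus_median)
}

#' Assess alternative GenBank records for one outlier
#'
#' Queries the source for all GenBank records of the outlier's species,
#' removes duplicates of the flagged record ([dedupe_identical()]), and
#' selects the *best* candidate — minimal absolute distance to the genus
#' median, ties broken by earliest publication date then accession. The
#' `closer` flag holds when a best candidate exists and is strictly closer
#' than the flagged record; `any_closer` whether *any* candidate is.
#'
#' @param outlier One row of the tibble from [detect_outliers()]
#'   (genus-rank).
#' @param source A summary-source function answering species-level GenBank
#'   queries.
#' @return A one-row tibble: the outlier's identifying fields plus
#'   `n_candidates`, `best_accession`, `best_length`, `best_published`,
#'   `best_distance`, `closer`, `any_closer`.
#' @export
assess_alternatives <- function(outlier, source) {
  cands <- fetch_summaries(outlier$organism, source, db = "genbank")
  cands <- cands[cands$organism == outlier$organism, , drop = FALSE]
  alts <- dedupe_identical(
    tibble::tibble(accession = outlier$accession,
                   length_bp = outlier$length_bp),
    cands
  )
  base <- tibble::tibble(
    species = outlier$organism, genus = outlier$taxon,
    accession = outlier$accession, length_bp = outlier$length_bp,
    published = outlier$published,
    genus_median = outlier$taxon_median, distance = outlier$distance
  )
  if (nrow(alts) == 0) {
    return(dplyr::bind_cols(base, tibble::tibble(
      n_candidates = 0L, best_accession = NA_character_,
      best_length = NA_integer_, best_published = as.Date(NA),
      best_distance = NA_real_, closer = FALSE, any_closer = FALSE
    )))
  }
  dist <- abs(alts$length_bp - outlier$taxon_median)
  ord <- order(dist, alts$published, alts$accession)
  best <- alts[ord[1], , drop = FALSE]
  dplyr::bind_cols(base, tibble::tibble(
    n_candidates = nrow(alts),
    best_accession = best$accession,
    best_length = best$length_bp,
    best_published = best$published,
    best_distance = abs(best$length_bp - outlier$taxon_median),
    closer = is_alternative_closer(outlier$taxon_median,
                                   outlier$length_bp, best$length_bp),
    any_closer = any(is_alternative_closer(outlier$taxon_median,
                                           outlier$length_bp,
                                           alts$length_bp))
  ))
}

#' Assess alternatives for every genus-level outlier
#'
#' Runs [assess_alternatives()] per outlier; a transport failure for one
#' species is downgraded to a warning and does not stop the assessment of
#' the others (the failed row carries `NA` candidate fields).
#'
#' @param outliers Tibble from [detect_outliers()] at genus rank.
#' @param source A summary-source function.
#' @return A tibble with one row per outlier.
#' @export
assess_all_alternatives <- function(outliers, source) {
  rows <- lapply(seq_len(nrow(outliers)), function(i) {
    tryCatch(assess_alternatives(outliers[i, , drop = FALSE], source),
             lenqc_transport_error = function(e) {
               warn(paste0("alternative assessment failed for ",
                           outliers$organism[i], ": ", conditionMessage(e)))
               tibble::tibble(
                 species = outliers$organism[i], genus = outliers$taxon[i],
                 accession = outliers$accession[i],
                 length_bp = outliers$length_bp[i],
                 published = outliers$published[i],
                 genus_median = outliers$taxon_median[i],
                 distance = outliers$distance[i],
                 n_candidates = NA_integer_,
                 best_accession = NA_character_, best_length = NA_integer_,
                 best_published = as.Date(NA), best_distance = NA_real_,
                 closer = NA, any_closer = NA
               )
             })
  })
  if (length(rows) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(species = character(), genus = character(),
                     accession = character(), length_bp = integer(),
                     published = as.Date(character()),
                     genus_median = numeric(), distance = numeric()),
      tibble::tibble(n_candidates = integer(), best_accession = character(),
                     best_length = integer(),
                     best_published = as.Date(character()),
                     best_distance = numeric(), closer = logical(),
                     any_closer = logical())
    ))
  }
  dplyr::bind_rows(rows)
}
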