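#' @title Taxonomy tables and lineage resolution
#' @description
#' Rank grouping (genus/family) and clade labelling need a taxonomy. lenqc
#' uses a desk-scale analogue of the NCBI nodes/names dumps: a tibble with
#' columns `taxid`, `parent_taxid`, `rank`, `name`, where the root's
#' `parent_taxid` is `NA`. Ranks are free strings; `"genus"`, `"family"` and
#' `"species"` are interpreted canonically, and the informal clade labels
#' (asterids, rosids, ...) are matched by *name* against a configurable
#' label list because NCBI encodes them as non-canonical ranks.
#' @name taxonomy
NULL

default_clade_labels <- c("asterids", "rosids")

#' Read a taxonomy table
#'
#' @param path TSV file with columns `taxid`, `parent_taxid`, `rank`, `name`.
#' @return A validated taxonomy tibble.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) {
    lenqc_abort(paste0("taxonomy file does not exist: ", path),
                class = "io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    taxid = readr::col_integer(), parent_taxid = readr::col_integer(),
    rank = readr::col_character(), name = readr::col_character()
  ), progress = FALSE)
  validate_taxonomy(raw)
}

#' Validate a taxonomy table
#'
#' Checks that required columns are present, that every non-root parent
#' exists in the table, and that parent chains are acyclic.
#'
#' @param taxonomy A data frame of taxon records.
#' @return The taxonomy as a tibble, invisibly usable downstream.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- tibble::as_tibble(taxonomy)
  need <- c("taxid", "parent_taxid", "rank", "name")
  missing <- setdiff(need, names(taxonomy))
  if (length(missing) > 0) {
    lenqc_abort(paste0("taxonomy table is missing column(s): ",
                       paste(missing, collapse = ", ")),
                class = "schema_error")
  }
  orphan <- !is.na(taxonomy$parent_taxid) &
    !taxonomy$parent_taxid %in% taxonomy$taxid
  if (any(orphan)) {
    lenqc_abort(paste0("taxonomy parents missing from table for taxid(s): ",
                       paste(taxonomy$taxid[orphan], collapse = ", ")),
                class = "validation_error")
  }
  # cycle check: walking up from any node must terminate within |table| steps
  parent_of <- stats::setNames(taxonomy$parent_taxid, taxonomy$taxid)
  for (tid in taxonomy$taxid) {
    cur <- tid
    for (step in seq_len(nrow(taxonomy) + 1)) {
      cur <- parent_of[[as.character(cur)]]
      if (is.na(cur)) break
      if (cur == tid || step > nrow(taxonomy)) {
        lenqc_abort(paste0("taxonomy parent chain contains a cycle at taxid ",
                           tid), class = "validation_error")
      }
    }
  }
  taxonomy
}

#' Resolve the lineage of a taxon
#'
#' Walks the parent chain from the queried node upward, collecting the
#' nearest ancestor (or the node itself) of rank `genus` and `family`, and
#' the nearest node whose *name* appears in `clade_labels`. Absent ranks
#' yield `NA`; the species field falls back to the queried node's own name
#' when no species-rank node is on the chain.
#'
#' @param taxid_or_name A taxid (numeric) or an exact taxon name (string).
#' @param taxonomy A taxonomy tibble (see [read_taxonomy_table()]).
#' @param clade_labels Names treated as informal clade labels.
#' @return A one-row tibble with columns `species`, `genus`, `family`,
#'   `clade` (character, `NA` where the rank is absent).
#' @examples
#' tax <- tibble::tibble(
#'   taxid = 1:4, parent_taxid = c(NA, 1L, 2L, 3L),
#'   rank = c("clade", "family", "genus", "species"),
#'   name = c("asterids", "Convolvulaceae", "Cuscuta", "Cuscuta europaea")
#' )
#' resolve_lineage("Cuscuta europaea", tax)
#' @export
resolve_lineage <- function(taxid_or_name, taxonomy,
                            clade_labels = default_clade_labels) {
  taxonomy <- tibble::as_tibble(taxonomy)
  if (is.numeric(taxid_or_name)) {
    idx <- which(taxonomy$taxid == as.integer(taxid_or_name))
  } else {
    idx <- which(taxonomy$name == as.character(taxid_or_name))
  }
  if (length(idx) == 0) {
    lenqc_abort(paste0("taxon not found in taxonomy: ", taxid_or_name),
                class = "lookup_error")
  }
  if (length(idx) > 1) {
    lenqc_abort(paste0("ambiguous taxon name in taxonomy: ", taxid_or_name),
                class = "lookup_error")
  }

  species <- genus <- family <- clade <- NA_character_
  cur <- idx
  for (step in seq_len(nrow(taxonomy) + 1)) {
    rk <- taxonomy$rank[cur]
    nm <- taxonomy$name[cur]
    if (is.na(species) && identical(rk, "species")) species <- nm
    if (is.na(genus) && identical(rk, "genus")) genus <- nm
    if (is.na(family) && identical(rk, "family")) family <- nm
    if (is.na(clade) && nm %in% clade_labels) clade <- nm
    parent <- taxonomy$parent_taxid[cur]
    if (is.na(parent)) break
    cur <- which(taxonomy$taxid == parent)
  }
  if (is.na(species)) species <- taxonomy$name[idx]
  tibble::tibble(species = species, genus = genus,
                 family = family, clade = clade)
}

#' Resolve lineages for every record of a summary table
#'
#' Fills the `genus`, `family` and `clade` columns by resolving each record's
#' `taxid` (preferred) or `organism` name against the taxonomy. Records that
#' cannot be resolved keep `NA` lineage and are counted in the returned
#' `"skipped"` attribute rather than raising an error; at grouping time such
#' records are excluded from the affected rank.
#'
#' @param table A summary tibble.
#' @param taxonomy A taxonomy tibble.
#' @param clade_labels Names treated as informal clade labels.
#' @return The table with lineage columns filled; attribute
#'   `"skipped_lineage"` holds the number of unresolvable records.
#' @export
resolve_lineages <- function(table, taxonomy,
                             clade_labels = default_clade_labels) {
  table <- as_summary_table(table)
  skipped <- 0L
  for (i in seq_len(nrow(table))) {
    key <- if (!is.na(table$taxid[i])) table$taxid[i] else table$organism[i]
    lin <- tryCatch(resolve_lineage(key, taxonomy, clade_labels),
                    lenqc_lookup_error = function(e) NULL)
    if (is.null(lin)) {
      skipped <- skipped + 1L
      next
    }
    table$genus[i] <- lin$genus
    table$family[i] <- lin$family
    table$clade[i] <- lin$clade
  }
  attr(table, "skipped_lineage") <- skipped
  table
}
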