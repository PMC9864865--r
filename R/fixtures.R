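#' @title Synthetic fixtures with ground truth
#' @description
#' Offline testing and power checks need summary tables whose anomalies are
#' known. The generator emulates the structure of a RefSeq chloroplast
#' snapshot: genera of typical plastome length (120--170 kbp) with very
#' narrow normal spread (default sd 150 bp, matching the empirically tight
#' within-genus length distributions), plus three generative regimes —
#' `narrow`, `wide_parasite` (spread inflated so the genus IQR/median ratio
#' exceeds 1%, as in strongly reduced parasite plastomes) and
#' `ir_loss_shift` (a random subset of members shifted down by one
#' IR-copy-scale step, giving a bimodal sample). Mis-assembly is emulated by
#' injecting signed length offsets (default magnitude 25 kbp) into
#' otherwise-typical members; every injected record is recorded in the
#' ground truth. A GenBank-style mirror adds, for every RefSeq record, its
#' identical-length pre-RefSeq submission, and for injected outliers a
#' "corrected" alternative near the genus center.
#' @name synthetic-fixtures
NULL

#' Specify one synthetic genus
#'
#' @param genus,family Names of the genus and its family.
#' @param clade Informal clade label (`"asterids"` or `"rosids"`).
#' @param n Number of records to generate (>= 1).
#' @param center Typical plastome length in bp (plastomes run roughly
#'   120--170 kbp).
#' @param spread_sd Within-genus standard deviation in bp (default 150).
#' @param injected_outliers Signed bp offsets, one injected record each.
#' @param regime `"narrow"`, `"wide_parasite"` or `"ir_loss_shift"`.
#' @return A `genus_spec` list.
#' @export
genus_spec <- function(genus, family, clade = "asterids", n = 30,
                       center = 150000, spread_sd = 150,
                       injected_outliers = numeric(0),
                       regime = c("narrow", "wide_parasite",
                                  "ir_loss_shift")) {
  regime <- match.arg(regime)
  stopifnot(n >= 1, spread_sd >= 0, center > 0,
            all(abs(injected_outliers) > 0),
            length(injected_outliers) <= n)
  structure(list(genus = genus, family = family, clade = clade, n = n,
                 center = center, spread_sd = spread_sd,
                 injected_outliers = injected_outliers, regime = regime),
            class = "genus_spec")
}

#' Default fixture: the package's reference study conditions
#'
#' Six genera in five families across both clades: four clean narrow genera
#' (n = 30, sd = 150 bp; two carry one injected mis-assembly offset of
#' +/-25 kbp), one parasite-like wide genus (n = 20), one bimodal IR-loss
#' genus (n = 12, below the family minimum so its family is skipped), and
#' one genus of n = 9 that falls below the genus minimum.
#'
#' @return A list of [genus_spec()] objects.
#' @export
default_fixture_specs <- function() {
  list(
    genus_spec("Fictulus", "Fictaceae", "asterids", n = 30,
               center = 152000),
    genus_spec("Simulago", "Fictaceae", "asterids", n = 30,
               center = 150500, injected_outliers = 25000),
    genus_spec("Parasimia", "Paraceae", "asterids", n = 20,
               center = 120000, regime = "wide_parasite"),
    genus_spec("Rosulago", "Rosulaceae", "rosids", n = 30,
               center = 156000, injected_outliers = -25000),
    genus_spec("Exemplum", "Rosulaceae", "rosids", n = 30,
               center = 158000),
    genus_spec("Varigena", "Variaceae", "rosids", n = 12,
               center = 155000, regime = "ir_loss_shift"),
    genus_spec("Minorus", "Minoraceae", "rosids", n = 9,
               center = 140000)
  )
}

#' Generate a synthetic RefSeq-style summary table with ground truth
#'
#' Per genus, draws `n` lengths from a normal law `(center, spread_sd)`,
#' rounded to integer bp and clipped to >= 10 kbp. The `wide_parasite`
#' regime multiplies `spread_sd` by `wide_sd_factor` (default 20, putting
#' the expected IQR/median ratio well above 1%); `ir_loss_shift` subtracts
#' `ir_shift` bp from a random subset (at least one member) giving a
#' bimodal sample. Each injected outlier offset is added to one
#' otherwise-typical member and that accession is recorded in the truth.
#' Organisms get synthetic binomials, accessions and taxids are assigned
#' deterministically, and a matching taxonomy table is emitted. Identical
#' `(specs, seed)` give bit-identical output.
#'
#' @param specs List of [genus_spec()] objects.
#' @param seed Integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @param wide_sd_factor Spread multiplier for `wide_parasite` (default 20).
#' @param ir_shift Downward shift in bp for `ir_loss_shift` (default
#'   25000, one IR copy).
#' @param ir_prob Per-member probability of the IR-loss shift (default
#'   0.4).
#' @return A list of class `lenqc_fixture`: `table` (summary tibble,
#'   `source_db = "refseq"`), `taxonomy` (taxonomy tibble), `truth` (list
#'   with `outlier_accessions`, `wide_taxa`, `corrected_alternatives`).
#' @export
generate_fixture <- function(specs, seed, wide_sd_factor = 20,
                             ir_shift = 25000, ir_prob = 0.4) {
  if (missing(seed) || is.null(seed)) {
    lenqc_abort("generate_fixture requires an explicit seed",
                class = "domain_error")
  }
  if (inherits(specs, "genus_spec")) specs <- list(specs)
  withr::with_seed(seed, {
    acc <- 0L
    species_taxid <- 10000L
    rows <- list()
    truth_outliers <- character(0)
    wide_taxa <- tibble::tibble(rank = character(), name = character())

    tax_rows <- list(tibble::tibble(
      taxid = 1L, parent_taxid = NA_integer_, rank = "no rank",
      name = "Eudicotyledons"
    ))
    clades <- unique(vapply(specs, `[[`, "", "clade"))
    clade_ids <- stats::setNames(seq_along(clades) + 9L, clades)
    for (cl in clades) {
      tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
        taxid = clade_ids[[cl]], parent_taxid = 1L, rank = "clade",
        name = cl
      )
    }
    fams <- unique(vapply(specs, `[[`, "", "family"))
    fam_ids <- stats::setNames(seq_along(fams) + 99L, fams)
    for (sp in specs) {
      if (!any(vapply(tax_rows, function(t) fam_ids[[sp$family]] %in% t$taxid,
                      logical(1)))) {
        tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
          taxid = fam_ids[[sp$family]],
          parent_taxid = clade_ids[[sp$clade]],
          rank = "family", name = sp$family
        )
      }
    }
    genus_ids <- stats::setNames(seq_along(specs) + 999L,
                                 vapply(specs, `[[`, "", "genus"))

    for (sp in specs) {
      gid <- genus_ids[[sp$genus]]
      tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
        taxid = gid, parent_taxid = fam_ids[[sp$family]],
        rank = "genus", name = sp$genus
      )
      sd_eff <- if (sp$regime == "wide_parasite") {
        sp$spread_sd * wide_sd_factor
      } else {
        sp$spread_sd
      }
      lengths <- pmax(10000, round(rnorm(sp$n, sp$center, sd_eff)))
      if (sp$regime == "ir_loss_shift") {
        shifted <- runif(sp$n) < ir_prob
        if (!any(shifted)) shifted[1] <- TRUE
        lengths[shifted] <- pmax(10000, lengths[shifted] - ir_shift)
      }
      k <- length(sp$injected_outliers)
      targets <- if (k > 0) sample(sp$n, k) else integer(0)
      lengths[targets] <- pmax(10000,
                               lengths[targets] + sp$injected_outliers)

      accs <- sprintf("NC_%06d.1", acc + seq_len(sp$n))
      acc <- acc + sp$n
      taxids <- species_taxid + seq_len(sp$n)
      species_names <- paste(sp$genus, sprintf("fictus%02d", seq_len(sp$n)))
      species_taxid <- species_taxid + sp$n

      tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
        taxid = taxids, parent_taxid = gid, rank = "species",
        name = species_names
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        accession = accs, organism = species_names, taxid = taxids,
        length_bp = as.integer(lengths),
        published = as.Date("2015-01-01") + sample.int(2500, sp$n,
                                                       replace = TRUE),
        source_db = "refseq", genus = sp$genus, family = sp$family,
        clade = sp$clade
      )
      truth_outliers <- c(truth_outliers, accs[targets])
      if (sp$regime == "wide_parasite") {
        wide_taxa <- dplyr::bind_rows(
          wide_taxa, tibble::tibble(rank = "genus", name = sp$genus)
        )
      }
    }
    table <- as_summary_table(dplyr::bind_rows(rows),
                              provenance = paste0("synthetic fixture, seed ",
                                                  seed))
    taxonomy <- validate_taxonomy(dplyr::bind_rows(tax_rows))
    structure(list(
      table = table, taxonomy = taxonomy,
      truth = list(outlier_accessions = truth_outliers,
                   wide_taxa = wide_taxa,
                   corrected_alternatives = character(0)),
      specs = specs, seed = seed
    ), class = "lenqc_fixture")
  })
}

#' Generate a GenBank-style mirror of a fixture table
#'
#' Emits one identical-length GenBank duplicate per RefSeq record (distinct
#' accession, earlier publication date — the pre-RefSeq submission), and
#' for each ground-truth outlier, with probability `correction_prob`, a
#' "corrected" alternative whose length is drawn uniformly within one
#' empirical standard deviation of the genus's clean-member median. Each
#' emitted alternative is recorded in `truth$corrected_alternatives`.
#'
#' @param table Fixture summary table (RefSeq side).
#' @param truth Fixture truth list.
#' @param seed Integer seed.
#' @param correction_prob Probability an outlier gets a corrected
#'   alternative (default 1).
#' @return A list: `mirror` (GenBank-side summary tibble) and `truth`
#'   (updated, with `corrected_alternatives` as a named character vector
#'   outlier accession -> alternative accession).
#' @export
generate_genbank_mirror <- function(table, truth, seed,
                                    correction_prob = 1) {
  withr::with_seed(seed, {
    dup <- table
    dup$accession <- sprintf("MK%06d.1", seq_len(nrow(table)))
    dup$published <- table$published - 200
    dup$source_db <- "genbank"

    alt_rows <- list()
    corrected <- character(0)
    j <- 0L
    for (out_acc in truth$outlier_accessions) {
      if (runif(1) >= correction_prob) next
      i <- match(out_acc, table$accession)
      g <- table$genus[i]
      clean <- table$length_bp[table$genus == g &
                                 !table$accession %in%
                                 truth$outlier_accessions]
      med <- median(clean)
      s <- max(sd(clean), 1)
      j <- j + 1L
      alt_acc <- sprintf("OM%06d.1", j)
      alt_rows[[j]] <- tibble::tibble(
        accession = alt_acc, organism = table$organism[i],
        taxid = table$taxid[i],
        length_bp = as.integer(round(runif(1, med - s, med + s))),
        published = max(table$published) + 30,
        source_db = "genbank", genus = g, family = table$family[i],
        clade = table$clade[i]
      )
      corrected[out_acc] <- alt_acc
    }
    mirror <- as_summary_table(
      dplyr::bind_rows(c(list(dup), alt_rows)),
      provenance = paste0("synthetic GenBank mirror, seed ", seed)
    )
    truth$corrected_alternatives <- corrected
    list(mirror = mirror, truth = truth)
  })
}

#' Write a fixture to a directory
#'
#' Emits `refseq.tsv`, `genbank.tsv` (if a mirror is present),
#' `taxonomy.tsv` and `truth.json` — the layout [fixture_source()] serves.
#'
#' @param fixture A `lenqc_fixture` (optionally with `$mirror` attached).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_table(fixture$table, file.path(dir, "refseq.tsv"))
  if (!is.null(fixture$mirror)) {
    write_summary_table(fixture$mirror, file.path(dir, "genbank.tsv"))
  }
  readr::write_tsv(fixture$taxonomy, file.path(dir, "taxonomy.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(
      outlier_accessions = fixture$truth$outlier_accessions,
      wide_taxa = fixture$truth$wide_taxa,
      corrected_alternatives = as.list(fixture$truth$corrected_alternatives)
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null"
  )
  invisible(dir)
}

#' Build and write a complete fixture in one call
#'
#' [generate_fixture()] plus [generate_genbank_mirror()] plus
#' [write_fixture()]. The mirror uses `seed + 1` so the two stages draw
#' independent streams.
#'
#' @inheritParams generate_fixture
#' @param dir Output directory, or `NULL` to skip writing.
#' @param correction_prob Passed to [generate_genbank_mirror()].
#' @param ... Passed on to [generate_fixture()].
#' @return The `lenqc_fixture` with `$mirror` attached (invisibly if
#'   written).
#' @export
make_fixture <- function(specs = default_fixture_specs(), seed = 1,
                         dir = NULL, correction_prob = 1, ...) {
  fx <- generate_fixture(specs, seed, ...)
  mir <- generate_genbank_mirror(fx$table, fx$truth, seed + 1,
                                 correction_prob = correction_prob)
  fx$mirror <- mir$mirror
  fx$truth <- mir$truth
  if (!is.null(dir)) {
    write_fixture(fx, dir)
    return(invisible(fx))
  }
  fx
}
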