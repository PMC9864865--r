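#' @title Diagnostic figures
#' @description
#' Figures are a side output of the pipeline and are validated
#' structurally (subplot counts, titles, threshold lines), not
#' pixel-exactly. Boxplot/violin panels are colored by informal clade
#' (asterids/rosids) where lineage labels provide one.
#' @name plots
NULL

#' Histogram of IQR/median ratios with threshold lines
#'
#' Family and genus ratios overlaid, with dashed vertical lines at the
#' configured wideness thresholds.
#'
#' @param dist_family,dist_genus Distribution tibbles.
#' @param wide_family_pct,wide_genus_pct Thresholds in percent.
#' @return A ggplot object.
#' @export
plot_ratio_histogram <- function(dist_family, dist_genus,
                                 wide_family_pct = 10, wide_genus_pct = 1) {
  dat <- dplyr::bind_rows(
    dist_family[c("rank", "taxon", "ratio_pct")],
    dist_genus[c("rank", "taxon", "ratio_pct")]
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio_pct,
                                    fill = .data$rank)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6,
                            bins = 30) +
    ggplot2::geom_vline(xintercept = c(wide_genus_pct, wide_family_pct),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(family = "#d62728",
                                          genus = "#1f77b4")) +
    ggplot2::labs(x = "IQR/median ratio (%)", y = "count",
                  title = "Width of length distributions by rank")
}

#' Per-family overview panel
#'
#' Counts per family, length boxplots per family, and length violins per
#' publication year; colored by clade. Combined with patchwork when
#' available, otherwise returned as a list of the three panels.
#'
#' @param table A summary tibble with lineage columns filled.
#' @return A patchwork/ggplot object, or a list of ggplots.
#' @export
plot_family_panel <- function(table) {
  dat <- table[!is.na(table$family), , drop = FALSE]
  dat$year <- factor(format(dat$published, "%Y"))
  p_counts <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$family,
                                                fill = .data$clade)) +
    ggplot2::geom_bar() +
    ggplot2::labs(y = "sequences", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  p_lengths <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$family,
                                                 y = .data$length_bp,
                                                 fill = .data$clade)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "length (bp)", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  p_years <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$year,
                                               y = .data$length_bp)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::labs(y = "length (bp)", x = "publication year")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p_counts / p_lengths / p_years
  } else {
    list(counts = p_counts, lengths = p_lengths, years = p_years)
  }
}

#' Wide-family decomposition plot
#'
#' The family's length distribution as a boxplot with violins for its
#' largest genera (at most `max_genera` genera with more than one
#' sequence).
#'
#' @param table A summary tibble with lineage columns filled.
#' @param family Family name.
#' @param max_genera Maximum genera shown (default 6).
#' @return A ggplot object.
#' @export
plot_family_decomposition <- function(table, family, max_genera = 6) {
  breakdown <- decompose_family(table, family, max_genera = max_genera)
  fam_stats <- compute_boxplot_stats(
    table$length_bp[!is.na(table$family) & table$family == family]
  )
  dat <- table[!is.na(table$genus) & !is.na(table$family) &
                 table$family == family &
                 table$genus %in% breakdown$genus, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genus, y = .data$length_bp,
                                    fill = .data$genus)) +
    ggplot2::geom_violin(alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.15, fill = "white",
                          outlier.shape = 1) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(
      x = NULL, y = "length (bp)",
      title = sprintf("%s (ratio=%.2f%%, n=%d)", family,
                      fam_stats$ratio_pct, fam_stats$n)
    )
}

#' Composite box/violin plots of wide genera
#'
#' One facet per wide genus, titled
#' `"genus (family) n=..., ratio=...%"`, arranged in descending ratio
#' order.
#'
#' @param table A summary tibble with lineage columns filled.
#' @param wide_genera The `wide_genera` tibble of a pipeline result.
#' @return A ggplot object, or `NULL` (with a warning) when no genus is
#'   wide.
#' @export
plot_wide_genera <- function(table, wide_genera) {
  if (nrow(wide_genera) == 0) {
    warn("no wide genera to plot")
    return(NULL)
  }
  fam_of <- function(g) {
    f <- unique(table$family[!is.na(table$genus) & table$genus == g])
    f <- f[!is.na(f)]
    if (length(f) == 0) "?" else f[1]
  }
  labels <- sprintf("%s (%s) n=%d, ratio=%.2f%%", wide_genera$taxon,
                    vapply(wide_genera$taxon, fam_of, ""),
                    wide_genera$n, wide_genera$ratio_pct)
  dat <- dplyr::bind_rows(lapply(seq_len(nrow(wide_genera)), function(i) {
    sub <- table[!is.na(table$genus) &
                   table$genus == wide_genera$taxon[i], , drop = FALSE]
    sub$panel <- labels[i]
    sub
  }))
  dat$panel <- factor(dat$panel, levels = labels)
  ggplot2::ggplot(dat, ggplot2::aes(x = "", y = .data$length_bp,
                                    fill = .data$clade)) +
    ggplot2::geom_violin(alpha = 0.7) +
    ggplot2::geom_boxplot(width = 0.15, fill = "white",
                          outlier.shape = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "length (bp)")
}

#' Write all report figures
#'
#' Emits the family overview, the ratio histogram with threshold lines,
#' one decomposition plot per wide family, and the wide-genus composite,
#' in the requested formats (vector and raster). An empty result is a
#' no-op with a warning.
#'
#' @param result A `lenqc_result`.
#' @param outdir Output directory (created if needed).
#' @param formats Device formats, subset of `c("png", "svg")`.
#' @param width,height Figure size in inches.
#' @return Invisibly, the paths written.
#' @export
plot_report <- function(result, outdir, formats = c("png", "svg"),
                        width = 9, height = 6) {
  if (nrow(result$table) == 0) {
    warn("empty result: no figures written")
    return(invisible(character(0)))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  plots <- list(families = plot_family_panel(result$table),
                ratio_histogram = plot_ratio_histogram(
                  result$dist_family, result$dist_genus,
                  result$config$wide_family_pct,
                  result$config$wide_genus_pct))
  for (fam in unique(result$wide_all$taxon[result$wide_all$rank ==
                                             "family"])) {
    plots[[paste0("wide_family_", fam)]] <-
      plot_family_decomposition(result$table, fam,
                                max_genera = result$config$max_genera)
  }
  if (nrow(result$wide_genera) > 0) {
    plots$wide_genera <- plot_wide_genera(result$table,
                                          result$wide_genera)
  }
  paths <- character(0)
  for (nm in names(plots)) {
    for (fmt in formats) {
      p <- file.path(outdir, paste0(nm, ".", fmt))
      ggplot2::ggsave(p, plots[[nm]], width = width, height = height)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
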