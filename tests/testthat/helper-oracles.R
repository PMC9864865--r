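# Independent brute-force oracles, deliberately written from first
# principles (sort + index arithmetic) rather than through any library
# quantile routine, so they can cross-check the package implementation.

oracle_quantile <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  vapply(p, function(pp) {
    h <- pp * (n - 1)
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo + 1] + (h - lo) * (s[hi + 1] - s[lo + 1])
  }, numeric(1))
}

oracle_boxplot <- function(lengths, k = 1.5) {
  q <- oracle_quantile(lengths, c(0.25, 0.5, 0.75))
  iqr <- q[3] - q[1]
  list(n = length(lengths), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       lower_fence = q[1] - k * iqr, upper_fence = q[3] + k * iqr,
       ratio_pct = 100 * iqr / q[2])
}

# O(n) fence scan: returns the indices of outlying values.
oracle_outliers <- function(lengths, k = 1.5) {
  o <- oracle_boxplot(lengths, k)
  which(lengths < o$lower_fence | lengths > o$upper_fence)
}

# A small hand-built summary table: two genera in one family plus one
# ungrouped record.
tiny_table <- function() {
  tibble::tibble(
    accession = sprintf("NC_%06d.1", 1:8),
    organism = c(paste("Alpha sp", 1:4), paste("Beta sp", 1:3),
                 "Gamma solo"),
    taxid = NA_integer_,
    length_bp = c(150000L, 151000L, 152000L, 150500L,
                  140000L, 150000L, 160000L, 130000L),
    published = as.Date("2020-01-01") + 0:7,
    source_db = "refseq",
    genus = c(rep("Alpha", 4), rep("Beta", 3), NA),
    family = c(rep("Alphaceae", 7), NA),
    clade = "asterids"
  )
}

tiny_taxonomy <- function() {
  tibble::tibble(
    taxid = c(1L, 2L, 3L, 4L, 5L, 6L),
    parent_taxid = c(NA, 1L, 2L, 3L, 4L, 3L),
    rank = c("no rank", "clade", "family", "genus", "species", "genus"),
    name = c("Eudicotyledons", "asterids", "Convolvulaceae", "Cuscuta",
             "Cuscuta europaea", "Ipomoea")
  )
}

# A deterministic in-memory summary source over explicit tables.
memory_source <- function(refseq, genbank) {
  function(query, db = c("refseq", "genbank")) {
    db <- match.arg(db)
    tab <- if (db == "refseq") refseq else genbank
    if (identical(query, "")) return(tab)
    tab[tab$organism == query |
          startsWith(tab$organism, paste0(query, " ")), , drop = FALSE]
  }
}
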