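make_genus_table <- function(lengths, genus = "Testus",
                             family = "Testaceae") {
  tibble::tibble(
    accession = sprintf("NC_%06d.1", seq_along(lengths)),
    organism = paste(genus, sprintf("sp%02d", seq_along(lengths))),
    taxid = NA_integer_, length_bp = as.integer(lengths),
    published = as.Date("2020-01-01") + seq_along(lengths),
    source_db = "refseq", genus = genus, family = family,
    clade = NA_character_
  )
}

detect_on <- function(lengths) {
  tab <- make_genus_table(lengths)
  d <- assess_distributions(tab, "genus", min_n = 1)
  detect_outliers(d, tab)
}

test_that("outliers are exactly the points strictly outside the fences", {
  # nine identical + one shrunken record: the single outlier, low side
  out <- detect_on(c(rep(150000, 9), 120000))
  expect_equal(nrow(out), 1)
  expect_equal(out$length_bp, 120000L)
  expect_equal(out$side, "low")
  expect_equal(out$distance, 30000)

  # constant sample: fences collapse, nothing strictly outside
  expect_equal(nrow(detect_on(rep(150000, 10))), 0)

  # 1..11: fences at -4 and 16 contain every point
  expect_equal(nrow(detect_on(1:11 * 1L)), 0)

  # a point exactly on a fence is not an outlier (strict inequality)
  # lengths 10,12,14,16,18: q1=12, q3=16, fences 6 and 22
  expect_equal(nrow(detect_on(c(10, 12, 14, 16, 18) * 1L)), 0)
  out <- detect_on(c(10, 12, 14, 16, 23) * 1L)  # fences 6.5 / 22.5
  expect_equal(out$length_bp, 23L)
  expect_equal(out$side, "high")
})

test_that("detection agrees with the brute-force fence scan", {
  withr::local_seed(99)
  for (i in 1:300) {
    n <- sample(2:200, 1)
    x <- round(c(rnorm(n - 1, 150000, sample(c(100, 1000, 10000), 1)),
                 runif(1, 100000, 250000)))
    x <- pmax(x, 10001)
    got <- detect_on(x)
    want <- oracle_outliers(x)
    expect_setequal(got$accession, sprintf("NC_%06d.1", want))
  }
})

test_that("detected outliers are written back into the distribution", {
  tab <- make_genus_table(c(rep(150000, 9), 120000))
  d <- assess_distributions(tab, "genus", min_n = 1)
  out <- detect_outliers(d, tab)
  d <- set_outliers(d, out)
  expect_equal(d$outliers[[1]], "NC_000010.1")

  # member accession missing from the table is a consistency error
  expect_error(detect_outliers(d, tab[-10, ]),
               class = "lenqc_consistency_error")
})

test_that("dedupe_identical removes same-stem and same-length records", {
  ref <- tibble::tibble(accession = "NC_000001.1", length_bp = 150000L)
  gb <- tibble::tibble(
    accession = c("MK000001.1", "MK000002.1", "NC_000001.2"),
    length_bp = c(150000L, 149999L, 140000L)
  )
  alts <- dedupe_identical(ref, gb)
  expect_equal(alts$accession, "MK000002.1")
  expect_equal(attr(alts, "n_identical"), 2L)

  empty <- dedupe_identical(ref, gb[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the closer-to-median comparison is strict", {
  expect_true(is_alternative_closer(146962, 142485, 146952))
  expect_true(is_alternative_closer(160971, 232020, 160976))
  expect_false(is_alternative_closer(150000, 149000, 149000))
  expect_false(is_alternative_closer(150000, 149000, 151000))  # tie
})

test_that("assess_alternatives picks the best candidate and verdicts", {
  lengths <- c(rep(155600, 9), 129788)
  tab <- make_genus_table(lengths, genus = "Fragaria")
  d <- assess_distributions(tab, "genus", min_n = 1)
  out <- detect_outliers(d, tab)
  med <- d$median

  gb <- tibble::tibble(
    accession = c("MK000010.1", "KC507757.1", "MG000001.1"),
    organism = out$organism,
    taxid = NA_integer_,
    length_bp = c(129788L, as.integer(med - 10), as.integer(med + 4477)),
    published = as.Date(c("2012-10-01", "2016-07-26", "2013-01-01")),
    source_db = "genbank"
  )
  src <- memory_source(tab, gb)
  a <- assess_alternatives(out[1, ], src)
  # the identical-length duplicate is excluded; distance-10 beats 4477
  expect_equal(a$n_candidates, 2L)
  expect_equal(a$best_accession, "KC507757.1")
  expect_true(a$closer)
  expect_true(a$any_closer)
  # the outlier's own record never appears among candidates
  expect_false(a$best_accession %in% out$accession)

  # tie on distance is broken by earliest publication date
  gb2 <- gb
  gb2$length_bp <- c(129788L, as.integer(med - 10), as.integer(med + 10))
  gb2$published <- as.Date(c("2012-10-01", "2016-07-26", "2014-01-01"))
  a2 <- assess_alternatives(out[1, ], memory_source(tab, gb2))
  expect_equal(a2$best_accession, "MG000001.1")

  # no candidates after dedup -> NULL best, closer FALSE
  gb3 <- gb[1, ]
  a3 <- assess_alternatives(out[1, ], memory_source(tab, gb3))
  expect_equal(a3$n_candidates, 0L)
  expect_true(is.na(a3$best_accession))
  expect_false(a3$closer)
})

test_that("a transport failure for one outlier does not stop the rest", {
  tab <- make_genus_table(c(rep(150000, 8), 120000, 180000))
  d <- assess_distributions(tab, "genus", min_n = 1)
  out <- detect_outliers(d, tab)
  expect_equal(nrow(out), 2)
  flaky <- function(query, db) {
    if (query == out$organism[1]) stop("simulated timeout")
    tibble::tibble(accession = "MK999999.1", organism = query,
                   taxid = NA_integer_, length_bp = 150001L,
                   published = as.Date("2021-01-01"),
                   source_db = "genbank")
  }
  expect_warning(a <- assess_all_alternatives(out, flaky),
                 "simulated timeout")
  expect_equal(nrow(a), 2)
  expect_true(is.na(a$closer[1]))
  expect_true(a$closer[2])
})

test_that("closer implies the best candidate is strictly nearer the median", {
  withr::local_seed(17)
  for (i in 1:100) {
    med <- 150000
    ref_len <- med + sample(c(-1, 1), 1) * sample(5000:40000, 1)
    cand <- tibble::tibble(
      accession = sprintf("MK%06d.1", 1:3), organism = "Testus sp01",
      taxid = NA_integer_,
      length_bp = as.integer(med + sample(-30000:30000, 3)),
      published = as.Date("2020-01-01") + 1:3, source_db = "genbank"
    )
    out <- tibble::tibble(
      rank = "genus", taxon = "Testus", accession = "NC_000001.1",
      organism = "Testus sp01", length_bp = as.integer(ref_len),
      published = as.Date("2019-01-01"), taxon_median = med,
      distance = abs(ref_len - med), side = "high"
    )
    a <- assess_alternatives(out, memory_source(NULL, cand))
    if (isTRUE(a$closer)) {
      expect_lt(a$best_distance, a$distance)
    }
  }
})
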