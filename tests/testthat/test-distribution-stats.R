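test_that("quantiles follow the linear-interpolation convention", {
  expect_equal(length_quantile(1:11, 0.5), 6)
  expect_equal(length_quantile(1:11, 0.25), 3.5)
  expect_equal(length_quantile(1:11, c(0, 1)), c(1, 11))
  expect_equal(length_quantile(rep(150000, 10), 0.73), 150000)
  # permutation invariance
  expect_equal(length_quantile(sample(1:11), 0.25), 3.5)
  expect_error(length_quantile(numeric(0), 0.5),
               class = "lenqc_domain_error")
  expect_error(length_quantile(1:5, 1.2), class = "lenqc_domain_error")
})

test_that("boxplot statistics match hand-derived examples", {
  s <- compute_boxplot_stats(rep(150000, 10))
  expect_equal(s$median, 150000)
  expect_equal(s$iqr, 0)
  expect_equal(s$ratio_pct, 0)
  expect_equal(s$lower_fence, 150000)
  expect_equal(s$upper_fence, 150000)

  s <- compute_boxplot_stats(1:11)
  expect_equal(s$median, 6)
  expect_equal(s$q1, 3.5)
  expect_equal(s$q3, 8.5)
  expect_equal(s$iqr, 5)
  expect_equal(s$ratio_pct, 100 * 5 / 6)

  # n = 3: quartiles interpolate to 145000/155000, so IQR = 10000 and the
  # fences sit at 145000 - 15000 and 155000 + 15000 (oracle-checked)
  s <- compute_boxplot_stats(c(140000, 150000, 160000))
  expect_equal(s$median, 150000)
  expect_equal(s$q1, 145000)
  expect_equal(s$q3, 155000)
  expect_equal(s$iqr, 10000)
  expect_equal(s$ratio_pct, 100 / 15)
  expect_equal(s$lower_fence, 130000)
  expect_equal(s$upper_fence, 170000)
  expect_equal(unclass(s), unclass(tibble::as_tibble(
    oracle_boxplot(c(140000, 150000, 160000))
  )), ignore_attr = TRUE)

  expect_error(compute_boxplot_stats(numeric(0)),
               class = "lenqc_domain_error")
  expect_error(compute_boxplot_stats(c(1000, -5)),
               class = "lenqc_validation_error")
})

test_that("boxplot statistics agree with the brute-force oracle", {
  withr::local_seed(42)
  for (i in 1:300) {
    n <- sample(2:200, 1)
    x <- round(runif(n, 10000, 300000))
    got <- compute_boxplot_stats(x)
    want <- oracle_boxplot(x)
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9)
    }
  }
})

test_that("location shifts and scalings act as expected on the stats", {
  withr::local_seed(7)
  for (i in 1:50) {
    x <- round(runif(sample(3:80, 1), 100000, 200000))
    base <- compute_boxplot_stats(x)
    shifted <- compute_boxplot_stats(x + 5000)
    for (f in c("median", "q1", "q3", "lower_fence", "upper_fence")) {
      expect_equal(shifted[[f]], base[[f]] + 5000)
    }
    expect_equal(shifted$iqr, base$iqr)
    if (base$iqr > 0) expect_lt(shifted$ratio_pct, base$ratio_pct)

    scaled <- compute_boxplot_stats(x * 3)
    for (f in c("median", "q1", "q3", "iqr", "lower_fence",
                "upper_fence")) {
      expect_equal(scaled[[f]], base[[f]] * 3)
    }
    expect_equal(scaled$ratio_pct, base$ratio_pct)

    # permutation invariance of the whole descriptor set
    perm <- compute_boxplot_stats(sample(x))
    expect_equal(perm, base)
  }
})

test_that("assess_distributions applies the minimum-count rules", {
  tab <- tiny_table()  # Alpha n=4, Beta n=3, one record without genus
  d <- assess_distributions(tab, "genus", min_n = 4)
  expect_equal(d$taxon, "Alpha")
  expect_equal(attr(d, "skipped")$taxa_below_min_n, 1)
  expect_equal(attr(d, "skipped")$records_without_rank, 1)

  # a genus of 9 is omitted at the default minimum of 10
  fx <- generate_fixture(list(
    genus_spec("Nine", "FamN", n = 9, center = 150000),
    genus_spec("Ten", "FamN", n = 10, center = 150000)
  ), seed = 5)
  d <- assess_distributions(fx$table, "genus")
  expect_equal(d$taxon, "Ten")

  # empty table -> empty result
  expect_equal(nrow(assess_distributions(tiny_table()[0, ], "genus")), 0)

  # zero-spread family propagates a zero ratio
  tab21 <- tibble::tibble(
    accession = sprintf("NC_%06d", 1:21), organism = "Flatus sp",
    taxid = NA_integer_, length_bp = 150000L,
    published = as.Date("2020-01-01"), source_db = "refseq",
    genus = "Flatus", family = "Flataceae", clade = NA_character_
  )
  d <- assess_distributions(tab21, "family")
  expect_equal(d$ratio_pct, 0)
  expect_equal(d$n, 21)

  expect_error(assess_distributions(tiny_table(), "order"),
               class = "lenqc_domain_error")
})

test_that("distributions are sorted by descending ratio, ties by name", {
  fx <- generate_fixture(list(
    genus_spec("Widest", "F1", n = 12, center = 150000,
               regime = "wide_parasite"),
    genus_spec("Anarrow", "F1", n = 12, center = 150000, spread_sd = 0),
    genus_spec("Bnarrow", "F2", clade = "rosids", n = 12,
               center = 150000, spread_sd = 0)
  ), seed = 2)
  d <- assess_distributions(fx$table, "genus")
  expect_equal(d$taxon, c("Widest", "Anarrow", "Bnarrow"))
  expect_equal(d$ratio_pct[2:3], c(0, 0))
})

test_that("shuffling table rows changes no distribution statistic", {
  fx <- generate_fixture(default_fixture_specs(), seed = 11)
  d1 <- assess_distributions(fx$table, "genus")
  shuffled <- fx$table[withr::with_seed(1, sample(nrow(fx$table))), ]
  d2 <- assess_distributions(shuffled, "genus")
  num_cols <- c("n", "median", "q1", "q3", "iqr", "lower_fence",
                "upper_fence", "ratio_pct")
  expect_equal(d1[num_cols], d2[num_cols])
  expect_equal(d1$taxon, d2$taxon)
})
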