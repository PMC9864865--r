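test_that("the generator is deterministic and respects its spec", {
  spec <- genus_spec("Solo", "Soloceae", n = 30, center = 155000,
                     spread_sd = 200, injected_outliers = 20000)
  fx1 <- generate_fixture(spec, seed = 1)
  expect_equal(nrow(fx1$table), 30)
  expect_length(fx1$truth$outlier_accessions, 1)
  expect_true(fx1$truth$outlier_accessions %in% fx1$table$accession)

  # identical call, identical seed -> byte-identical serialization
  fx2 <- generate_fixture(spec, seed = 1)
  d <- withr::local_tempdir()
  write_fixture(fx1, file.path(d, "a"))
  write_fixture(fx2, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a", "refseq.tsv")),
                   readLines(file.path(d, "b", "refseq.tsv")))
  expect_identical(readLines(file.path(d, "a", "taxonomy.tsv")),
                   readLines(file.path(d, "b", "taxonomy.tsv")))

  # a different seed gives different lengths
  fx3 <- generate_fixture(spec, seed = 2)
  expect_false(identical(fx1$table$length_bp, fx3$table$length_bp))

  expect_error(generate_fixture(spec), class = "lenqc_domain_error")
})

test_that("generated tables validate and carry a consistent taxonomy", {
  fx <- generate_fixture(default_fixture_specs(), seed = 6)
  expect_silent(validate_taxonomy(fx$taxonomy))
  # lineage columns in the table agree with resolution from the taxonomy
  for (i in c(1, 50, 100)) {
    lin <- resolve_lineage(fx$table$taxid[i], fx$taxonomy)
    expect_equal(lin$genus, fx$table$genus[i])
    expect_equal(lin$family, fx$table$family[i])
    expect_equal(lin$clade, fx$table$clade[i])
  }
  expect_true(all(fx$table$length_bp >= 10000))
})

test_that("wide_parasite genera exceed the 1% ratio in nearly all seeds", {
  hits <- 0
  for (s in 1:100) {
    fx <- generate_fixture(genus_spec("Paras", "Paraceae", n = 20,
                                      center = 120000,
                                      regime = "wide_parasite"),
                           seed = s)
    r <- compute_boxplot_stats(fx$table$length_bp)$ratio_pct
    if (r > 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("ir_loss_shift produces a bimodal, downward-shifted subset", {
  fx <- generate_fixture(genus_spec("Irless", "Iraceae", n = 40,
                                    center = 155000,
                                    regime = "ir_loss_shift"),
                         seed = 3)
  low <- fx$table$length_bp < 145000
  expect_gt(sum(low), 0)
  expect_lt(sum(low), 40)
  expect_equal(median(fx$table$length_bp[low]) + 25000,
               median(fx$table$length_bp[!low]), tolerance = 0.01)
})

test_that("the GenBank mirror duplicates every record and corrects outliers", {
  spec <- genus_spec("Solo", "Soloceae", n = 30, center = 155000,
                     spread_sd = 200, injected_outliers = 20000)
  fx <- generate_fixture(spec, seed = 1)

  m1 <- generate_genbank_mirror(fx$table, fx$truth, seed = 2,
                                correction_prob = 1)
  expect_equal(nrow(m1$mirror), 31)  # 30 duplicates + 1 alternative
  expect_length(m1$truth$corrected_alternatives, 1)
  expect_equal(names(m1$truth$corrected_alternatives),
               fx$truth$outlier_accessions)

  m0 <- generate_genbank_mirror(fx$table, fx$truth, seed = 2,
                                correction_prob = 0)
  expect_equal(nrow(m0$mirror), 30)
  expect_length(m0$truth$corrected_alternatives, 0)

  # duplicates preserve organism and length under a distinct accession
  dup <- m0$mirror
  expect_equal(dup$length_bp, fx$table$length_bp)
  expect_equal(dup$organism, fx$table$organism)
  expect_false(any(dup$accession %in% fx$table$accession))
  expect_true(all(dup$source_db == "genbank"))
})

test_that("corrected alternatives are strictly closer than the outlier", {
  spec <- genus_spec("Solo", "Soloceae", n = 30, center = 155000,
                     spread_sd = 200, injected_outliers = 20000)
  for (s in 1:100) {
    fx <- generate_fixture(spec, seed = s)
    m <- generate_genbank_mirror(fx$table, fx$truth, seed = s + 1,
                                 correction_prob = 1)
    out_acc <- fx$truth$outlier_accessions
    alt_acc <- m$truth$corrected_alternatives[[out_acc]]
    med <- median(fx$table$length_bp)
    ref_len <- fx$table$length_bp[fx$table$accession == out_acc]
    alt_len <- m$mirror$length_bp[m$mirror$accession == alt_acc]
    expect_true(is_alternative_closer(med, ref_len, alt_len))
  }
})

test_that("the pipeline recovers injected outliers on clean fixtures", {
  # offsets of 50 sd in genera of n >= 20: sensitivity 1 over 50 seeds
  spec <- list(
    genus_spec("Hitme", "Hitaceae", n = 25, center = 150000,
               spread_sd = 150, injected_outliers = c(7500, -7500)),
    genus_spec("Clean", "Hitaceae", n = 20, center = 153000)
  )
  found <- 0
  truth_n <- 0
  for (s in 1:50) {
    fx <- generate_fixture(spec, seed = s)
    d <- assess_distributions(fx$table, "genus")
    out <- detect_outliers(d, fx$table)
    truth_n <- truth_n + length(fx$truth$outlier_accessions)
    found <- found + sum(fx$truth$outlier_accessions %in% out$accession)
  }
  expect_equal(found, truth_n)  # sensitivity 1.0
})
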