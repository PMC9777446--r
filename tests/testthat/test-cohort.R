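test_that("cohort frequencies reproduce the reporting convention", {
  expect_equal(mov_frequency(126, 6422), 1.962)
  expect_equal(mov_frequency(98, 6422), 1.526)
  expect_equal(mov_frequency(31, 6422), 0.483)
  expect_equal(mov_frequency(13, 6422), 0.202)
  expect_equal(mov_frequency(1, 3, digits = NA), 100 / 3)
  expect_error(mov_frequency(1, 0), ">= 1")
})

test_that("identical recurrent calls collapse to one MOV with the right frequency", {
  calls <- make_calls(sprintf("S%03d", 1:126), "chr6",
                      rep(168340000, 126), rep(168580000, 126), "gain")
  movs <- cluster_movs(calls, cohort_size = 6422)
  expect_equal(nrow(movs), 1)
  expect_true(movs$is_mov)
  expect_equal(movs$n_occurrences, 126)
  expect_equal(round(movs$frequency_pct, 3), 1.962)
  expect_equal(movs$start_bp, 168340000)
})

test_that("a single un-replicated call is a cluster but not a MOV", {
  movs <- cluster_movs(make_calls("S1", "chr1", 1e6, 1.4e6, "loss"), 100)
  expect_equal(nrow(movs), 1)
  expect_false(movs$is_mov)
})

test_that("reciprocal-overlap linking honours the threshold", {
  # 60% reciprocal overlap: separate at 0.75, merged at 0.5
  calls <- make_calls(c("S1", "S2"), "chr2", c(0, 400000),
                      c(1000000, 1400000), "gain")
  expect_equal(nrow(cluster_movs(calls, 100, 0.75)), 2)
  expect_equal(nrow(cluster_movs(calls, 100, 0.5)), 1)
  # gains and losses never merge
  mixed <- make_calls(c("S1", "S2"), "chr2", c(0, 0), c(1e6, 1e6),
                      c("gain", "loss"))
  expect_equal(nrow(cluster_movs(mixed, 100)), 2)
})

test_that("clustering is order-invariant and conserves occurrences", {
  set.seed(71)
  base <- make_calls(sprintf("S%02d", 1:12), "chr3",
                     rep(c(2e6, 2.02e6, 7e6), 4),
                     rep(c(2.4e6, 2.42e6, 7.3e6), 4), "gain")
  m1 <- cluster_movs(base, 50)
  for (i in 1:5) {
    perm <- base[sample(nrow(base)), ]
    m2 <- cluster_movs(perm, 50)
    expect_equal(m1, m2)
  }
  expect_equal(sum(m1$n_occurrences), nrow(base))
})

test_that("the representative interval is the modal one, ties leftmost-shortest", {
  calls <- make_calls(c("S1", "S2", "S3"), "chr1",
                      c(1000000, 1000000, 980000),
                      c(1400000, 1400000, 1380000), "loss")
  movs <- cluster_movs(calls, 10)
  expect_equal(movs$start_bp, 1000000)  # modal interval (2 of 3)
  expect_equal(movs$end_bp, 1400000)
})

test_that("chi-squared matches the hand-built contingency-table oracle", {
  res <- compare_to_db(126, 6422, 1.4, 7624, label = "dup 6q27")
  db_n <- round(0.014 * 7624)
  expect_equal(res$chi2_stat, chi2_oracle(126, 6422, db_n, 7624),
               tolerance = 1e-10)
  expect_equal(res$db_n, db_n)
  # identical frequencies on both sides: statistic 0, p 1
  null_res <- compare_to_db(10, 1000, 1, 2000)
  expect_equal(null_res$chi2_stat, 0, tolerance = 1e-12)
  expect_equal(null_res$p_value, 1, tolerance = 1e-12)
  # degenerate table flagged
  expect_warning(deg <- compare_to_db(0, 100, 0, 200), "undefined")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
})

test_that("the 15q13.3 duplication excess over gnomAD is significant", {
  res <- compare_to_db(42, 6422, 0.23, 7624, label = "dup 15q13.3")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$cohort_freq_pct, 0.654, tolerance = 0.001)
})

test_that("variants-per-Mb densities and p-values reproduce the printed table", {
  tab <- load_report_fixture("density")
  res <- chromosome_density(stats::setNames(tab$n_variants, tab$chrom),
                            stats::setNames(tab$effective_length_bp,
                                            tab$chrom))
  expect_equal(res$per_mb, tab$per_mb, tolerance = 1e-8)
  expect_equal(res$p_value, tab$p_value, tolerance = 1e-6)
  expect_equal(res$chrom[res$significant], "19")
  # chrX extreme in the high tail is not flagged one-sided, but is two-sided
  res2 <- chromosome_density(stats::setNames(tab$n_variants, tab$chrom),
                             stats::setNames(tab$effective_length_bp,
                                             tab$chrom),
                             two_sided = TRUE)
  expect_true(res2$significant[res2$chrom == "X"])
})

test_that("density closed form and degenerate branch", {
  counts <- c(A = 1, B = 1, C = 4)
  lens <- c(A = 1e6, B = 1e6, C = 1e6)
  res <- chromosome_density(counts, lens)
  expect_equal(res$per_mb, c(1, 1, 4))
  expect_equal(res$p_value[3], stats::pnorm(2 / sqrt(3)))
  expect_equal(res$p_value[1], stats::pnorm(-1 / sqrt(3)))
  expect_warning(deg <- chromosome_density(c(A = 2, B = 2, C = 2), lens),
                 "identical")
  expect_equal(deg$p_value, rep(0.5, 3))
  expect_false(any(deg$significant))
  expect_error(chromosome_density(c(A = 1, B = 2), lens[1:2]), "at least 3")
  expect_error(chromosome_density(counts, c(A = 1e6, B = 0, C = 1e6)),
               "positive")
})

test_that("cohort summary counts distinct variants and MOVs", {
  calls <- rbind(make_calls(c("S1", "S2", "S3"), "chr1",
                            rep(2e6, 3), rep(2.4e6, 3), "gain"),
                 make_calls("S4", "chr2", 5e6, 5.5e6, "loss"))
  movs <- cluster_movs(calls, 50)
  s <- summarize_cohort(movs, calls)
  expect_equal(s$n_distinct, 2)
  expect_equal(s$n_mov, 1)
  expect_equal(s$n_gain, 1)
  expect_equal(s$n_loss, 1)
  expect_equal(s$mov_table$n, 3)
  expect_equal(s$mov_table$size_kb, 400)
  # empty input
  s0 <- summarize_cohort(cluster_movs(NULL, 10), NULL)
  expect_equal(s0$n_distinct, 0)
  expect_equal(nrow(s0$mov_table), 0)
})
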