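test_that("genotype tabulation reproduces count-derived percentages exactly", {
  # biallelic-target cohort: 321 blastomeres
  counts <- c("homo-Indel" = 121, "homo-Del" = 8, "homo-HDR" = 6,
              "homo-WT" = 26, "WT/Indel" = 28, "Indel/Indel" = 87,
              "Del/Indel" = 31, "Del/Del" = 1, "Del/HDR" = 1, "WT/HDR" = 12)
  tab <- counts_table(counts, "blastomeres")
  expect_equal(attr(tab, "total"), 321L)
  expect_equal(tab$pct[tab$label == "Indel/Indel"], 100 * 87 / 321)
  expect_equal(round(tab$pct[tab$label == "Indel/Indel"], 1), 27.1)
  expect_equal(round(tab$pct[tab$label == "homo-Indel"], 1), 37.7)
  expect_equal(sum(tab$n), 321L)
  # percentages always re-derive from their counts
  expect_equal(tab$pct, 100 * tab$n / attr(tab, "total"))
  expect_error(tabulate_genotype_frequencies(tibble::tibble(label = character())),
               "empty", class = "blastocall_data_error")
  single <- tabulate_genotype_frequencies(tibble::tibble(label = "homo-WT"))
  expect_equal(single$pct, 100)
})

test_that("homozygosity fractions reproduce the published worked examples", {
  tab_mybpc3 <- counts_table(c("homo-Indel" = 121, "homo-Del" = 8,
                               "homo-HDR" = 6, "homo-WT" = 26,
                               "WT/Indel" = 28, "Indel/Indel" = 87,
                               "Del/Indel" = 31, "Del/Del" = 1,
                               "Del/HDR" = 1, "WT/HDR" = 12))
  expect_equal(round(100 * homozygosity_fraction(tab_mybpc3), 1), 50.2)
  tab_ldlrap1 <- counts_table(c("homo-WT" = 43, "homo-Mut" = 14,
                                "homo-Indel" = 2, "WT/Mut" = 69,
                                "WT/Indel" = 11, "Mut/Indel" = 5,
                                "Indel/Indel" = 5))
  expect_equal(attr(tab_ldlrap1, "total"), 149L)
  expect_equal(round(100 * homozygosity_fraction(tab_ldlrap1), 1), 39.6)
  expect_equal(homozygosity_fraction(counts_table(c("WT/Indel" = 9))), 0)
})

test_that("one-tailed Fisher equals exhaustive enumeration on small tables", {
  expect_equal(as.numeric(fisher_exact_one_tailed(
    matrix(c(2, 0, 0, 2), 2, byrow = TRUE))), 1 / 6)
  # sweep a lattice of tables and compare three routes
  set.seed(7)
  for (rep in 1:200) {
    tot <- sample(2:24, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- tot - cuts[3]
    p <- as.numeric(fisher_exact_one_tailed(
      matrix(c(a, b, c, d), 2, byrow = TRUE)))
    p_oracle <- fisher_enum_oracle(a, b, c, d)
    expect_equal(p, p_oracle, tolerance = 1e-12)
    if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
      p_ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                  alternative = "greater")$p.value
      expect_equal(p, p_ref, tolerance = 1e-9)
    }
  }
})

test_that("degenerate margins give p = 1 with a flag", {
  p <- fisher_exact_one_tailed(matrix(c(0, 5, 0, 7), 2, byrow = TRUE))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_error(fisher_exact_one_tailed(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative", class = "blastocall_data_error")
})

test_that("LOH comparisons reproduce the blastomere-vs-ESC rates", {
  blast <- counts_table(c("homo-Indel" = 121, "WT/Indel" = 200),
                        "blastomeres")
  esc <- counts_table(c("homo-Indel" = 2, "WT/Indel" = 12), "esc_lines")
  cmp <- compare_loh_rates(blast, esc, loh_labels = "homo-Indel")
  expect_equal(round(100 * cmp$rate_a, 1), 37.7)
  expect_equal(round(100 * cmp$rate_b, 1), 14.3)
  expect_equal(cmp$p_value,
               stats::fisher.test(matrix(c(121, 200, 2, 12), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  td <- tidy(cmp)
  expect_equal(td$rate, c(cmp$rate_a, cmp$rate_b))
  gl <- glance(cmp)
  expect_equal(gl$p_value, cmp$p_value)
  # identical cohorts show no enrichment
  same <- compare_loh_rates(blast, blast, loh_labels = "homo-Indel")
  expect_gte(same$p_value, 0.5)
})

test_that("equal-rate simulated cohorts keep type-I error at the nominal level", {
  set.seed(17)
  alpha <- 0.05
  n_rep <- 400
  rejections <- 0
  for (i in seq_len(n_rep)) {
    a <- stats::rbinom(1, 60, 0.3)
    b <- stats::rbinom(1, 60, 0.3)
    p <- fisher_exact_one_tailed(matrix(c(a, 60 - a, b, 60 - b), 2,
                                        byrow = TRUE))
    if (as.numeric(p) < alpha) rejections <- rejections + 1
  }
  # exact test is conservative: empirical size should not exceed alpha
  # (binomial slack for 400 replicates)
  expect_lte(rejections / n_rep, alpha + 2 * sqrt(alpha * (1 - alpha) / n_rep))
})

test_that("reports are deterministic, complete and verifiable", {
  cells <- tibble::tibble(label = c("homo-Indel", "WT/Indel", "homo-Indel"))
  tab <- tabulate_genotype_frequencies(cells, "demo")
  est <- sample_ado_rate(call_genotypes(depth_rows(c(G = 40))), "L1")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- render_report(list(genotypes = tidy(tab), ado = tidy(est)),
                      d1, seed = 5)
  m2 <- render_report(list(genotypes = tidy(tab), ado = tidy(est)),
                      d2, seed = 5)
  expect_identical(m1$checksums, m2$checksums)
  expect_true(verify_manifest(d1))
  # report totals equal input counts
  written <- readr::read_tsv(file.path(d1, "genotypes.tsv"),
                             show_col_types = FALSE)
  expect_equal(sum(written$n), nrow(cells))
  # tampering fails the manifest check
  writeLines("tampered", file.path(d1, "genotypes.tsv"))
  expect_error(verify_manifest(d1), "mismatch",
               class = "blastocall_data_error")
  expect_error(render_report(list(), d2), "named",
               class = "blastocall_data_error")
  expect_error(render_report(list(x = tibble::tibble()), d2), "empty",
               class = "blastocall_data_error")
})
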