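test_that("allele keys parse into the taxonomy with signed sizes", {
  p <- parse_allele_key(c("WT", "Mut", "HDR", "indel-2.3", "indel+5.ACGTA",
                          "del-824.0"))
  expect_equal(p$category, c("WT", "Mut", "HDR", "Indel", "Indel",
                             "LargeDel"))
  expect_equal(p$size_bp, c(0L, 0L, 0L, -2L, 5L, -824L))
  expect_error(parse_allele_key("del-50.0"), "100",
               class = "blastocall_data_error")
  expect_error(parse_allele_key("mystery"), "unrecognised",
               class = "blastocall_data_error")
})

test_that("sequence classification recovers the category of every allele type", {
  cfg <- sim_config(seed = 61, n_markers = 4)
  hp <- simulate_trio_haplotypes(cfg, 4)
  cases <- list(
    list(key = "WT", category = "WT", size = 0L),
    list(key = "Mut", category = "Mut", size = 0L),
    list(key = "HDR", category = "HDR", size = 0L),
    list(key = "indel-2.0", category = "Indel", size = -2L),
    list(key = "indel+3.TAG", category = "Indel", size = 3L),
    list(key = "indel-99.5", category = "Indel", size = -99L),
    list(key = "del-1873.2", category = "LargeDel", size = -1873L),
    list(key = "del-100.0", category = "LargeDel", size = -100L)
  )
  for (cs in cases) {
    m <- materialize_allele(cs$key, hp)
    r <- classify_on_target_allele(m$allele_seq, m$reference_context,
                                   m$markers, m$mut_def)
    expect_equal(r$category, cs$category, info = cs$key)
    expect_equal(r$size_bp, cs$size, info = cs$key)
  }
})

test_that("markers plus a large deletion is a conflict; partial markers an audit flag", {
  cfg <- sim_config(seed = 62)
  hp <- simulate_trio_haplotypes(cfg, 4)
  m <- materialize_allele("HDR", hp)
  # graft a 150 bp deletion onto the all-markers allele
  alt <- strsplit(m$allele_seq, "")[[1]]
  alt <- paste(alt[-(1000:1149)], collapse = "")
  expect_error(
    classify_on_target_allele(alt, m$reference_context, m$markers, m$mut_def),
    "conflict", class = "blastocall_classification_error")
  # only some markers present, no other change
  partial <- strsplit(m$reference_context, "")[[1]]
  partial[m$markers$pos[1]] <- m$markers$marker_base[1]
  r <- classify_on_target_allele(paste(partial, collapse = ""),
                                 m$reference_context, m$markers, m$mut_def)
  expect_true(is.na(r$category))
  expect_true(r$partial_hdr)
})

test_that("cell labels are canonical and homo labels set the LOH flag", {
  expect_equal(label_cell_genotype(c("WT", "indel-2.0"))$label, "WT/Indel")
  expect_equal(label_cell_genotype(c("indel+1.A", "del-824.0"))$label,
               "Del/Indel")
  expect_equal(label_cell_genotype(c("HDR", "del-824.0"))$label, "Del/HDR")
  expect_equal(label_cell_genotype(c("Mut", "indel-4.1"))$label, "Mut/Indel")
  expect_equal(label_cell_genotype(c("indel-1.0", "indel-2.0"))$label,
               "Indel/Indel")
  lab <- label_cell_genotype("indel-1.0")
  expect_equal(lab$label, "homo-Indel")
  expect_true(lab$loh_flag)
  expect_false(label_cell_genotype(c("WT", "HDR"))$loh_flag)
  expect_error(label_cell_genotype(character()), "no-call",
               class = "blastocall_data_error")
  expect_error(label_cell_genotype(c("WT", "Mut", "HDR")), "multi-allelic",
               class = "blastocall_data_error")
  # every produced label belongs to the closed set
  keys <- c("WT", "Mut", "HDR", "indel-2.0", "del-824.0")
  for (i in seq_along(keys)) for (j in seq_len(i)) {
    lab <- label_cell_genotype(unique(c(keys[i], keys[j])))$label
    expect_true(lab %in% genotype_label_set(), info = lab)
  }
})

test_that("embryo mosaicism is the complement of a single shared label", {
  cells <- tibble::tibble(
    embryo_id = c(rep("E1", 4), rep("E2", 3)),
    cell_id = paste0("c", 1:7),
    label = c(rep("homo-Indel", 4), "WT/Indel", "homo-Indel", "homo-Indel"))
  res <- classify_embryo_mosaicism(cells)
  expect_equal(res$classification, c("uniform", "mosaic"))
  expect_equal(res$n_distinct, c(1L, 2L))
  # stricter reading: >= 3 distinct genotypes
  res3 <- classify_embryo_mosaicism(cells, min_distinct = 3)
  expect_equal(res3$classification, c("uniform", "uniform"))
  expect_error(classify_embryo_mosaicism(cells[0, ]), "empty",
               class = "blastocall_data_error")
})

test_that("with zygotic repair the classified cohort is 100% uniform", {
  cfg <- sim_config(n_embryos = 12, p_zygote_edit = 1, n_panel_loci = 0,
                    seed = 63)
  hp <- simulate_trio_haplotypes(cfg, 4)
  truth <- simulate_embryo_cohort(cfg, hp)
  labels <- truth_cell_labels(truth)
  res <- classify_embryo_mosaicism(labels)
  expect_true(all(res$classification == "uniform"))
})

test_that("round trip: artifact-free calls reproduce truth labels; dropout only creates homo labels", {
  cfg <- sim_config(n_embryos = 10, q_copy_fail = 0, f_locus_fail = 0,
                    n_panel_loci = 0, seed = 64)
  hp <- simulate_trio_haplotypes(cfg, 4)
  truth <- simulate_embryo_cohort(cfg, hp)
  ev <- simulate_wga_evidence(truth, hp, cfg)
  calls <- call_genotypes(ev) |> dplyr::filter(locus_id == "target")
  observed <- classify_cells(calls)
  expected <- truth_cell_labels(truth)
  m <- dplyr::inner_join(observed, expected, by = "cell_id",
                         suffix = c("_obs", "_true"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$label_obs, m$label_true)

  # with dropout, any discrepancy is a true heterozygote shown as homo-*
  cfg2 <- sim_config(n_embryos = 40, q_copy_fail = 0.3, f_locus_fail = 0,
                     n_panel_loci = 0, seed = 65)
  truth2 <- simulate_embryo_cohort(cfg2, hp)
  ev2 <- simulate_wga_evidence(truth2, hp, cfg2)
  calls2 <- call_genotypes(ev2) |> dplyr::filter(locus_id == "target")
  observed2 <- classify_cells(calls2) |> dplyr::filter(!is.na(label))
  m2 <- dplyr::inner_join(observed2, truth_cell_labels(truth2),
                          by = "cell_id", suffix = c("_obs", "_true"))
  mismatch <- m2[m2$label_obs != m2$label_true, ]
  expect_gt(nrow(mismatch), 0)
  expect_true(all(startsWith(mismatch$label_obs, "homo-")))
  expect_true(all(!startsWith(mismatch$label_true, "homo-")))
})
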