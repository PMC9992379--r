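test_that("informativeness follows the parental-genotype definition", {
  expect_equal(classify_informativeness("A/A", "G/G"), "informative")
  expect_equal(classify_informativeness("A/G", "G/G"), "semi_informative")
  expect_equal(classify_informativeness("A/A", "A/G"), "semi_informative")
  expect_equal(classify_informativeness("A/G", "A/G"), "semi_informative")
  expect_equal(classify_informativeness("A/A", "A/A"), "uninformative")
  expect_equal(classify_informativeness(NA_character_, "A/A"),
               "undetermined")
  expect_equal(classify_informativeness(c("A/A", "A/G"), c("G/G", "G/G")),
               c("informative", "semi_informative"))
})

# hand-built per-cell calls: offsets with statuses (target at 0)
mk_calls <- function(offsets, statuses, alleles = NULL) {
  if (is.null(alleles)) alleles <- rep(NA_character_, length(offsets))
  tibble::tibble(offset_bp = offsets, status = statuses, allele = alleles)
}

test_that("the LOH segment is the maximal homozygous run containing the target", {
  cc <- mk_calls(c(-3324, -2623, -2551, 0, 2963, 8000),
                 c("heterozygous", "homozygous", "homozygous", "homozygous",
                   "homozygous", "heterozygous"))
  seg <- detect_loh_segment(cc)
  expect_equal(seg$seg_left, -2623)
  expect_equal(seg$seg_right, 2963)
  expect_equal(seg$left_het, -3324)
  expect_equal(seg$right_het, 8000)

  # heterozygous target: no segment
  cc2 <- mk_calls(c(-100, 0, 100),
                  c("homozygous", "heterozygous", "homozygous"))
  expect_null(detect_loh_segment(cc2))

  # all flanks heterozygous: target-only segment
  cc3 <- mk_calls(c(-100, 0, 100),
                  c("heterozygous", "homozygous", "heterozygous"))
  seg3 <- detect_loh_segment(cc3)
  expect_equal(c(seg3$seg_left, seg3$seg_right), c(0, 0))

  # every flank unamplified: target alone, low confidence
  cc4 <- mk_calls(c(-100, 0, 100),
                  c("not_amplified", "homozygous", "not_amplified"))
  seg4 <- detect_loh_segment(cc4)
  expect_true(seg4$low_confidence)
  expect_equal(seg4$n_skipped, 2L)
})

test_that("unamplified variants are transparent unless strict mode breaks the run", {
  cc <- mk_calls(c(-200, -100, 0, 100, 200),
                 c("homozygous", "not_amplified", "homozygous",
                   "not_amplified", "homozygous"))
  seg <- detect_loh_segment(cc)
  expect_equal(c(seg$seg_left, seg$seg_right), c(-200, 200))
  expect_equal(seg$n_skipped, 2L)
  seg_strict <- detect_loh_segment(cc, strict = TRUE)
  expect_equal(c(seg_strict$seg_left, seg_strict$seg_right), c(0, 0))
})

test_that("template parent comes from converted variants, with conflicts flagged", {
  variants <- tibble::tibble(
    locus_id = c("v1", "v2", "v3"),
    offset_bp = c(-2000, -1000, 1000),
    maternal_gt = c("A/A", "C/T", "G/G"),
    paternal_gt = c("G/G", "T/T", "T/T"),
    informativeness = classify_informativeness(
      c("A/A", "C/T", "G/G"), c("G/G", "T/T", "T/T"))
  )
  seg <- list(seg_left = -2000, seg_right = 1000,
              left_het = NA, right_het = NA)
  # all informative/determined sites show the maternal allele
  cc <- mk_calls(c(-2000, -1000, 0, 1000),
                 rep("homozygous", 4), c("A", "C", "x", "G"))
  par <- infer_template_parent(seg, cc, variants)
  expect_equal(par$template_parent, "maternal")
  expect_false(par$conflict)
  expect_equal(par$n_converted, 3L)         # v2: C absent from father
  expect_equal(par$n_converted_informative, 2L)
  expect_equal(par$converted_offsets, c(-2000, -1000, 1000))

  # semi-informative homozygosity compatible with both parents: ambiguous
  cc_amb <- mk_calls(c(-1000, 0), c("homozygous", "homozygous"), c("T", "x"))
  par_amb <- infer_template_parent(
    list(seg_left = -1000, seg_right = 0, left_het = NA, right_het = NA),
    cc_amb, variants)
  expect_equal(par_amb$template_parent, "undetermined")
  expect_equal(par_amb$n_ambiguous, 1L)

  # conflicting informative votes
  cc_conf <- mk_calls(c(-2000, 0, 1000), rep("homozygous", 3),
                      c("A", "x", "T"))
  par_conf <- infer_template_parent(seg, cc_conf, variants)
  expect_equal(par_conf$template_parent, "undetermined")
  expect_true(par_conf$conflict)
})

test_that("tract bounds reproduce the printed-offset worked example", {
  variants <- tibble::tibble(offset_bp = c(-3324, -2623, 2963, 8000, 16185))
  seg <- list(seg_left = -2623, seg_right = 2963,
              left_het = -3324, right_het = 8000)
  b <- tract_length_bounds(seg, variants, converted_offsets = c(-2623, 2963))
  expect_equal(b[["min_tract_bp"]], 2963 - (-2623) + 1)  # 5587
  expect_equal(b[["min_tract_bp"]], 5587)
  expect_equal(b[["max_tract_bp"]], 8000 - (-3324) - 1)  # 11323
  expect_equal(b[["max_tract_bp"]], 11323)

  # target-only segment: min = 1
  seg0 <- list(seg_left = 0, seg_right = 0, left_het = -3324,
               right_het = 2963)
  b0 <- tract_length_bounds(seg0, variants)
  expect_equal(b0[["min_tract_bp"]], 1)
  expect_equal(b0[["max_tract_bp"]], 2963 - (-3324) - 1)

  # no heterozygous flank: fall back to the panel edge
  seg_edge <- list(seg_left = -2623, seg_right = 2963,
                   left_het = NA, right_het = NA)
  b_edge <- tract_length_bounds(seg_edge, variants,
                                converted_offsets = c(-2623, 2963))
  expect_equal(b_edge[["max_tract_bp"]], (16185 + 1) - (-3324 - 1) - 1)
})

test_that("adding an informative variant inside the segment never widens the bounds", {
  variants <- tibble::tibble(offset_bp = c(-3000, -1500, 1500, 3000))
  seg <- list(seg_left = -1500, seg_right = 1500,
              left_het = -3000, right_het = 3000)
  b1 <- tract_length_bounds(seg, variants, converted_offsets = c(-1500))
  b2 <- tract_length_bounds(seg, variants,
                            converted_offsets = c(-1500, 800))
  expect_gte(b2[["min_tract_bp"]], b1[["min_tract_bp"]])  # min can only tighten up
  expect_equal(b2[["max_tract_bp"]], b1[["max_tract_bp"]])
  expect_lte(b2[["min_tract_bp"]], b2[["max_tract_bp"]])
})

test_that("simulated conversions are bracketed and the template recovered", {
  cfg <- conversion_config(p_conv = 0.5, n_cells = 80, q = 0, seed = 81,
                           max_extent = 2600)
  # designed panel: informative variants at known offsets, tract extents
  # bounded inside the assayed flank span
  design <- flank_panel_design(cfg$seed)
  hp <- simulate_trio_haplotypes(cfg, 27, offsets = design$offsets,
                                 informativeness = design$informativeness)
  truth <- simulate_embryo_cohort(cfg, hp)
  ev <- simulate_wga_evidence(truth, hp, cfg)
  tracts <- infer_tracts(call_genotypes(ev), hp$variants)
  conv <- dplyr::filter(truth, !is.na(tract_parent))
  m <- dplyr::inner_join(conv, tracts, by = "cell_id")
  true_len <- m$tract_right - m$tract_left + 1
  expect_true(all(m$has_loh))
  expect_true(all(m$min_tract_bp <= true_len))
  expect_true(all(true_len <= m$max_tract_bp))
  has_inf <- purrr::map2_lgl(m$tract_left, m$tract_right, function(l, r)
    any(hp$variants$informativeness == "informative" &
          hp$variants$offset_bp >= l & hp$variants$offset_bp <= r))
  expect_true(all(m$template_parent[has_inf] == m$tract_parent[has_inf]))
  # assigned directions never contradict the truth in artifact-free data
  assigned <- m$template_parent %in% c("maternal", "paternal")
  expect_true(all(m$template_parent[assigned] == m$tract_parent[assigned]))
  # het-target cells yield no tract call
  nonconv <- dplyr::semi_join(tracts, dplyr::filter(truth, is.na(tract_parent)),
                              by = "cell_id")
  expect_true(all(!nonconv$has_loh |
                    nonconv$min_tract_bp <= nonconv$max_tract_bp))
})
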