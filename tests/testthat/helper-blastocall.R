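# shared fixture builders -- everything is generated in code

# unedited single cells on a heterozygous panel: the ADO measurement design
no_edit_config <- function(q, f = 0, n_cells = 1, n_loci = 1000, seed = 1) {
  sim_config(
    n_embryos = n_cells, cells_per_embryo = 1, p_zygote_edit = 0,
    p_intact = 1, p_indel = 0, p_large_del = 0, p_hdr = 0, p_conversion = 0,
    q_copy_fail = q, f_locus_fail = f, n_panel_loci = n_loci, seed = seed
  )
}

# conversion-vs-indel cohort with tract extents bounded inside the flank span
conversion_config <- function(p_conv, n_cells, q = 0, seed = 1,
                              max_extent = 6000) {
  sim_config(
    n_embryos = n_cells, cells_per_embryo = 1, p_zygote_edit = 1,
    p_intact = 0, p_indel = 1 - p_conv, p_large_del = 0, p_hdr = 0,
    p_conversion = p_conv,
    tract_length_dist = function(n) pmin(stats::rexp(n, 1 / 2000), max_extent),
    q_copy_fail = q, f_locus_fail = 0, n_panel_loci = 0, seed = seed
  )
}

# evidence rows for one sample/locus from a named depth vector
depth_rows <- function(depths, sample_id = "s1", locus_id = "L1") {
  tibble::tibble(
    sample_id = sample_id, locus_id = locus_id,
    chrom = "chr1", pos = 100L,
    allele = names(depths), depth = as.integer(depths)
  )
}

# category table directly from label counts (printed-table input path)
counts_table <- function(counts, cohort_id = "cohort") {
  tabulate_genotype_frequencies(
    tibble::tibble(label = rep(names(counts), counts)),
    cohort_id = cohort_id
  )
}

# exhaustive-enumeration Fisher oracle using plain factorials
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(xs, function(x) {
    (factorial(r1) / (factorial(x) * factorial(r1 - x))) *
      (factorial(r2) / (factorial(c1 - x) * factorial(r2 - c1 + x))) /
      (factorial(n) / (factorial(c1) * factorial(n - c1)))
  }, numeric(1))
  sum(prob[xs >= a])
}
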