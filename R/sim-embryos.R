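## Allele keys --------------------------------------------------------------
##
## Resolved on-target alleles are carried through the pipeline as compact
## canonical strings ("sequence keys"):
##   "WT"                intact wild-type allele
##   "Mut"               intact pathogenic point-mutant allele
##   "HDR"               allele carrying all ssODN marker substitutions
##   "indel<+/-size>.<tag>"  NHEJ indel; tag = deletion start shift or the
##                           inserted bases, so independent events of equal
##                           net size remain distinct alleles
##   "del-<size>.<shift>"    large deletion (>= 100 bp)
## Gene conversion copies the template allele's key verbatim, which is what
## makes converted cells genuinely homozygous downstream.

new_indel_key <- function(size) {
  vapply(size, function(s) {
    if (s < 0) sprintf("indel%+d.%d", s, sample(-10:10, 1L))
    else sprintf("indel%+d.%s", s,
                 paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
                       collapse = ""))
  }, character(1))
}

new_del_key <- function(size) {
  vapply(size, function(s) sprintf("del-%d.%d", s, sample(-10:10, 1L)),
         character(1))
}

#' Simulate a cohort of mosaic gene-edited embryos with ground truth
#'
#' Draws DSB repair outcomes per allele: with probability `p_zygote_edit`
#' both alleles resolve in the zygote and every sister blastomere inherits
#' the same genotype (uniform embryo); otherwise repair resolves
#' independently on each of two lineage branches at the 2-cell stage, the
#' minimal model producing mosaic 4-8 cell embryos. Each allele draws one
#' of `intact`, `indel`, `large_del`, `hdr`, `conversion`; a conversion
#' copies the homologous (template) allele's resolved state and renders a
#' tract of flanking variants homozygous. Tract extents left and right of
#' the cut site are drawn independently from `tract_length_dist`, so the
#' tract always covers offset 0 but is asymmetric in general.
#'
#' With `allele_specific = TRUE` only `"Mut"` alleles are cleavable; with
#' `p_paternal_mut` set, each embryo draws whether the sperm transmitted
#' the mutant allele (heterozygous donor).
#'
#' @param config A [sim_config()].
#' @param haplotypes A [simulate_trio_haplotypes()] result.
#' @return A `sim_truth` tibble, one row per cell: `embryo_id, cell_id,
#'   uniform, outcome_m, outcome_p` (drawn repair outcomes), `allele_m,
#'   allele_p` (resolved allele keys), `tract_parent, tract_left,
#'   tract_right` (NA when no conversion).
#' @examples
#' cfg <- sim_config(n_embryos = 3, seed = 2)
#' hp <- simulate_trio_haplotypes(cfg, n_flank_variants = 4)
#' simulate_embryo_cohort(cfg, hp)
#' @export
simulate_embryo_cohort <- function(config, haplotypes) {
  validate_sim_config(config)
  stopifnot(inherits(haplotypes, "parental_haplotypes"))
  set.seed(config$seed + 1L)

  out_levels <- c("intact", "indel", "large_del", "hdr", "conversion")
  out_probs <- c(config$p_intact, config$p_indel, config$p_large_del,
                 config$p_hdr, config$p_conversion)

  draw_outcome <- function(state) {
    if (config$allele_specific && state == "WT") return("intact")
    sample(out_levels, 1L, prob = out_probs)
  }

  resolve_plain <- function(outcome, state) {
    switch(outcome,
      intact = state,
      indel = new_indel_key(config$indel_size_dist(1L)),
      large_del = new_del_key(config$del_size_dist(1L)),
      hdr = "HDR",
      conversion = NA_character_  # resolved against the template below
    )
  }

  # resolve one repair-outcome pair; draw order: maternal outcome, paternal
  # outcome, allele realisations, then tract extents
  draw_pair <- function(mat_state, pat_state) {
    om <- draw_outcome(mat_state)
    op <- draw_outcome(pat_state)
    template <- NA_character_
    if (om == "conversion" && op == "conversion") {
      # interhomolog copy of an allele that itself resolved without repair:
      # one (random) allele acts as the intact template
      template <- sample(c("maternal", "paternal"), 1L)
    } else if (om == "conversion") {
      template <- "paternal"
    } else if (op == "conversion") {
      template <- "maternal"
    }
    am <- if (om == "conversion") NA_character_ else resolve_plain(om, mat_state)
    ap <- if (op == "conversion") NA_character_ else resolve_plain(op, pat_state)
    if (!is.na(template)) {
      if (template == "maternal") {
        if (is.na(am)) am <- mat_state        # both-conversion: template intact
        ap <- am
      } else {
        if (is.na(ap)) ap <- pat_state
        am <- ap
      }
      ext_l <- config$tract_length_dist(1L)
      ext_r <- config$tract_length_dist(1L)
      list(allele_m = am, allele_p = ap, outcome_m = om, outcome_p = op,
           tract_parent = template,
           tract_left = -as.numeric(ceiling(ext_l)),
           tract_right = as.numeric(ceiling(ext_r)))
    } else {
      list(allele_m = am, allele_p = ap, outcome_m = om, outcome_p = op,
           tract_parent = NA_character_,
           tract_left = NA_real_, tract_right = NA_real_)
    }
  }

  rows <- vector("list", config$n_embryos)
  for (e in seq_len(config$n_embryos)) {
    embryo_id <- sprintf("E%04d", e)
    pat_state <- haplotypes$target$paternal_state
    if (!is.na(config$p_paternal_mut))
      pat_state <- if (runif(1) < config$p_paternal_mut) "Mut" else "WT"
    mat_state <- haplotypes$target$maternal_state
    n_cells <- if (length(config$cells_per_embryo) == 1L)
      config$cells_per_embryo else sample(config$cells_per_embryo, 1L)
    uniform <- runif(1) < config$p_zygote_edit
    if (uniform) {
      pair <- draw_pair(mat_state, pat_state)
      pairs <- rep(list(pair), n_cells)
    } else {
      b1 <- draw_pair(mat_state, pat_state)
      b2 <- draw_pair(mat_state, pat_state)
      n1 <- if (n_cells > 1L) sample(seq_len(n_cells - 1L), 1L) else 1L
      pairs <- c(rep(list(b1), n1), rep(list(b2), n_cells - n1))
    }
    rows[[e]] <- tibble::tibble(
      embryo_id = embryo_id,
      cell_id = sprintf("%s_c%d", embryo_id, seq_len(n_cells)),
      uniform = uniform,
      outcome_m = vapply(pairs, `[[`, character(1), "outcome_m"),
      outcome_p = vapply(pairs, `[[`, character(1), "outcome_p"),
      allele_m = vapply(pairs, `[[`, character(1), "allele_m"),
      allele_p = vapply(pairs, `[[`, character(1), "allele_p"),
      tract_parent = vapply(pairs, `[[`, character(1), "tract_parent"),
      tract_left = vapply(pairs, `[[`, numeric(1), "tract_left"),
      tract_right = vapply(pairs, `[[`, numeric(1), "tract_right")
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sim_truth", class(out))
  out
}

#' True per-cell genotypes at flanking variants and the target
#'
#' Expands a simulated cohort into the long table of true allele copies per
#' cell and locus: the two target-site allele keys plus the maternal- and
#' paternal-transmitted base at every flanking variant, with gene-conversion
#' tracts applied (the converted allele carries the template parent's
#' transmitted base at every variant inside the tract).
#'
#' @param truth A `sim_truth` tibble from [simulate_embryo_cohort()].
#' @param haplotypes The matching [simulate_trio_haplotypes()] result.
#' @return Tibble: `cell_id, locus_id, chrom, pos, offset_bp, copy_m,
#'   copy_p` (one row per cell x locus; target row has `offset_bp = 0`).
#' @export
true_locus_copies <- function(truth, haplotypes) {
  stopifnot(inherits(haplotypes, "parental_haplotypes"))
  v <- haplotypes$variants
  flank <- tidyr::crossing(
    tibble::tibble(cell_id = truth$cell_id),
    v[, c("locus_id", "chrom", "pos", "offset_bp",
          "mat_transmitted", "pat_transmitted")]
  ) |>
    dplyr::left_join(
      truth[, c("cell_id", "tract_parent", "tract_left", "tract_right")],
      by = "cell_id"
    ) |>
    dplyr::mutate(
      in_tract = !is.na(.data$tract_parent) &
        .data$offset_bp >= .data$tract_left &
        .data$offset_bp <= .data$tract_right,
      copy_m = dplyr::if_else(.data$in_tract & .data$tract_parent == "paternal",
                              .data$pat_transmitted, .data$mat_transmitted),
      copy_p = dplyr::if_else(.data$in_tract & .data$tract_parent == "maternal",
                              .data$mat_transmitted, .data$pat_transmitted)
    ) |>
    dplyr::select("cell_id", "locus_id", "chrom", "pos", "offset_bp",
                  "copy_m", "copy_p")
  target <- tibble::tibble(
    cell_id = truth$cell_id,
    locus_id = haplotypes$target$locus_id,
    chrom = haplotypes$target$chrom,
    pos = haplotypes$target$pos,
    offset_bp = 0L,
    copy_m = truth$allele_m,
    copy_p = truth$allele_p
  )
  dplyr::bind_rows(flank, target) |>
    dplyr::arrange(.data$cell_id, .data$offset_bp)
}
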