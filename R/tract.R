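#' Classify flanking-variant informativeness from parental genotypes
#'
#' A variant is `informative` when both parents are homozygous for
#' different alleles (offspring allele origin is unambiguous),
#' `semi_informative` when at least one parent is heterozygous (offspring
#' homozygosity is detectable but its parental origin is not), and
#' `uninformative` when both parents are homozygous for the same allele.
#' Missing parental genotypes give `undetermined`.
#'
#' @param maternal_gt,paternal_gt Diploid genotypes as `"A/G"` strings
#'   (vectorised).
#' @return Character vector of informativeness classes.
#' @examples
#' classify_informativeness(c("A/A", "A/G", "A/A"), c("G/G", "G/G", "A/A"))
#' @export
classify_informativeness <- function(maternal_gt, paternal_gt) {
  split_gt <- function(gt) strsplit(gt, "/", fixed = TRUE)
  m <- split_gt(maternal_gt)
  p <- split_gt(paternal_gt)
  vapply(seq_along(m), function(i) {
    if (is.na(maternal_gt[i]) || is.na(paternal_gt[i])) return("undetermined")
    mhom <- m[[i]][1] == m[[i]][2]
    phom <- p[[i]][1] == p[[i]][2]
    if (mhom && phom) {
      if (m[[i]][1] != p[[i]][1]) "informative" else "uninformative"
    } else {
      "semi_informative"
    }
  }, character(1))
}

hom_allele <- function(gt) {
  al <- strsplit(gt, "/", fixed = TRUE)
  vapply(al, function(x) if (x[1] == x[2]) x[1] else NA_character_,
         character(1))
}

#' Detect the LOH segment around the cut site in one cell
#'
#' Finds the maximal contiguous run of homozygous calls containing the
#' target locus (offset 0). Variants that did not amplify are transparent:
#' they neither extend nor break the run (they are counted as skipped);
#' `strict = TRUE` instead breaks the run at missing data. Returns `NULL`
#' when the target call is absent or not homozygous. When every flanking
#' variant failed to amplify the segment is the target alone, flagged
#' low-confidence.
#'
#' @param cell_calls Tibble for one cell with columns `offset_bp, status`
#'   (the target row has `offset_bp = 0`), sorted or sortable by offset.
#' @param strict Break the segment at non-amplified variants.
#' @return `NULL`, or a list with `seg_left, seg_right` (outermost
#'   homozygous offsets in the segment, 0 when the target alone),
#'   `left_het, right_het` (innermost heterozygous offsets flanking the
#'   segment, `NA` when none before the panel edge), `hom_offsets`,
#'   `n_skipped`, `low_confidence`.
#' @export
detect_loh_segment <- function(cell_calls, strict = FALSE) {
  cc <- dplyr::arrange(cell_calls, .data$offset_bp)
  t_row <- which(cc$offset_bp == 0)
  if (length(t_row) != 1)
    abort("cell calls must contain exactly one target row (offset 0)",
          class = "blastocall_data_error")
  if (cc$status[t_row] != "homozygous") return(NULL)

  walk <- function(idx_seq) {
    hom <- integer(0); het <- NA_integer_; skipped <- 0L
    for (i in idx_seq) {
      s <- cc$status[i]
      if (s == "homozygous") {
        hom <- c(hom, cc$offset_bp[i])
      } else if (s == "not_amplified") {
        if (strict) { break } else { skipped <- skipped + 1L }
      } else {  # heterozygous or multi_allelic ends the run
        het <- cc$offset_bp[i]
        break
      }
    }
    list(hom = hom, het = het, skipped = skipped)
  }
  left <- walk(rev(seq_len(t_row - 1L)))
  right <- walk(seq(t_row + 1L, length.out = nrow(cc) - t_row))

  hom_offsets <- c(left$hom, 0L, right$hom)
  flank_assayed <- any(cc$status[-t_row] != "not_amplified")
  list(
    seg_left = min(hom_offsets),
    seg_right = max(hom_offsets),
    left_het = left$het,
    right_het = right$het,
    hom_offsets = sort(hom_offsets),
    n_skipped = left$skipped + right$skipped,
    low_confidence = !flank_assayed
  )
}

#' Classify homozygous in-segment variants and assign the template parent
#'
#' Each homozygous variant inside the segment is scored against the
#' parental genotypes. A site is *converted* when the observed homozygous
#' allele is incompatible with one parent's possible contributions — at an
#' informative site any homozygosity qualifies (the parents are homozygous
#' for different alleles, so the offspring is obligate heterozygous); at a
#' semi-informative site it qualifies only when the observed allele is
#' absent from one parent's genotype. Converted sites identify the lost
#' parental allele, so each votes for the surviving (template) parent.
#' Homozygosity compatible with both parents (possible identical
#' transmission) is *ambiguous*: it extends the segment but proves
#' nothing. A unanimous vote names the template parent; conflicting votes
#' give `undetermined` with a conflict flag; only-ambiguous segments are
#' `undetermined`.
#'
#' @param segment Result of [detect_loh_segment()].
#' @param cell_calls The same per-cell call tibble, with an `allele` column
#'   holding the single supported allele of homozygous calls.
#' @param variants Flank-variant tibble (from
#'   [simulate_trio_haplotypes()]`$variants` or [read_panel_tsv()]) with
#'   `offset_bp, maternal_gt, paternal_gt, informativeness`.
#' @return List: `template_parent` (`"maternal"`, `"paternal"` or
#'   `"undetermined"`), `conflict`, `n_converted_informative` (converted
#'   sites at informative variants), `n_converted` (all converted sites),
#'   `converted_offsets`, `n_ambiguous`.
#' @export
infer_template_parent <- function(segment, cell_calls, variants) {
  empty <- list(template_parent = "undetermined", conflict = FALSE,
                n_converted_informative = 0L, n_converted = 0L,
                converted_offsets = integer(0), n_ambiguous = 0L)
  if (is.null(segment)) return(empty)
  seg_vars <- variants |>
    dplyr::filter(.data$offset_bp >= segment$seg_left,
                  .data$offset_bp <= segment$seg_right) |>
    dplyr::inner_join(
      dplyr::filter(cell_calls, .data$status == "homozygous"),
      by = "offset_bp"
    )
  if (nrow(seg_vars) == 0) return(empty)

  gt_alleles <- function(gt) strsplit(gt, "/", fixed = TRUE)[[1]]
  votes <- character(0)
  conv_off <- integer(0)
  n_conv_inf <- 0L
  n_amb <- 0L
  for (i in seq_len(nrow(seg_vars))) {
    obs <- seg_vars$allele[i]
    if (is.na(obs)) { n_amb <- n_amb + 1L; next }
    in_m <- obs %in% gt_alleles(seg_vars$maternal_gt[i])
    in_p <- obs %in% gt_alleles(seg_vars$paternal_gt[i])
    if (in_m && !in_p) {
      votes <- c(votes, "maternal")   # paternal allele lost
    } else if (!in_m && in_p) {
      votes <- c(votes, "paternal")   # maternal allele lost
    } else {
      n_amb <- n_amb + 1L             # compatible with both (or neither)
      next
    }
    conv_off <- c(conv_off, seg_vars$offset_bp[i])
    if (seg_vars$informativeness[i] == "informative")
      n_conv_inf <- n_conv_inf + 1L
  }
  if (length(votes) == 0) {
    empty$n_ambiguous <- n_amb
    return(empty)
  }
  conflict <- dplyr::n_distinct(votes) > 1
  list(
    template_parent = if (conflict) "undetermined" else votes[1],
    conflict = conflict,
    n_converted_informative = n_conv_inf,
    n_converted = length(votes),
    converted_offsets = sort(conv_off),
    n_ambiguous = n_amb
  )
}

#' Bound the gene-conversion tract length
#'
#' The minimum tract spans the outermost *converted* positions in the
#' segment (homozygous sites whose allele rules out one parent; see
#' [infer_template_parent()]) together with the target at offset 0,
#' inclusive of both endpoints — merely-homozygous ambiguous sites carry no
#' proof of conversion and never extend the minimum. The maximum spans the
#' innermost heterozygous variants flanking the segment, exclusive, falling
#' back to the panel edge (outermost assayed variant, inclusive) on sides
#' with no heterozygous flank. A segment with no converted variant has
#' `min_tract_bp = 1` (the target base alone).
#'
#' @param segment Result of [detect_loh_segment()] (non-`NULL`).
#' @param variants Flank-variant tibble with `offset_bp`.
#' @param converted_offsets Offsets of converted variants inside the
#'   segment (from [infer_template_parent()]); empty means target-only.
#' @return Named numeric vector `c(min_tract_bp, max_tract_bp)`.
#' @examples
#' # converted variants at -2623 and +2963, het flanks at -3324 and +8000:
#' seg <- list(seg_left = -2623, seg_right = 2963,
#'             left_het = -3324, right_het = 8000)
#' tract_length_bounds(seg, tibble::tibble(offset_bp = c(-3324, -2623,
#'                                                       2963, 8000)),
#'                     converted_offsets = c(-2623, 2963))
#' @export
tract_length_bounds <- function(segment, variants,
                                converted_offsets = integer(0)) {
  if (is.null(segment))
    abort("no LOH segment: tract bounds are undefined",
          class = "blastocall_data_error")
  conv <- c(converted_offsets, 0L)
  min_bp <- max(conv) - min(conv) + 1
  left_excl <- if (!is.null(segment$left_het) && !is.na(segment$left_het))
    segment$left_het else min(variants$offset_bp, 0) - 1
  right_excl <- if (!is.null(segment$right_het) && !is.na(segment$right_het))
    segment$right_het else max(variants$offset_bp, 0) + 1
  max_bp <- right_excl - left_excl - 1
  c(min_tract_bp = as.numeric(min_bp), max_tract_bp = as.numeric(max_bp))
}

#' Infer LOH segments and conversion tracts for every cell
#'
#' Runs [detect_loh_segment()], [infer_template_parent()] and
#' [tract_length_bounds()] over each sample's calls at the flank variants
#' and the target locus.
#'
#' @param calls Genotype calls (from [call_genotypes()]) covering the flank
#'   loci and the target locus for one or more samples.
#' @param variants Flank-variant tibble with `locus_id, offset_bp,
#'   maternal_gt, paternal_gt, informativeness`.
#' @param target_locus_id Locus id of the cut-site call (offset 0).
#' @param strict Passed to [detect_loh_segment()].
#' @return Tibble: `cell_id, has_loh, template_parent, min_tract_bp,
#'   max_tract_bp, n_converted_informative, n_converted, n_ambiguous,
#'   conflict, n_skipped, low_confidence`.
#' @export
infer_tracts <- function(calls, variants, target_locus_id = "target",
                         strict = FALSE) {
  offsets <- dplyr::bind_rows(
    variants[, c("locus_id", "offset_bp")],
    tibble::tibble(locus_id = target_locus_id, offset_bp = 0L)
  )
  cc <- calls |>
    dplyr::inner_join(offsets, by = "locus_id") |>
    dplyr::mutate(allele = purrr::map_chr(
      .data$alleles, ~ if (length(.x) == 1) .x else NA_character_))

  purrr::map_dfr(split(cc, cc$sample_id), function(one) {
    seg <- detect_loh_segment(one, strict = strict)
    if (is.null(seg)) {
      return(tibble::tibble(
        cell_id = one$sample_id[1], has_loh = FALSE,
        template_parent = NA_character_, min_tract_bp = NA_real_,
        max_tract_bp = NA_real_, n_converted_informative = 0L,
        n_converted = 0L, n_ambiguous = 0L, conflict = FALSE,
        n_skipped = NA_integer_, low_confidence = FALSE))
    }
    par <- infer_template_parent(seg, one, variants)
    b <- tract_length_bounds(seg, variants, par$converted_offsets)
    tibble::tibble(
      cell_id = one$sample_id[1], has_loh = TRUE,
      template_parent = par$template_parent,
      min_tract_bp = b[["min_tract_bp"]],
      max_tract_bp = b[["max_tract_bp"]],
      n_converted_informative = par$n_converted_informative,
      n_converted = par$n_converted,
      n_ambiguous = par$n_ambiguous,
      conflict = par$conflict,
      n_skipped = seg$n_skipped,
      low_confidence = seg$low_confidence)
  })
}
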