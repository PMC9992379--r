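#' Simulate a parental haplotype pair around the cut site
#'
#' Builds the phased trio context the tract-inference stage consumes: a set
#' of flanking variants at signed bp offsets from the DSB (offset 0), each
#' with diploid maternal and paternal genotypes, the allele each parent
#' transmitted to the embryo, and an informativeness class (informative =
#' parents homozygous for different alleles; semi-informative = heterozygous
#' in at least one parent; uninformative otherwise). The target site itself
#' carries a WT or pathogenic-Mut state per transmitted allele, plus the
#' synonymous ssODN marker substitutions used to recognise HDR alleles.
#'
#' @param config A [sim_config()].
#' @param n_flank_variants Number of flanking variants (>= 2).
#' @param p_informative,p_semi_informative Probabilities that a variant is
#'   informative / semi-informative (remainder uninformative). Defaults
#'   4/27 and 23/27, the composition observed around a real cut site.
#' @param max_offset Flank variants are placed within `+/- max_offset` bp.
#' @param offsets Optional explicit signed offsets (overrides random
#'   placement; length must equal `n_flank_variants`).
#' @param informativeness Optional explicit per-variant classes
#'   (`"informative"`, `"semi_informative"`, `"uninformative"`), aligned
#'   with the sorted offsets — use this to reproduce a designed panel whose
#'   informative positions are known; overrides the random class draw.
#' @param chrom,target_pos Coordinates of the cut site (1-based).
#'
#' @return A `parental_haplotypes` list with elements `variants` (tibble:
#'   `variant_idx, locus_id, chrom, pos, offset_bp, maternal_gt,
#'   paternal_gt, mat_transmitted, pat_transmitted, informativeness`),
#'   `target` (chrom/pos/locus_id and transmitted target states) and
#'   `markers` (tibble of marker substitutions within +/-110 bp).
#' @examples
#' hp <- simulate_trio_haplotypes(sim_config(seed = 7), n_flank_variants = 6)
#' hp$variants
#' @export
simulate_trio_haplotypes <- function(config,
                                     n_flank_variants = 27,
                                     p_informative = 4 / 27,
                                     p_semi_informative = 23 / 27,
                                     max_offset = 20000,
                                     offsets = NULL,
                                     informativeness = NULL,
                                     chrom = "chr11",
                                     target_pos = 47332000L) {
  validate_sim_config(config)
  if (n_flank_variants < 2)
    abort("n_flank_variants must be >= 2", class = "blastocall_config_error")
  if (p_informative < 0 || p_semi_informative < 0 ||
      p_informative + p_semi_informative > 1 + 1e-12)
    abort("invalid sim_config: field `p_informative`/`p_semi_informative` must be probabilities summing to <= 1",
          class = "blastocall_config_error")
  set.seed(config$seed)

  if (is.null(offsets)) {
    offsets <- sort(sample(setdiff(seq(-max_offset, max_offset), 0),
                           n_flank_variants))
  } else {
    if (length(offsets) != n_flank_variants)
      abort("length(offsets) must equal n_flank_variants",
            class = "blastocall_config_error")
    if (any(offsets == 0) || anyDuplicated(offsets))
      abort("offsets must be non-zero and unique",
            class = "blastocall_config_error")
    offsets <- sort(as.integer(offsets))
  }
  n <- n_flank_variants
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, n, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))

  if (is.null(informativeness)) {
    cls <- sample(c("informative", "semi_informative", "uninformative"), n,
                  replace = TRUE,
                  prob = c(p_informative, p_semi_informative,
                           max(0, 1 - p_informative - p_semi_informative)))
  } else {
    if (length(informativeness) != n ||
        !all(informativeness %in% c("informative", "semi_informative",
                                    "uninformative")))
      abort("informativeness must give one known class per flank variant",
            class = "blastocall_config_error")
    cls <- informativeness
  }

  mk_gt <- function(x, y) paste(x, y, sep = "/")
  maternal_gt <- character(n); paternal_gt <- character(n)
  for (i in seq_len(n)) {
    if (cls[i] == "informative") {
      maternal_gt[i] <- mk_gt(a1[i], a1[i]); paternal_gt[i] <- mk_gt(a2[i], a2[i])
    } else if (cls[i] == "semi_informative") {
      # at least one parent heterozygous; the other random
      het_parent <- sample(c("m", "p"), 1L)
      het <- mk_gt(a1[i], a2[i])
      hom <- mk_gt(sample(c(a1[i], a2[i]), 1L), NA)
      hom <- sub("/NA", "", hom); hom <- mk_gt(hom, hom)
      if (het_parent == "m") { maternal_gt[i] <- het; paternal_gt[i] <- hom }
      else                   { maternal_gt[i] <- hom; paternal_gt[i] <- het }
    } else {
      maternal_gt[i] <- mk_gt(a1[i], a1[i]); paternal_gt[i] <- mk_gt(a1[i], a1[i])
    }
  }
  transmit <- function(gt) {
    al <- strsplit(gt, "/", fixed = TRUE)[[1]]
    if (al[1] == al[2]) al[1] else sample(al, 1L)
  }
  mat_tx <- vapply(maternal_gt, transmit, character(1), USE.NAMES = FALSE)
  pat_tx <- vapply(paternal_gt, transmit, character(1), USE.NAMES = FALSE)

  variants <- tibble::tibble(
    variant_idx = seq_len(n),
    locus_id = sprintf("flank_%02d", seq_len(n)),
    chrom = chrom,
    pos = as.integer(target_pos + offsets),
    offset_bp = as.integer(offsets),
    maternal_gt = maternal_gt,
    paternal_gt = paternal_gt,
    mat_transmitted = mat_tx,
    pat_transmitted = pat_tx,
    informativeness = classify_informativeness(maternal_gt, paternal_gt)
  )

  n_mark <- config$n_markers
  marker_off <- sort(sample(setdiff(-110:110, 0), n_mark))
  ref_base <- sample(bases, n_mark, replace = TRUE)
  marker_base <- vapply(ref_base, function(b) sample(setdiff(bases, b), 1L),
                        character(1), USE.NAMES = FALSE)

  # with a heterozygous sperm donor (p_paternal_mut set) the Mut/WT draw is
  # per embryo and happens in simulate_embryo_cohort(); here we record the
  # donor-level default state only
  pat_target <- config$paternal_target

  mut_ref_base <- sample(bases, 1L)
  mut_alt_base <- sample(setdiff(bases, mut_ref_base), 1L)

  structure(
    list(
      variants = variants,
      target = list(chrom = chrom, pos = as.integer(target_pos),
                    locus_id = "target",
                    maternal_state = config$maternal_target,
                    paternal_state = pat_target,
                    mut_ref_base = mut_ref_base,
                    mut_alt_base = mut_alt_base),
      markers = tibble::tibble(offset_bp = as.integer(marker_off),
                               ref_base = ref_base,
                               marker_base = marker_base),
      seed = config$seed
    ),
    class = "parental_haplotypes"
  )
}

#' Reference flank-panel design around a cut site
#'
#' Layout of a designed 27-variant flank panel mirroring the real analysis:
#' four informative variants at -2623, -2551, -2069 and +2963 bp from the
#' cut site, plus 23 semi-informative variants scattered between -3324 and
#' +16185 bp. Pass the result to [simulate_trio_haplotypes()] via its
#' `offsets` and `informativeness` arguments.
#'
#' @param seed Integer seed for the scatter positions.
#' @return List with sorted `offsets` and aligned `informativeness`.
#' @examples
#' d <- flank_panel_design(1)
#' table(d$informativeness)
#' @export
flank_panel_design <- function(seed) {
  informative_at <- c(-2623L, -2551L, -2069L, 2963L)
  set.seed(seed + 6L)
  scatter <- sample(setdiff(seq(-3324L, 16185L), c(0L, informative_at)), 23L)
  offsets <- c(informative_at, scatter)
  cls <- c(rep("informative", 4L), rep("semi_informative", 23L))
  ord <- order(offsets)
  list(offsets = offsets[ord], informativeness = cls[ord])
}

#' @export
print.parental_haplotypes <- function(x, ...) {
  cat(sprintf("<parental_haplotypes> %d flank variants (%d informative, %d semi-informative), target %s:%d (m:%s / p:%s), %d ssODN markers\n",
              nrow(x$variants),
              sum(x$variants$informativeness == "informative"),
              sum(x$variants$informativeness == "semi_informative"),
              x$target$chrom, x$target$pos,
              x$target$maternal_state, x$target$paternal_state,
              nrow(x$markers)))
  invisible(x)
}
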