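## canonical category print order; reproduces the compound labels used in
## the field (WT/Del, Del/Indel, Del/HDR, Indel/HDR, Mut/Indel, ...)
category_order <- c(WT = 1, Mut = 2, Del = 3, Indel = 4, HDR = 5)

category_print <- c(WT = "WT", Mut = "Mut", Indel = "Indel",
                    LargeDel = "Del", HDR = "HDR")

#' Parse canonical allele keys into edit categories
#'
#' Allele keys are the compact strings carried through the pipeline:
#' `"WT"`, `"Mut"`, `"HDR"`, `"indel<+/-size>.<tag>"` (NHEJ indel,
#' `1 <= |size| < 100`), `"del-<size>.<shift>"` (large deletion,
#' `size >= 100`).
#'
#' @param keys Character vector of allele keys.
#' @return Tibble: `key, category` (`WT, Mut, Indel, LargeDel, HDR`),
#'   `size_bp` (signed net length change; 0 for WT/Mut/HDR).
#' @examples
#' parse_allele_key(c("WT", "indel-2.0", "del-1873.3"))
#' @export
parse_allele_key <- function(keys) {
  category <- character(length(keys))
  size_bp <- integer(length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% c("WT", "Mut", "HDR")) {
      category[i] <- k; size_bp[i] <- 0L
    } else if (grepl("^indel[+-][0-9]+\\.", k)) {
      s <- as.integer(sub("^indel([+-][0-9]+)\\..*$", "\\1", k))
      if (abs(s) < 1 || abs(s) >= 100)
        abort(sprintf("indel key out of range: %s", k),
              class = "blastocall_data_error")
      category[i] <- "Indel"; size_bp[i] <- s
    } else if (grepl("^del-[0-9]+\\.", k)) {
      s <- as.integer(sub("^del-([0-9]+)\\..*$", "\\1", k))
      if (s < 100)
        abort(sprintf("large-deletion key below 100 bp: %s", k),
              class = "blastocall_data_error")
      category[i] <- "LargeDel"; size_bp[i] <- -s
    } else {
      abort(sprintf("unrecognised allele key: %s", k),
            class = "blastocall_data_error")
    }
  }
  tibble::tibble(key = keys, category = category, size_bp = size_bp)
}

#' Classify an on-target allele sequence
#'
#' Resolves one aligned target-window allele into the edit taxonomy:
#' an exact reference match is `WT`; the known pathogenic base alone is
#' `Mut`; all ssODN marker substitutions present with no other change is
#' `HDR`; otherwise the net length change decides between `Indel`
#' (`< 100` bp) and `LargeDel` (`>= 100` bp). An allele carrying all
#' markers *and* a large deletion is a classification conflict and raises
#' an error rather than a guess. Partial marker presence (some but not all
#' substitutions, no other change) is not a valid category: the result
#' carries `category = NA` with `partial_hdr = TRUE` as an audit flag.
#'
#' @param allele_seq Allele sequence aligned to the target window.
#' @param reference_context Reference sequence of the same window.
#' @param markers Tibble with `pos` (1-based position in
#'   `reference_context`) and `marker_base`.
#' @param mut_def List with `pos` and `alt` (the pathogenic base).
#' @return One-row tibble: `category, size_bp, partial_hdr`.
#' @export
classify_on_target_allele <- function(allele_seq, reference_context,
                                      markers, mut_def) {
  d <- nchar(allele_seq) - nchar(reference_context)
  marker_hits <- marker_presence(allele_seq, reference_context, markers, d)

  if (d != 0) {
    if (d <= -100 && all(marker_hits))
      abort("classification conflict: allele carries all ssODN markers and a >=100 bp deletion",
            class = "blastocall_classification_error")
    if (d >= 100)
      abort("insertions >= 100 bp are outside the edit taxonomy",
            class = "blastocall_classification_error")
    cat_ <- if (d <= -100) "LargeDel" else "Indel"
    return(tibble::tibble(category = cat_, size_bp = as.integer(d),
                          partial_hdr = FALSE))
  }

  ref <- strsplit(reference_context, "")[[1]]
  alt <- strsplit(allele_seq, "")[[1]]
  diffs <- which(ref != alt)
  if (length(diffs) == 0)
    return(tibble::tibble(category = "WT", size_bp = 0L, partial_hdr = FALSE))
  if (identical(diffs, as.integer(mut_def$pos)) &&
      alt[mut_def$pos] == mut_def$alt)
    return(tibble::tibble(category = "Mut", size_bp = 0L, partial_hdr = FALSE))
  marker_pos <- as.integer(markers$pos)
  if (all(diffs %in% marker_pos)) {
    if (all(marker_hits))
      return(tibble::tibble(category = "HDR", size_bp = 0L,
                            partial_hdr = FALSE))
    return(tibble::tibble(category = NA_character_, size_bp = 0L,
                          partial_hdr = TRUE))
  }
  # substitutions outside the known mutation/marker set: report, don't guess
  tibble::tibble(category = NA_character_, size_bp = 0L, partial_hdr = FALSE)
}

## check each marker base at its unshifted or deletion-shifted position
marker_presence <- function(allele_seq, reference_context, markers, d) {
  alt <- strsplit(allele_seq, "")[[1]]
  vapply(seq_len(nrow(markers)), function(i) {
    p <- markers$pos[i]
    b <- markers$marker_base[i]
    hit <- p <= length(alt) && alt[p] == b
    if (!hit && d != 0) {
      ps <- p + d
      hit <- ps >= 1 && ps <= length(alt) && alt[ps] == b
    }
    hit
  }, logical(1))
}

#' Label a cell's on-target genotype
#'
#' Maps the distinct observed alleles at the cut site to the canonical
#' paired label. One distinct allele gives `homo-<category>` with
#' `loh_flag = TRUE` (the cell shows loss of heterozygosity: a true
#' conversion/deletion event or an allelic dropout). Two distinct alleles
#' give a compound label in fixed category order
#' (WT, Mut, Del, Indel, HDR), e.g. `"WT/Indel"`, `"Del/Indel"`.
#'
#' @param allele_keys Character vector of 1 or 2 *distinct* allele keys
#'   (see [parse_allele_key()]).
#' @return One-row tibble: `label, loh_flag, n_distinct`.
#' @examples
#' label_cell_genotype(c("WT", "indel-2.0"))   # WT/Indel
#' label_cell_genotype("indel-1.0")            # homo-Indel
#' @export
label_cell_genotype <- function(allele_keys) {
  allele_keys <- unique(allele_keys)
  n <- length(allele_keys)
  if (n == 0)
    abort("no alleles observed: cannot label genotype (no-call)",
          class = "blastocall_data_error")
  if (n > 2)
    abort("more than two distinct alleles: multi-allelic state is an error, not a genotype",
          class = "blastocall_data_error")
  cats <- parse_allele_key(allele_keys)$category
  if (any(is.na(cats)))
    abort("unclassified allele cannot be labelled",
          class = "blastocall_data_error")
  pr <- category_print[cats]
  if (n == 1) {
    tibble::tibble(label = paste0("homo-", pr), loh_flag = TRUE,
                   n_distinct = 1L)
  } else {
    pr <- pr[order(category_order[pr])]
    tibble::tibble(label = paste(pr, collapse = "/"), loh_flag = FALSE,
                   n_distinct = 2L)
  }
}

#' Label every cell's genotype from target-locus calls
#'
#' Applies [label_cell_genotype()] to the supported allele keys of each
#' cell's target-locus genotype call. Cells whose target locus did not
#' amplify get `label = NA`.
#'
#' @param calls Call tibble from [call_genotypes()] restricted to the
#'   target locus (allele keys in the `alleles` list-column).
#' @return Tibble: `cell_id, label, loh_flag, n_distinct, status`.
#' @export
classify_cells <- function(calls) {
  purrr::pmap_dfr(
    list(calls$sample_id, calls$alleles, calls$status),
    function(id, keys, status) {
      if (status == "not_amplified" || length(keys) == 0) {
        return(tibble::tibble(cell_id = id, label = NA_character_,
                              loh_flag = NA, n_distinct = 0L,
                              status = status))
      }
      lab <- label_cell_genotype(keys)
      tibble::tibble(cell_id = id, label = lab$label,
                     loh_flag = lab$loh_flag,
                     n_distinct = lab$n_distinct, status = status)
    }
  )
}

#' Ground-truth cell labels from a simulated cohort
#'
#' Derives the label each cell would receive under perfect (dropout-free)
#' observation of its true alleles, for recovery tests against the calling
#' and classification pipeline.
#'
#' @param truth `sim_truth` tibble.
#' @return Tibble: `embryo_id, cell_id, label, loh_flag`.
#' @export
truth_cell_labels <- function(truth) {
  labs <- purrr::map2_dfr(truth$allele_m, truth$allele_p,
                          ~ label_cell_genotype(unique(c(.x, .y))))
  tibble::tibble(embryo_id = truth$embryo_id, cell_id = truth$cell_id,
                 label = labs$label, loh_flag = labs$loh_flag)
}

#' Classify embryos as uniform or mosaic
#'
#' An embryo is uniform when all sister blastomeres share one on-target
#' genotype label, mosaic when at least `min_distinct` distinct labels are
#' present (default 2, the complement of "uniformly edited"; set 3 for the
#' stricter reading of "more than 2 differently edited blastomeres").
#' Cells without a label (target not amplified) are excluded.
#'
#' @param cell_labels Tibble with `embryo_id, cell_id, label`.
#' @param min_distinct Distinct-label count at or above which an embryo is
#'   called mosaic.
#' @return Tibble: `embryo_id, n_cells, n_distinct, mosaic, classification`.
#' @export
classify_embryo_mosaicism <- function(cell_labels, min_distinct = 2) {
  if (nrow(cell_labels) == 0)
    abort("empty cohort: no cells to classify",
          class = "blastocall_data_error")
  kept <- dplyr::filter(cell_labels, !is.na(.data$label))
  if (nrow(kept) == 0)
    abort("no labelled cells: every target locus failed to amplify",
          class = "blastocall_data_error")
  kept |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_distinct = dplyr::n_distinct(.data$label),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mosaic = .data$n_distinct >= min_distinct,
      classification = dplyr::if_else(.data$mosaic, "mosaic", "uniform")
    )
}

#' Materialise an allele key as a target-window sequence
#'
#' Builds the reference window and the allele sequence a key represents,
#' so sequence-level classification can be checked against the simulator's
#' ground truth. The window is a deterministic pseudo-random sequence
#' anchored to the haplotype seed, with the pathogenic base at the centre
#' (the cut site) and the ssODN markers at their signed offsets.
#'
#' @param key Allele key (see [parse_allele_key()]).
#' @param haplotypes [simulate_trio_haplotypes()] result.
#' @param halfwidth Half window width in bp; must exceed any deletion size
#'   plus shift in `key`.
#' @return List: `allele_seq`, `reference_context`, `markers` (tibble with
#'   in-window `pos`), `mut_def` (list with `pos`, `alt`).
#' @export
materialize_allele <- function(key, haplotypes, halfwidth = 2500) {
  stopifnot(inherits(haplotypes, "parental_haplotypes"))
  set.seed(haplotypes$seed + 4L)
  width <- 2L * halfwidth + 1L
  centre <- halfwidth + 1L
  ref <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  ref[centre] <- haplotypes$target$mut_ref_base
  mk <- haplotypes$markers
  mk$pos <- centre + mk$offset_bp
  ref[mk$pos] <- mk$ref_base
  mut_def <- list(pos = centre, alt = haplotypes$target$mut_alt_base)

  alt <- ref
  info <- parse_allele_key(key)
  if (info$category == "Mut") {
    alt[centre] <- mut_def$alt
  } else if (info$category == "HDR") {
    alt[mk$pos] <- mk$marker_base
  } else if (info$category %in% c("Indel", "LargeDel")) {
    tag <- sub("^(indel[+-][0-9]+|del-[0-9]+)\\.", "", key)
    if (info$size_bp < 0) {
      k <- -info$size_bp
      shift <- as.integer(tag)
      start <- if (info$category == "LargeDel")
        centre + shift - k %/% 2L else centre + shift
      start <- max(1L, min(start, length(alt) - k))
      alt <- alt[-(start:(start + k - 1L))]
    } else {
      ins <- strsplit(tag, "")[[1]]
      alt <- append(alt, ins, after = centre)
    }
  }
  list(allele_seq = paste(alt, collapse = ""),
       reference_context = paste(ref, collapse = ""),
       markers = mk[, c("pos", "marker_base")],
       mut_def = mut_def)
}
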