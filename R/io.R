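## Tab-separated interchange formats. All files are UTF-8 TSV with a header
## row; coordinates are 1-based inclusive (VCF convention); signed offsets
## relative to the cut site appear only in the flank-variant panel.

#' Read and write pipeline tables
#'
#' TSV readers/writers for the interchange formats: allele-depth evidence
#' (`sample_id, locus_id, chrom, pos, allele, depth`), simulation truth
#' (`embryo_id, cell_id, allele_m, allele_p, tract_parent, tract_left,
#' tract_right`), the flank-variant panel (`locus_id, chrom, pos,
#' offset_bp, maternal_allele, paternal_allele, informativeness`), genotype
#' calls (alleles comma-joined) and ADO estimates.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
write_evidence_tsv <- function(x, path) {
  readr::write_tsv(x[, c("sample_id", "locus_id", "chrom", "pos",
                         "allele", "depth")], path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_evidence_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", locus_id = "c", chrom = "c", pos = "i",
    allele = "c", depth = "i"))
}

#' @rdname pipeline-io
#' @export
write_truth_tsv <- function(x, path) {
  cols <- c("embryo_id", "cell_id", "allele_m", "allele_p",
            "tract_parent", "tract_left", "tract_right")
  readr::write_tsv(x[, cols], path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    embryo_id = "c", cell_id = "c", allele_m = "c", allele_p = "c",
    tract_parent = "c", tract_left = "d", tract_right = "d"))
}

#' @rdname pipeline-io
#' @param haplotypes For `write_panel_tsv()`, a
#'   [simulate_trio_haplotypes()] result (its `variants` are written).
#' @export
write_panel_tsv <- function(haplotypes, path) {
  v <- haplotypes$variants
  out <- tibble::tibble(
    locus_id = v$locus_id, chrom = v$chrom, pos = v$pos,
    offset_bp = v$offset_bp,
    maternal_allele = v$maternal_gt, paternal_allele = v$paternal_gt,
    informativeness = v$informativeness
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_panel_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    locus_id = "c", chrom = "c", pos = "i", offset_bp = "i",
    maternal_allele = "c", paternal_allele = "c",
    informativeness = "c")) |>
    dplyr::rename(maternal_gt = "maternal_allele",
                  paternal_gt = "paternal_allele")
}

#' @rdname pipeline-io
#' @export
write_calls_tsv <- function(x, path) {
  out <- x |>
    dplyr::mutate(alleles = purrr::map_chr(
      .data$alleles, paste, collapse = ",")) |>
    dplyr::select("sample_id", "locus_id", "status", "alleles",
                  "total_depth")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", locus_id = "c", status = "c", alleles = "c",
    total_depth = "i")) |>
    dplyr::mutate(
      alleles = purrr::map(.data$alleles, ~ {
        if (is.na(.x) || .x == "") character() else
          strsplit(.x, ",", fixed = TRUE)[[1]]
      }),
      n_alleles = lengths(.data$alleles)
    ) |>
    dplyr::select("sample_id", "locus_id", "status", "alleles",
                  "n_alleles", "total_depth")
}

#' @rdname pipeline-io
#' @export
write_ado_tsv <- function(x, path) {
  readr::write_tsv(x[, c("scope", "scope_id", "n_homozygous",
                         "n_amplified", "rate")], path)
  invisible(path)
}
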