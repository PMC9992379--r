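#' Call per-locus genotypes from allele-depth evidence
#'
#' Implements the coverage-threshold caller used for amplicon panels:
#' a locus with total depth below `min_depth` (default 12x) is considered
#' not amplified and excluded from genotyping; otherwise an allele is
#' supported when its depth reaches both `min_allele_reads` reads and
#' `min_allele_frac` of the locus depth. One supported allele gives a
#' homozygous call, two a heterozygous call; more than two are reported as
#' `multi_allelic` (possible contamination or WGA chimera) and never
#' silently collapsed.
#'
#' @param evidence Tibble with columns `sample_id, locus_id, allele, depth`
#'   (rows with allele `"."` mark assayed-but-unamplified loci and are never
#'   supported). `(sample_id, locus_id, allele)` must be unique.
#' @param min_depth Minimum total locus depth to attempt genotyping.
#' @param min_allele_frac Minimum fraction of locus depth per supported allele.
#' @param min_allele_reads Minimum reads per supported allele.
#' @return Tibble: `sample_id, locus_id, status, alleles` (list-column of
#'   supported alleles, depth-sorted), `n_alleles, total_depth`, with
#'   `status` one of `not_amplified, homozygous, heterozygous,
#'   multi_allelic`.
#' @examples
#' ev <- tibble::tibble(sample_id = "c1", locus_id = "L1",
#'                      allele = c("G", "A"), depth = c(30L, 25L))
#' call_genotypes(ev)
#' @export
call_genotypes <- function(evidence, min_depth = 12, min_allele_frac = 0.1,
                           min_allele_reads = 3) {
  req <- c("sample_id", "locus_id", "allele", "depth")
  if (!all(req %in% names(evidence)))
    abort(paste("evidence must have columns:", paste(req, collapse = ", ")),
          class = "blastocall_data_error")
  if (any(evidence$depth < 0))
    abort("depth must be non-negative", class = "blastocall_data_error")
  if (anyDuplicated(evidence[, c("sample_id", "locus_id", "allele")]))
    abort("(sample_id, locus_id, allele) rows must be unique",
          class = "blastocall_data_error")

  calls <- evidence |>
    dplyr::group_by(.data$sample_id, .data$locus_id) |>
    dplyr::summarise(
      total_depth = sum(.data$depth),
      alleles = list({
        keep <- .data$allele != "."
        a <- .data$allele[keep]
        d <- .data$depth[keep]
        thr <- max(min_allele_reads, min_allele_frac * sum(.data$depth))
        sup <- d >= thr
        a[sup][order(d[sup], decreasing = TRUE)]
      }),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_alleles = lengths(.data$alleles),
      status = dplyr::case_when(
        .data$total_depth < min_depth ~ "not_amplified",
        .data$n_alleles == 1L ~ "homozygous",
        .data$n_alleles == 2L ~ "heterozygous",
        TRUE ~ "multi_allelic"  # includes the degenerate 0-supported case
      ),
      alleles = purrr::map2(.data$alleles, .data$status,
                            ~ if (.y == "not_amplified") character() else .x),
      n_alleles = lengths(.data$alleles)
    ) |>
    dplyr::select("sample_id", "locus_id", "status", "alleles",
                  "n_alleles", "total_depth")
  calls
}

#' Genotype a single sample-locus group
#'
#' Single-group form of [call_genotypes()]; errors if the rows mix samples
#' or loci.
#'
#' @inheritParams call_genotypes
#' @param rows Evidence rows for exactly one sample and locus.
#' @return One-row call tibble (see [call_genotypes()]).
#' @export
call_locus_genotype <- function(rows, min_depth = 12, min_allele_frac = 0.1,
                                min_allele_reads = 3) {
  if (dplyr::n_distinct(rows$sample_id) > 1L ||
      dplyr::n_distinct(rows$locus_id) > 1L)
    abort("rows must come from a single sample and locus",
          class = "blastocall_data_error")
  call_genotypes(rows, min_depth = min_depth,
                 min_allele_frac = min_allele_frac,
                 min_allele_reads = min_allele_reads)
}

#' Filter annotated variant records (FreeBayes-style)
#'
#' Applies the high-confidence record filter
#' `QUAL > 1 & QUAL/AO > 10 & SAF > 0 & SAR > 0 & RPR > 1 & RPL > 1`
#' (quality, per-observation quality, alt support on both strands, and read
#' placement on both sides). Clauses are individually toggleable; the
#' reduced long-range amplicon filter corresponds to
#' `clauses = c("qual", "saf", "sar")`. A missing annotation is an error,
#' never a silent pass.
#'
#' @param records Tibble with numeric columns `qual, ao, saf, sar, rpr, rpl`
#'   (only the columns needed by the active clauses are required).
#' @param clauses Character subset of
#'   `c("qual", "qual_ao", "saf", "sar", "rpr", "rpl")`.
#' @return `records` with logical column `pass` and list-column
#'   `failed_clauses` appended.
#' @examples
#' recs <- tibble::tibble(qual = c(200, 50), ao = c(10, 10), saf = c(5, 5),
#'                        sar = c(5, 5), rpr = c(3, 3), rpl = c(3, 3))
#' filter_variant_records(recs)
#' @export
filter_variant_records <- function(records,
                                   clauses = c("qual", "qual_ao", "saf",
                                               "sar", "rpr", "rpl")) {
  clauses <- match.arg(clauses, c("qual", "qual_ao", "saf", "sar",
                                  "rpr", "rpl"), several.ok = TRUE)
  need <- unique(c(
    if ("qual" %in% clauses) "qual",
    if ("qual_ao" %in% clauses) c("qual", "ao"),
    if ("saf" %in% clauses) "saf",
    if ("sar" %in% clauses) "sar",
    if ("rpr" %in% clauses) "rpr",
    if ("rpl" %in% clauses) "rpl"
  ))
  missing_col <- setdiff(need, names(records))
  if (length(missing_col) > 0)
    abort(paste("missing annotation column(s):",
                paste(missing_col, collapse = ", ")),
          class = "blastocall_data_error")
  for (col in need) {
    if (any(is.na(records[[col]])))
      abort(sprintf("annotation `%s` has missing values; cannot filter", col),
            class = "blastocall_data_error")
  }
  tests <- list(
    qual = function(r) r$qual > 1,
    qual_ao = function(r) r$qual / r$ao > 10,
    saf = function(r) r$saf > 0,
    sar = function(r) r$sar > 0,
    rpr = function(r) r$rpr > 1,
    rpl = function(r) r$rpl > 1
  )
  res <- vapply(clauses, function(cl) tests[[cl]](records),
                logical(nrow(records)))
  res <- matrix(res, nrow = nrow(records),
                dimnames = list(NULL, clauses))
  records$pass <- apply(res, 1L, all)
  records$failed_clauses <- apply(res, 1L, function(x) clauses[!x],
                                  simplify = FALSE)
  records
}

#' Estimate a large deletion from amplicon lengths
#'
#' A secondary long-range PCR band smaller than the expected amplicon
#' indicates a deletion; the deletion size is the length difference when it
#' reaches `min_del` (the 100 bp boundary separating large deletions from
#' NHEJ indels), otherwise `NA`.
#'
#' @param expected_len,observed_len Amplicon lengths in bp (vectorised).
#' @param min_del Minimum length difference reported as a deletion.
#' @return Integer deletion sizes (`NA` where the difference is below
#'   `min_del`).
#' @examples
#' estimate_deletion_from_amplicon(3054, 1181)  # 1873
#' @export
estimate_deletion_from_amplicon <- function(expected_len, observed_len,
                                            min_del = 100) {
  if (any(observed_len < 0) || any(expected_len < 0))
    abort("amplicon lengths must be non-negative",
          class = "blastocall_data_error")
  if (any(observed_len > expected_len))
    abort("observed amplicon longer than expected: insertions are not supported by length-based screening",
          class = "blastocall_data_error")
  d <- as.integer(expected_len - observed_len)
  ifelse(d >= min_del, d, NA_integer_)
}
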