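ado_tbl <- function(scope, ids, n_hom, n_amp) {
  out <- tibble::tibble(
    scope = scope,
    scope_id = ids,
    n_homozygous = as.integer(n_hom),
    n_amplified = as.integer(n_amp),
    rate = ifelse(n_amp > 0, n_hom / n_amp, NA_real_),
    undefined = n_amp == 0
  )
  class(out) <- c("ado_estimate", class(out))
  out
}

amplified_statuses <- c("homozygous", "heterozygous", "multi_allelic")

restrict_to_panel <- function(calls, panel_loci) {
  dplyr::filter(calls, .data$locus_id %in% panel_loci)
}

#' Sample-specific allelic dropout rates
#'
#' For each sample, the ADO rate is the fraction of apparently homozygous
#' loci among the amplified heterozygous-expected panel loci; loci that did
#' not amplify (total depth below the calling threshold) are excluded from
#' both numerator and denominator. A sample with zero amplified panel loci
#' gets an undefined (flagged `NA`) rate rather than a silent zero.
#'
#' @param calls Genotype calls from [call_genotypes()].
#' @param panel_loci Character vector of heterozygous-expected locus ids
#'   (e.g. `ado_panel(cfg)$locus_id`).
#' @return An `ado_estimate` tibble: `scope, scope_id, n_homozygous,
#'   n_amplified, rate, undefined`.
#' @examples
#' ev <- tibble::tibble(sample_id = "c1",
#'                      locus_id = rep(c("L1", "L2"), each = 2),
#'                      allele = c("A", "G", "A", "A"),
#'                      depth = c(40L, 35L, 50L, 0L))
#' sample_ado_rate(call_genotypes(ev), c("L1", "L2"))
#' @export
sample_ado_rate <- function(calls, panel_loci) {
  x <- restrict_to_panel(calls, panel_loci) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_amp = sum(.data$status %in% amplified_statuses),
      n_hom = sum(.data$status == "homozygous"),
      .groups = "drop"
    )
  ado_tbl("sample", x$sample_id, x$n_hom, x$n_amp)
}

#' Locus-specific allelic dropout rates
#'
#' The per-locus mirror of [sample_ado_rate()]: for each panel locus, the
#' fraction of samples in which it was amplified but called homozygous.
#'
#' @inheritParams sample_ado_rate
#' @return An `ado_estimate` tibble with `scope = "locus"`.
#' @export
locus_ado_rate <- function(calls, panel_loci) {
  x <- restrict_to_panel(calls, panel_loci) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_amp = sum(.data$status %in% amplified_statuses),
      n_hom = sum(.data$status == "homozygous"),
      .groups = "drop"
    )
  ado_tbl("locus", x$locus_id, x$n_hom, x$n_amp)
}

#' Fraction of panel loci amplified per sample
#'
#' Amplified panel loci divided by the panel size (loci with no evidence at
#' all count as not amplified).
#'
#' @inheritParams sample_ado_rate
#' @return Tibble: `sample_id, n_amplified, panel_size, amplified_fraction`.
#' @export
amplified_fraction <- function(calls, panel_loci) {
  restrict_to_panel(calls, panel_loci) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_amplified = sum(.data$status %in% amplified_statuses),
      .groups = "drop"
    ) |>
    dplyr::mutate(panel_size = length(panel_loci),
                  amplified_fraction = .data$n_amplified / .data$panel_size)
}

#' ADO profile across pool sizes
#'
#' Summarises ADO for WGA samples pooled from `k` clonal cells. With
#' per-copy dropout `q`, the expected observed ADO among amplified loci is
#' `2 q^k / (1 + q^k)`, so estimates should be non-increasing in `k`; the
#' result records whether the pooled point estimates satisfy that.
#'
#' @param calls Genotype calls for the pooled samples.
#' @param panel_loci Heterozygous-expected panel locus ids.
#' @param pool_sizes Tibble `sample_id, k` giving each pool's cell count.
#' @return An `ado_estimate` tibble with `scope = "pool"`, one row per pool
#'   size (counts summed over pools of that size), extra columns `k` and
#'   `n_pools`, and attribute `non_increasing`.
#' @export
pooled_ado_profile <- function(calls, panel_loci, pool_sizes) {
  per_pool <- sample_ado_rate(calls, panel_loci) |>
    dplyr::left_join(pool_sizes, by = c(scope_id = "sample_id"))
  if (any(is.na(per_pool$k)))
    abort("every pooled sample needs a pool size in `pool_sizes`",
          class = "blastocall_data_error")
  x <- per_pool |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(
      n_pools = dplyr::n(),
      n_hom = sum(.data$n_homozygous),
      n_amp = sum(.data$n_amplified),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$k)
  out <- ado_tbl("pool", sprintf("k=%d", x$k), x$n_hom, x$n_amp)
  out$k <- x$k
  out$n_pools <- x$n_pools
  attr(out, "non_increasing") <-
    all(diff(out$rate[!is.na(out$rate)]) <= 0)
  out
}

#' Summarise ADO estimates for a cohort
#'
#' Unweighted mean, minimum and maximum of the defined rates, with the
#' number of undefined (zero-amplified) estimates excluded from the mean
#' reported alongside.
#'
#' @param estimates An `ado_estimate` tibble.
#' @return One-row tibble: `scope, n, n_undefined, mean_rate, min_rate,
#'   max_rate`.
#' @export
ado_summary <- function(estimates) {
  ok <- !estimates$undefined
  tibble::tibble(
    scope = unique(estimates$scope)[1],
    n = nrow(estimates),
    n_undefined = sum(!ok),
    mean_rate = mean(estimates$rate[ok]),
    min_rate = if (any(ok)) min(estimates$rate[ok]) else NA_real_,
    max_rate = if (any(ok)) max(estimates$rate[ok]) else NA_real_
  )
}
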