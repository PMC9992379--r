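#' Heterozygous ADO panel definition
#'
#' Builds the panel of heterozygous-expected loci used to measure allelic
#' dropout (608 loci spread across all 23 chromosomes in the study design).
#' Each locus carries two distinct alleles, one per homolog, so any call
#' showing a single allele after amplification is an apparent-homozygosity
#' (ADO) event.
#'
#' @param config A [sim_config()]; `n_panel_loci` and `seed` are used.
#' @return Tibble: `locus_id, chrom, pos, allele_a, allele_b`.
#' @export
ado_panel <- function(config) {
  validate_sim_config(config)
  n <- config$n_panel_loci
  if (n == 0L)
    return(tibble::tibble(locus_id = character(), chrom = character(),
                          pos = integer(), allele_a = character(),
                          allele_b = character()))
  set.seed(config$seed + 3L)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(bases, x), 1L), character(1),
              USE.NAMES = FALSE)
  tibble::tibble(
    locus_id = sprintf("panel_%04d", seq_len(n)),
    chrom = paste0("chr", c(1:22, "X"))[1L + (seq_len(n) - 1L) %% 23L],
    pos = as.integer(1e6 + seq_len(n) * 1000L),
    allele_a = a,
    allele_b = b
  )
}

## core WGA model over a long table of (sample, locus, copy_m, copy_p):
## 1. per (sample, locus): blanket failure with prob f_locus_fail
## 2. per template copy: independent amplification failure (prob given)
## 3. per surviving copy: depth ~ NB(mu = depth_mean / 2, size = dispersion)
## loci where nothing amplifies are emitted as a single allele "." row with
## depth 0 -- indistinguishable from blanket failure, as in real data
wga_amplify <- function(copies, config, p_copy_fail) {
  n <- nrow(copies)
  locus_fail <- runif(n) < config$f_locus_fail
  drop1 <- runif(n) < p_copy_fail
  drop2 <- runif(n) < p_copy_fail
  mu <- config$depth_mean / 2
  d1 <- rnbinom(n, size = config$depth_dispersion, mu = mu)
  d2 <- rnbinom(n, size = config$depth_dispersion, mu = mu)
  s1 <- !locus_fail & !drop1
  s2 <- !locus_fail & !drop2

  long <- dplyr::bind_rows(
    copies[s1, ] |> dplyr::mutate(allele = .data$copy_m, depth = d1[s1]),
    copies[s2, ] |> dplyr::mutate(allele = .data$copy_p, depth = d2[s2])
  ) |>
    dplyr::group_by(.data$sample_id, .data$locus_id, .data$chrom, .data$pos,
                    .data$allele) |>
    dplyr::summarise(depth = sum(.data$depth), .groups = "drop")

  dead <- copies[!(s1 | s2), ] |>
    dplyr::mutate(allele = ".", depth = 0L) |>
    dplyr::select("sample_id", "locus_id", "chrom", "pos", "allele", "depth")

  evidence <- dplyr::bind_rows(long, dead) |>
    dplyr::arrange(.data$sample_id, .data$locus_id, .data$allele) |>
    dplyr::mutate(depth = as.integer(.data$depth))

  dropouts <- dplyr::bind_rows(
    copies[!locus_fail & drop1, ] |> dplyr::mutate(allele = .data$copy_m),
    copies[!locus_fail & drop2, ] |> dplyr::mutate(allele = .data$copy_p)
  ) |> dplyr::select("sample_id", "locus_id", "allele")
  failed <- copies[locus_fail, ] |> dplyr::select("sample_id", "locus_id")

  attr(evidence, "dropouts") <- dropouts
  attr(evidence, "failed_loci") <- failed
  evidence
}

cell_copy_table <- function(truth, haplotypes, config,
                            include_panel = TRUE, include_target = TRUE) {
  parts <- list()
  if (include_target) {
    parts$target <- true_locus_copies(truth, haplotypes) |>
      dplyr::rename(sample_id = "cell_id")
  }
  if (include_panel && config$n_panel_loci > 0L) {
    panel <- ado_panel(config)
    parts$panel <- tidyr::crossing(
      tibble::tibble(sample_id = truth$cell_id), panel
    ) |>
      dplyr::mutate(offset_bp = NA_integer_,
                    copy_m = .data$allele_a, copy_p = .data$allele_b) |>
      dplyr::select("sample_id", "locus_id", "chrom", "pos", "offset_bp",
                    "copy_m", "copy_p")
  }
  dplyr::bind_rows(parts)
}

#' Simulate single-cell WGA allele-depth evidence
#'
#' Applies the whole-genome-amplification artifact model to the true allele
#' copies of each simulated cell: every locus fails entirely with
#' probability `f_locus_fail`; otherwise each of the two template copies
#' amplifies independently, failing with probability `q_copy_fail`
#' (allelic dropout); surviving copies receive negative-binomial read
#' depths. Covers the ADO panel loci, the flanking variants and the target
#' site. One call consumes one RNG stream seeded from the configuration,
#' so passing the whole cohort at once gives reproducible per-cell draws.
#'
#' @param truth `sim_truth` tibble (one or more cells).
#' @param haplotypes Matching [simulate_trio_haplotypes()] result.
#' @param config A [sim_config()].
#' @param include_panel,include_target Restrict the simulated loci.
#' @return An allele-evidence tibble `sample_id, locus_id, chrom, pos,
#'   allele, depth` (allele `"."` with depth 0 marks a locus where nothing
#'   amplified). Attributes `dropouts` and `failed_loci` log the true
#'   artifact events for recovery tests.
#' @examples
#' cfg <- sim_config(n_embryos = 1, n_panel_loci = 20, seed = 3)
#' hp <- simulate_trio_haplotypes(cfg, n_flank_variants = 4)
#' tr <- simulate_embryo_cohort(cfg, hp)
#' simulate_wga_evidence(tr[1, ], hp, cfg)
#' @export
simulate_wga_evidence <- function(truth, haplotypes, config,
                                  include_panel = TRUE,
                                  include_target = TRUE) {
  validate_sim_config(config)
  if (nrow(truth) == 0)
    abort("truth must contain at least one cell", class = "blastocall_data_error")
  set.seed(config$seed + 2L)
  copies <- cell_copy_table(truth, haplotypes, config,
                            include_panel, include_target)
  wga_amplify(copies, config, p_copy_fail = config$q_copy_fail)
}

#' Simulate WGA evidence for DNA pooled from k clonal cells
#'
#' In a pool of `k` genetically identical cells each allele is represented
#' by `k` template copies, so an allele drops out only when all `k` copies
#' fail: per-allele dropout probability `q_copy_fail^k`. Otherwise the
#' model matches [simulate_wga_evidence()]. This mirrors pooling DNA from
#' 2, 3 or 6 clonal fibroblasts before amplification.
#'
#' @param truths `sim_truth` rows for the pooled cells (must be clonal:
#'   identical resolved alleles).
#' @param haplotypes,config As in [simulate_wga_evidence()].
#' @param pool_id Sample identifier for the pooled evidence rows.
#' @return Allele-evidence tibble as in [simulate_wga_evidence()].
#' @export
simulate_pooled_evidence <- function(truths, haplotypes, config,
                                     pool_id = "pool") {
  validate_sim_config(config)
  k <- nrow(truths)
  if (k == 0)
    abort("pool must contain at least one cell", class = "blastocall_data_error")
  if (dplyr::n_distinct(truths$allele_m) != 1L ||
      dplyr::n_distinct(truths$allele_p) != 1L)
    abort("pooled cells must be clonal (identical resolved alleles)",
          class = "blastocall_data_error")
  set.seed(config$seed + 2L)
  copies <- cell_copy_table(truths[1L, ], haplotypes, config) |>
    dplyr::mutate(sample_id = pool_id)
  wga_amplify(copies, config, p_copy_fail = config$q_copy_fail^k)
}
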