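#' Simulation configuration for mosaic edited embryos and WGA artifacts
#'
#' Bundles every knob of the generative model: cohort shape, per-allele DSB
#' repair outcome probabilities, size distributions for NHEJ indels
#' (< 100 bp), large deletions (>= 100 bp) and gene-conversion tracts,
#' the whole-genome-amplification (WGA) artifact model (per-template-copy
#' dropout and per-locus blanket failure), the amplicon read-depth model,
#' and the heterozygous-locus ADO panel size.
#'
#' Defaults encode the study conditions this package targets: 4-8 cell
#' embryos, a 608-locus heterozygous panel, mean amplicon coverage 143x,
#' a per-copy dropout probability `q_copy_fail = 0.1534` chosen so the
#' expected observed ADO among amplified heterozygous loci,
#' `2q/(1+q)`, equals 26.6% (the blastomere average), and a blanket locus
#' failure rate such that on average 84.8% of panel loci amplify.
#'
#' @param n_embryos Number of embryos to simulate.
#' @param cells_per_embryo Integer vector of admissible blastomere counts;
#'   each embryo draws its cell number uniformly from this set (default 4:8).
#' @param p_zygote_edit Probability that both-allele repair resolves before
#'   the first cleavage, so all sister blastomeres share one genotype
#'   (uniform, non-mosaic embryo).
#' @param p_intact,p_indel,p_large_del,p_hdr,p_conversion Per-allele repair
#'   outcome probabilities; must sum to 1.
#' @param indel_size_dist Function `n -> integer(n)` of signed NHEJ indel
#'   sizes with `1 <= |size| <= 99` (negative = deletion).
#' @param del_size_dist Function `n -> integer(n)` of large-deletion sizes,
#'   `100 <= size <= 10000`.
#' @param tract_length_dist Function `n -> numeric(n)` of one-sided
#'   gene-conversion tract extents in bp (the tract always covers the cut
#'   site; left and right extents are drawn independently).
#' @param q_copy_fail Per-template-copy amplification failure probability.
#' @param f_locus_fail Per-locus blanket amplification failure probability.
#' @param depth_mean Mean total read depth of a fully amplified locus
#'   (each surviving allele copy contributes `depth_mean / 2` on average).
#' @param depth_dispersion Negative-binomial size parameter of per-copy depth.
#' @param n_panel_loci Number of heterozygous-expected panel loci per cell.
#' @param maternal_target,paternal_target Target-site state of each
#'   transmitted allele, `"WT"` or `"Mut"`.
#' @param p_paternal_mut For a heterozygous sperm donor, probability that an
#'   embryo inherits the mutant paternal allele; `NA` (default) keeps
#'   `paternal_target` fixed.
#' @param allele_specific If `TRUE`, only `"Mut"` alleles can be cleaved
#'   (an allele-specific sgRNA); `"WT"` alleles always stay intact.
#' @param n_markers Number of synonymous ssODN marker substitutions carried
#'   by an HDR allele (4, 2 and 3 for the three loci studied).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#'
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(n_embryos = 2, seed = 1)
#' cfg$q_copy_fail
#' @export
sim_config <- function(n_embryos = 12,
                       cells_per_embryo = 4:8,
                       p_zygote_edit = 0.125,
                       p_intact = 0.15,
                       p_indel = 0.55,
                       p_large_del = 0.05,
                       p_hdr = 0.05,
                       p_conversion = 0.20,
                       indel_size_dist = default_indel_sizes,
                       del_size_dist = default_del_sizes,
                       tract_length_dist = default_tract_extents,
                       q_copy_fail = 0.1534,
                       f_locus_fail = 0.1316,
                       depth_mean = 143,
                       depth_dispersion = 10,
                       n_panel_loci = 608,
                       maternal_target = "WT",
                       paternal_target = "WT",
                       p_paternal_mut = NA_real_,
                       allele_specific = FALSE,
                       n_markers = 4,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_embryos = as.integer(n_embryos),
      cells_per_embryo = as.integer(cells_per_embryo),
      p_zygote_edit = p_zygote_edit,
      p_intact = p_intact, p_indel = p_indel, p_large_del = p_large_del,
      p_hdr = p_hdr, p_conversion = p_conversion,
      indel_size_dist = indel_size_dist,
      del_size_dist = del_size_dist,
      tract_length_dist = tract_length_dist,
      q_copy_fail = q_copy_fail,
      f_locus_fail = f_locus_fail,
      depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      n_panel_loci = as.integer(n_panel_loci),
      maternal_target = maternal_target,
      paternal_target = paternal_target,
      p_paternal_mut = p_paternal_mut,
      allele_specific = allele_specific,
      n_markers = as.integer(n_markers),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  embryos: %d (%s cells each), p_zygote_edit = %.3g\n",
              x$n_embryos, paste(range(x$cells_per_embryo), collapse = "-"),
              x$p_zygote_edit))
  cat(sprintf("  outcomes: intact %.3g, indel %.3g, large_del %.3g, hdr %.3g, conversion %.3g\n",
              x$p_intact, x$p_indel, x$p_large_del, x$p_hdr, x$p_conversion))
  cat(sprintf("  WGA: q_copy_fail %.4g, f_locus_fail %.4g; depth NB(mean %g, size %g)\n",
              x$q_copy_fail, x$f_locus_fail, x$depth_mean, x$depth_dispersion))
  cat(sprintf("  panel: %d het loci; seed %d\n", x$n_panel_loci, x$seed))
  invisible(x)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    abort(sprintf("invalid sim_config: field `%s` %s", field, why),
          class = "blastocall_config_error")
  }
  probs <- c(p_zygote_edit = cfg$p_zygote_edit, p_intact = cfg$p_intact,
             p_indel = cfg$p_indel, p_large_del = cfg$p_large_del,
             p_hdr = cfg$p_hdr, p_conversion = cfg$p_conversion,
             q_copy_fail = cfg$q_copy_fail, f_locus_fail = cfg$f_locus_fail)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      bad(nm, "must be a probability in [0, 1]")
  }
  s <- cfg$p_intact + cfg$p_indel + cfg$p_large_del + cfg$p_hdr + cfg$p_conversion
  if (abs(s - 1) > 1e-9)
    bad("p_intact..p_conversion", sprintf("outcome probabilities must sum to 1 (got %.12g)", s))
  if (cfg$n_embryos < 1) bad("n_embryos", "must be >= 1")
  if (length(cfg$cells_per_embryo) < 1 || any(cfg$cells_per_embryo < 1))
    bad("cells_per_embryo", "must be positive counts")
  if (cfg$n_panel_loci < 0) bad("n_panel_loci", "must be >= 0")
  if (!is.function(cfg$indel_size_dist)) bad("indel_size_dist", "must be a function(n)")
  if (!is.function(cfg$del_size_dist)) bad("del_size_dist", "must be a function(n)")
  if (!is.function(cfg$tract_length_dist)) bad("tract_length_dist", "must be a function(n)")
  sz <- cfg$indel_size_dist(200L)
  if (any(abs(sz) < 1 | abs(sz) >= 100))
    bad("indel_size_dist", "must return signed sizes with 1 <= |size| < 100")
  dz <- cfg$del_size_dist(200L)
  if (any(dz < 100 | dz > 10000))
    bad("del_size_dist", "must return sizes in [100, 10000]")
  if (cfg$depth_mean <= 0) bad("depth_mean", "must be > 0")
  if (cfg$depth_dispersion <= 0) bad("depth_dispersion", "must be > 0")
  if (!cfg$maternal_target %in% c("WT", "Mut")) bad("maternal_target", "must be \"WT\" or \"Mut\"")
  if (!cfg$paternal_target %in% c("WT", "Mut")) bad("paternal_target", "must be \"WT\" or \"Mut\"")
  if (!is.na(cfg$p_paternal_mut) &&
      (cfg$p_paternal_mut < 0 || cfg$p_paternal_mut > 1))
    bad("p_paternal_mut", "must be NA or a probability in [0, 1]")
  if (cfg$n_markers < 1) bad("n_markers", "must be >= 1")
  if (is.na(cfg$seed)) bad("seed", "must be an integer")
  cfg
}

#' Default repair-product size distributions
#'
#' `default_indel_sizes()` draws signed NHEJ indel sizes: 85% deletions,
#' 15% insertions, magnitudes geometric (p = 0.3, shifted to start at 1)
#' truncated at 99 bp, so most events are 1-10 bp as seen in amplicon data.
#' `default_del_sizes()` draws large-deletion sizes log-uniform over
#' 100-10000 bp (the observed range spans ~100 bp to 3.8 kb, with 824 and
#' 1873 bp examples validated in stem-cell lines).
#' `default_tract_extents()` draws one-sided conversion-tract extents,
#' exponential with mean 4 kb truncated at 20 kb, reflecting homozygosity
#' tracts of up to ~20 kb.
#'
#' @param n Number of draws.
#' @return Integer (sizes) or numeric (extents) vector of length `n`.
#' @name size-distributions
NULL

#' @rdname size-distributions
#' @export
default_indel_sizes <- function(n) {
  mag <- pmin(1L + stats::rgeom(n, prob = 0.3), 99L)
  sgn <- ifelse(runif(n) < 0.85, -1L, 1L)
  as.integer(sgn * mag)
}

#' @rdname size-distributions
#' @export
default_del_sizes <- function(n) {
  as.integer(round(exp(runif(n, log(100), log(10000)))))
}

#' @rdname size-distributions
#' @export
default_tract_extents <- function(n) {
  pmin(stats::rexp(n, rate = 1 / 4000), 20000)
}
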