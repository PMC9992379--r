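#' Canned simulation scenarios
#'
#' Presets reproducing the study designs the package targets, scaled for
#' in-memory use:
#'
#' * `mybpc3_biallelic` — both wild-type alleles cleaved; ssODN with 4
#'   synonymous markers; full outcome mix including HDR and conversion.
#' * `ldlrap1_biallelic` — heterozygous background (homozygous-mutant
#'   sperm donor, so every embryo is WT/Mut); ssODN with 2 markers but no
#'   HDR observed; both alleles cleavable.
#' * `myh7_monoallelic` — allele-specific sgRNA cleaving only the mutant
#'   paternal allele; heterozygous sperm donor (each embryo draws Mut or
#'   WT sperm with probability 1/2); 3 markers, no HDR observed.
#' * `ado_panel` — no editing; the 608-locus heterozygous dropout panel
#'   measured on 18 blastomere-like and 33 fibroblast-like single cells,
#'   with per-copy dropout set so the expected observed ADO is 26.6% and
#'   37.2% respectively and ~84.8% of loci amplify.
#'
#' Cohort sizes are scaled down from the study's hundreds of blastomeres;
#' cohort-level expectations are therefore distributional, not exact
#' counts.
#'
#' @param name Preset name.
#' @return A `scenario_preset` list: `name`, `config` (a [sim_config()]),
#'   `n_flank_variants`, `allele_specific`, and for `ado_panel` also
#'   `fibroblast_config` plus the sample counts.
#' @examples
#' load_preset("mybpc3_biallelic")$config
#' @export
load_preset <- function(name) {
  presets <- c("mybpc3_biallelic", "ldlrap1_biallelic",
               "myh7_monoallelic", "ado_panel")
  if (!name %in% presets)
    abort(paste0("unknown preset \"", name, "\"; available: ",
                 paste(presets, collapse = ", ")),
          class = "blastocall_config_error")
  p <- switch(
    name,
    mybpc3_biallelic = list(
      config = sim_config(
        n_embryos = 16, cells_per_embryo = 4:8, p_zygote_edit = 0.125,
        p_intact = 0.15, p_indel = 0.55, p_large_del = 0.05,
        p_hdr = 0.05, p_conversion = 0.20,
        n_markers = 4, n_panel_loci = 0, seed = 101L),
      n_flank_variants = 27, allele_specific = FALSE),
    ldlrap1_biallelic = list(
      config = sim_config(
        n_embryos = 16, cells_per_embryo = 4:8, p_zygote_edit = 0.125,
        p_intact = 0.45, p_indel = 0.30, p_large_del = 0.02,
        p_hdr = 0, p_conversion = 0.23,
        maternal_target = "WT", paternal_target = "Mut",
        n_markers = 2, n_panel_loci = 0, seed = 102L),
      n_flank_variants = 27, allele_specific = FALSE),
    myh7_monoallelic = list(
      config = sim_config(
        n_embryos = 16, cells_per_embryo = 4:8, p_zygote_edit = 0.125,
        p_intact = 0.12, p_indel = 0.55, p_large_del = 0.03,
        p_hdr = 0, p_conversion = 0.30,
        maternal_target = "WT", paternal_target = "Mut",
        p_paternal_mut = 0.5, allele_specific = TRUE,
        n_markers = 3, n_panel_loci = 0, seed = 103L),
      n_flank_variants = 27, allele_specific = TRUE),
    ado_panel = list(
      config = sim_config(            # blastomere-like single cells
        n_embryos = 18, cells_per_embryo = 1, p_zygote_edit = 0,
        p_intact = 1, p_indel = 0, p_large_del = 0, p_hdr = 0,
        p_conversion = 0,
        # q from a = 2q/(1+q) = 0.266; f from (1-f)(1-q^2) = 0.848
        q_copy_fail = 0.1534, f_locus_fail = 0.1316,
        n_panel_loci = 608, seed = 104L),
      fibroblast_config = sim_config( # G1-arrested fibroblast-like cells
        n_embryos = 33, cells_per_embryo = 1, p_zygote_edit = 0,
        p_intact = 1, p_indel = 0, p_large_del = 0, p_hdr = 0,
        p_conversion = 0,
        # q from a = 2q/(1+q) = 0.372; f from (1-f)(1-q^2) = 0.848 so both
        # cohorts amplify the same expected fraction of panel loci
        q_copy_fail = 0.2285, f_locus_fail = 0.1053,
        n_panel_loci = 608, seed = 105L),
      n_blastomeres = 18, n_fibroblasts = 33,
      n_flank_variants = 4, allele_specific = FALSE)
  )
  structure(c(list(name = name), p), class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("<scenario_preset> %s (allele-specific: %s)\n", x$name,
              x$allele_specific))
  print(x$config)
  invisible(x)
}

#' Generate a fixture bundle for a scenario preset
#'
#' Runs the full simulation for a preset and writes truth, evidence and
#' panel TSVs plus a checksum manifest, so any example can run end-to-end
#' without external data. Fixed seeds give identical checksums run to run.
#'
#' @param preset A [load_preset()] result or preset name.
#' @param out_dir Writable output directory.
#' @return Invisibly, the manifest list (see [render_report()]).
#' @export
generate_fixture_bundle <- function(preset, out_dir) {
  if (is.character(preset)) preset <- load_preset(preset)
  stopifnot(inherits(preset, "scenario_preset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  run_one <- function(config, prefix) {
    hp <- simulate_trio_haplotypes(config, preset$n_flank_variants)
    truth <- simulate_embryo_cohort(config, hp)
    truth$cell_id <- paste0(prefix, truth$cell_id)
    ev <- simulate_wga_evidence(truth, hp, config)
    list(hp = hp, truth = truth, evidence = ev)
  }
  if (preset$name == "ado_panel") {
    b <- run_one(preset$config, "b_")
    f <- run_one(preset$fibroblast_config, "f_")
    truth <- dplyr::bind_rows(b$truth, f$truth)
    evidence <- dplyr::bind_rows(b$evidence, f$evidence)
    hp <- b$hp
    panel <- ado_panel(preset$config)
    readr::write_tsv(panel, file.path(out_dir, "ado_panel.tsv"))
  } else {
    r <- run_one(preset$config, "")
    truth <- r$truth; evidence <- r$evidence; hp <- r$hp
  }
  write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
  write_evidence_tsv(evidence, file.path(out_dir, "evidence.tsv"))
  write_panel_tsv(hp, file.path(out_dir, "flank_panel.tsv"))

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "blastocall",
    preset = preset$name,
    seed = preset$config$seed,
    checksums = as.list(tools::md5sum(sort(files)) |>
                          setNames(basename(sort(files))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
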