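#' Render a run report from pipeline outputs
#'
#' Writes every tabular result to TSV, a human-readable markdown summary,
#' and a machine-readable `manifest.json` recording the seed, the scalar
#' configuration values, the package version and an MD5 checksum per file.
#' Output is deterministic: fixed inputs give byte-identical files, so a
#' report can be regenerated and diffed against its manifest.
#'
#' @param results Named list of tibbles/data frames (e.g. cell labels,
#'   embryo mosaicism table, category tables, ADO estimates, tract calls).
#' @param out_dir Output directory (created if missing).
#' @param config Optional [sim_config()] whose scalar fields go into the
#'   manifest.
#' @param seed Optional seed to record.
#' @return Invisibly, the manifest as a list.
#' @export
render_report <- function(results, out_dir, config = NULL, seed = NULL) {
  if (length(results) == 0 || is.null(names(results)) ||
      any(names(results) == ""))
    abort("results must be a non-empty named list",
          class = "blastocall_data_error")
  ok <- vapply(results, is.data.frame, logical(1))
  if (!all(ok))
    abort(paste("results must be data frames; offending:",
                paste(names(results)[!ok], collapse = ", ")),
          class = "blastocall_data_error")
  if (any(vapply(results, nrow, integer(1)) == 0))
    abort("empty result table: refusing to render an empty report",
          class = "blastocall_data_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  flatten_lists <- function(df) {
    for (col in names(df)) {
      if (is.list(df[[col]]))
        df[[col]] <- purrr::map_chr(df[[col]], paste, collapse = ",")
    }
    df
  }
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(flatten_lists(results[[nm]]), f)
    files <- c(files, f)
  }

  md <- c("# Run report", "")
  for (nm in names(results)) {
    df <- flatten_lists(results[[nm]])
    md <- c(md, paste0("## ", nm), "",
            paste0("| ", paste(names(df), collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"))
    for (i in seq_len(min(nrow(df), 50L))) {
      row <- vapply(df[i, ], function(x)
        if (is.numeric(x)) format(x, digits = 6) else as.character(x),
        character(1))
      md <- c(md, paste0("| ", paste(row, collapse = " | "), " |"))
    }
    if (nrow(df) > 50L)
      md <- c(md, paste0("(", nrow(df) - 50L, " further rows in ", nm,
                         ".tsv)"))
    md <- c(md, "")
  }
  md_file <- file.path(out_dir, "report.md")
  writeLines(md, md_file)
  files <- c(files, md_file)

  cfg_scalars <- NULL
  if (!is.null(config)) {
    keep <- vapply(config, function(x)
      is.numeric(x) || is.character(x) || is.logical(x), logical(1))
    cfg_scalars <- lapply(unclass(config)[keep], function(x)
      if (length(x) > 1) paste(x, collapse = ",") else x)
  }
  manifest <- list(
    package = "blastocall",
    version = as.character(utils::packageVersion("blastocall")),
    seed = seed,
    config = cfg_scalars,
    tables = lapply(results, function(df)
      list(rows = nrow(df), cols = ncol(df))),
    checksums = as.list(tools::md5sum(sort(files)) |>
                          setNames(basename(sort(files))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Verify report or fixture files against their manifest
#'
#' Recomputes MD5 checksums for every file listed in `manifest.json` and
#' compares; a missing or altered file fails the check.
#'
#' @param dir Directory containing `manifest.json`.
#' @return `TRUE` invisibly if all checksums match.
#' @export
verify_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    abort("manifest.json not found", class = "blastocall_data_error")
  manifest <- jsonlite::read_json(mf)
  for (fname in names(manifest$checksums)) {
    f <- file.path(dir, fname)
    if (!file.exists(f))
      abort(sprintf("manifest check failed: %s missing", fname),
            class = "blastocall_data_error")
    sum_now <- unname(tools::md5sum(f))
    if (!identical(sum_now, manifest$checksums[[fname]]))
      abort(sprintf("manifest check failed: %s checksum mismatch", fname),
            class = "blastocall_data_error")
  }
  invisible(TRUE)
}
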