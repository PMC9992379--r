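#' Plot a genotype frequency table
#'
#' Bar chart of label frequencies per cohort, the summary view of
#' on-target genotype composition.
#'
#' @param object A `category_table` (or several row-bound tables).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.category_table <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$n),
    y = .data$pct, fill = .data$cohort_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of cells", fill = NULL,
                  title = "On-target genotype frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the distribution of ADO estimates
#'
#' Box-and-jitter view of per-sample or per-locus allelic dropout rates,
#' the standard display for WGA artifact burden.
#'
#' @param object An `ado_estimate` tibble (row-bind several to compare
#'   scopes or cohorts; add a `group` column to facet the comparison).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ado_estimate <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object)) |>
    dplyr::filter(!.data$undefined)
  grp <- if ("group" %in% names(df)) "group" else "scope"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[grp]], y = .data$rate)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "allelic dropout rate",
                  title = "Allelic dropout distribution") +
    ggplot2::theme_minimal()
}

#' Plot inferred conversion tract bounds per cell
#'
#' One horizontal segment per cell/clone: the thick segment spans the
#' minimum tract (outermost converted variants), the thin line the maximum
#' (innermost heterozygous flanks), coloured by template parent — the
#' display used to compare tract extents across clones.
#'
#' @param tracts Result of [infer_tracts()].
#' @return A ggplot object.
#' @export
plot_tract_bounds <- function(tracts) {
  df <- dplyr::filter(tracts, .data$has_loh)
  seg_l <- -(df$min_tract_bp - 1) / 2
  seg_r <- (df$min_tract_bp - 1) / 2
  max_l <- -(df$max_tract_bp - 1) / 2
  max_r <- (df$max_tract_bp - 1) / 2
  df2 <- dplyr::mutate(df, seg_l = seg_l, seg_r = seg_r,
                       max_l = max_l, max_r = max_r)
  ggplot2::ggplot(df2, ggplot2::aes(y = .data$cell_id,
                                    colour = .data$template_parent)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$max_l,
                                       xend = .data$max_r,
                                       yend = .data$cell_id),
                          linewidth = 0.4, alpha = 0.5) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$seg_l,
                                       xend = .data$seg_r,
                                       yend = .data$cell_id),
                          linewidth = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "bp (tract length, centred for display)", y = NULL,
                  colour = "template",
                  title = "Gene-conversion tract bounds") +
    ggplot2::theme_minimal()
}
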