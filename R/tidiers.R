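#' Tidy and glance methods for blastocall results
#'
#' broom-style accessors: `tidy()` returns the per-unit table, `glance()`
#' a one-row summary.
#'
#' @param x A `loh_comparison`, `category_table` or `ado_estimate` object.
#' @param ... Unused.
#' @return A tibble.
#' @name blastocall-tidiers
NULL

#' @rdname blastocall-tidiers
#' @export
tidy.loh_comparison <- function(x, ...) {
  tibble::tibble(
    cohort = c(x$cohort_a, x$cohort_b),
    loh = c(x$loh_a, x$loh_b),
    total = c(x$n_a, x$n_b),
    rate = c(x$rate_a, x$rate_b)
  )
}

#' @rdname blastocall-tidiers
#' @export
glance.loh_comparison <- function(x, ...) {
  tibble::tibble(
    rate_a = x$rate_a, rate_b = x$rate_b,
    direction = x$direction, p_value = x$p_value,
    degenerate = isTRUE(x$degenerate)
  )
}

#' @rdname blastocall-tidiers
#' @export
tidy.category_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname blastocall-tidiers
#' @export
glance.category_table <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$cohort_id[1],
    total = attr(x, "total") %||% sum(x$n),
    n_labels = nrow(x),
    homozygosity = homozygosity_fraction(x)
  )
}

#' @rdname blastocall-tidiers
#' @export
tidy.ado_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname blastocall-tidiers
#' @export
glance.ado_estimate <- function(x, ...) {
  ado_summary(x)
}
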