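#' The closed set of cell genotype labels
#'
#' All labels [label_cell_genotype()] can produce: `homo-<cat>` for the
#' five allele categories, every compound pair of distinct categories in
#' canonical order, plus `Indel/Indel` and `Del/Del` (the only categories
#' in which two distinct alleles can share a category).
#'
#' @return Character vector of valid labels.
#' @export
genotype_label_set <- function() {
  cats <- names(category_order)
  pairs <- utils::combn(cats, 2L, FUN = function(x)
    paste(x[order(category_order[x])], collapse = "/"))
  c(paste0("homo-", cats), pairs, "Indel/Indel", "Del/Del")
}

#' Tabulate on-target genotype frequencies
#'
#' Counts cells per genotype label and derives percentages (stored exactly;
#' printed to one decimal).
#'
#' @param cell_labels Tibble with a `label` column (e.g. from
#'   [classify_cells()]); unlabelled (`NA`) cells are dropped with a
#'   message.
#' @param cohort_id Name attached to the table.
#' @return A `category_table` tibble: `cohort_id, label, n, pct`, with
#'   attribute `total`.
#' @examples
#' cells <- tibble::tibble(label = c("homo-Indel", "homo-Indel", "WT/Indel"))
#' tabulate_genotype_frequencies(cells)
#' @export
tabulate_genotype_frequencies <- function(cell_labels, cohort_id = "cohort") {
  if (nrow(cell_labels) == 0)
    abort("empty cohort: nothing to tabulate", class = "blastocall_data_error")
  labs <- cell_labels$label
  if (anyNA(labs)) {
    message(sum(is.na(labs)), " unlabelled cell(s) dropped from the table")
    labs <- labs[!is.na(labs)]
  }
  if (length(labs) == 0)
    abort("empty cohort: nothing to tabulate", class = "blastocall_data_error")
  unknown <- setdiff(unique(labs), genotype_label_set())
  if (length(unknown) > 0)
    warning("labels outside the closed label set: ",
            paste(unknown, collapse = ", "))
  counts <- table(labs)
  out <- tibble::tibble(
    cohort_id = cohort_id,
    label = names(counts),
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / length(labs)
  ) |>
    dplyr::arrange(dplyr::desc(.data$n))
  attr(out, "total") <- length(labs)
  class(out) <- c("category_table", class(out))
  out
}

#' Fraction of cells with a homozygous (LOH) genotype
#'
#' Sum of `homo-*` label counts over the table total: the overall
#' homozygosity a cohort displays at the target locus, mixing true LOH
#' (conversion, deletion of one allele) with WGA allelic dropout.
#'
#' @param category_table A [tabulate_genotype_frequencies()] result.
#' @return Fraction in `[0, 1]`.
#' @export
homozygosity_fraction <- function(category_table) {
  total <- attr(category_table, "total")
  if (is.null(total)) total <- sum(category_table$n)
  sum(category_table$n[startsWith(category_table$label, "homo-")]) / total
}

#' One-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability with all margins fixed, computed
#' by log-factorial (log-binomial) accumulation. `alternative = "greater"`
#' tests enrichment of the first row in the first column (odds ratio > 1).
#' A table with a zero margin carries no information: the p-value is 1 and
#' the result is flagged degenerate.
#'
#' @param x 2x2 integer matrix (rows = cohorts, columns = outcome yes/no),
#'   or the count `a` with `b, c, d` supplied.
#' @param b,c,d Optional scalar counts completing the table.
#' @param alternative `"greater"` (first row enriched) or `"less"`.
#' @return The p-value, with attribute `degenerate`.
#' @examples
#' fisher_exact_one_tailed(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))  # 1/6
#' @export
fisher_exact_one_tailed <- function(x, b = NULL, c = NULL, d = NULL,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("contingency table entries must be non-negative integers",
          class = "blastocall_data_error")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  xs <- if (alternative == "greater") {
    seq.int(a, min(r1, c1))
  } else {
    seq.int(max(0L, c1 - r2), a)
  }
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  m <- max(lp)
  p <- min(1, exp(m) * sum(exp(lp - m)))
  attr(p, "degenerate") <- FALSE
  p
}

#' Compare LOH rates between two cohorts
#'
#' Builds the 2x2 LOH vs non-LOH table from two genotype frequency tables
#' and applies the one-tailed Fisher exact test. Which labels count as LOH
#' is configurable per locus (e.g. `"homo-Indel"` alone where LOH means
#' homozygous indel genotypes, `"homo-WT"` where it means loss of the
#' mutant allele); the default is every `homo-*` label. The direction must
#' be stated by the caller: `"a_higher"` tests for higher LOH in the first
#' cohort.
#'
#' @param table_a,table_b `category_table` objects
#'   (see [tabulate_genotype_frequencies()]).
#' @param loh_labels Labels counted as LOH; `NULL` means all `homo-*`.
#' @param direction `"a_higher"` or `"b_higher"`.
#' @return A `loh_comparison` object (list with cohort ids, counts, rates,
#'   `p_value`, `degenerate`); see [tidy.loh_comparison()].
#' @export
compare_loh_rates <- function(table_a, table_b, loh_labels = NULL,
                              direction = c("a_higher", "b_higher")) {
  direction <- match.arg(direction)
  count_loh <- function(tab) {
    labs <- if (is.null(loh_labels))
      tab$label[startsWith(tab$label, "homo-")] else loh_labels
    sum(tab$n[tab$label %in% labs])
  }
  n_a <- attr(table_a, "total") %||% sum(table_a$n)
  n_b <- attr(table_b, "total") %||% sum(table_b$n)
  loh_a <- count_loh(table_a)
  loh_b <- count_loh(table_b)
  m <- matrix(c(loh_a, n_a - loh_a, loh_b, n_b - loh_b), 2L, byrow = TRUE)
  if (direction == "b_higher") m <- m[2:1, ]
  p <- fisher_exact_one_tailed(m)
  structure(
    list(
      cohort_a = table_a$cohort_id[1], cohort_b = table_b$cohort_id[1],
      loh_a = loh_a, n_a = n_a, loh_b = loh_b, n_b = n_b,
      rate_a = loh_a / n_a, rate_b = loh_b / n_b,
      direction = direction,
      p_value = as.numeric(p),
      degenerate = attr(p, "degenerate")
    ),
    class = "loh_comparison"
  )
}

#' @export
print.loh_comparison <- function(x, ...) {
  cat(sprintf("<loh_comparison> %s: %d/%d (%.1f%%) vs %s: %d/%d (%.1f%%)\n",
              x$cohort_a, x$loh_a, x$n_a, 100 * x$rate_a,
              x$cohort_b, x$loh_b, x$n_b, 100 * x$rate_b))
  cat(sprintf("  one-tailed Fisher exact (%s): p = %.4g%s\n",
              x$direction, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate margin]" else ""))
  invisible(x)
}
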