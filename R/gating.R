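#' Flow-style expression gates
#'
#' A gate keeps cells whose expression of one gene is strictly above
#' (`positive`) or strictly below (`negative`) a threshold on the
#' log2(TPM+1) scale. Cells exactly at the threshold satisfy neither
#' direction, mirroring the `> 4 or < 4` convention used when treating
#' log-scale single-cell data like flow cytometry channels.
#'
#' @param gene gene id.
#' @param threshold gate cut-off in log2(TPM+1) units; default 4.
#' @param direction `"positive"` (`value > threshold`) or `"negative"`
#'   (`value < threshold`).
#' @return A `gate_definition`.
#' @examples
#' gate("LAIR2")            # LAIR2 > 4
#' gate("LAIR2", direction = "negative")
#' @export
gate <- function(gene, threshold = 4,
                 direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene))
    abort("`gene` must be a single non-empty gene id", "tregsig_validation_error")
  if (!is.finite(threshold))
    abort("`threshold` must be finite", "tregsig_validation_error")
  structure(list(gene = gene, threshold = threshold, direction = direction),
            class = "gate_definition")
}

#' @export
print.gate_definition <- function(x, ...) {
  cat(sprintf("<gate> %s %s %g\n", x$gene,
              if (x$direction == "positive") ">" else "<", x$threshold))
  invisible(x)
}

#' Apply gates to an expression matrix
#'
#' Returns the ids of the columns (cells/samples) satisfying *all* gates
#' (conjunction). An empty result is a valid outcome, not an error.
#'
#' @param x an `expr_matrix`.
#' @param gates a `gate_definition` or list of them.
#' @param subset optional character vector of column ids to gate within.
#' @return Character vector of column ids passing every gate.
#' @export
apply_gate <- function(x, gates, subset = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (inherits(gates, "gate_definition")) gates <- list(gates)
  ids <- colnames(x$values)
  if (!is.null(subset)) {
    bad <- setdiff(subset, ids)
    if (length(bad))
      abort(sprintf("unknown sample id(s) in subset: %s",
                    paste(head(bad, 5L), collapse = ", ")),
            "tregsig_validation_error")
    ids <- ids[ids %in% subset]
  }
  keep <- rep(TRUE, length(ids))
  for (g in gates) {
    v <- gene_row(x, g$gene)[ids]
    keep <- keep & if (g$direction == "positive") v > g$threshold else v < g$threshold
  }
  ids[keep]
}

#' Quadrant co-expression statistics
#'
#' Partitions cells by joint thresholding of two genes into the four
#' flow-cytometry quadrants (double positive, x-only, y-only, double
#' negative), with strict inequalities on both sides: cells lying exactly
#' on either threshold are counted separately as boundary cells and belong
#' to no quadrant. Percentages are over all cells considered (including
#' boundary cells) and are kept exact internally; `print()` rounds to one
#' decimal as conventional in the field's figures.
#'
#' @param x an `expr_matrix`.
#' @param gene_x,gene_y the two gated genes.
#' @param threshold shared gate cut-off, default 4 log2(TPM+1).
#' @param subset optional cell ids defining the denominator population
#'   (e.g. tumor-tissue cells only); default all columns.
#' @return A `quadrant_stats` list: `counts` and `percent` (named
#'   `double_pos`, `x_only`, `y_only`, `double_neg`), `boundary`, `total`.
#' @export
quadrant_fractions <- function(x, gene_x, gene_y, threshold = 4,
                               subset = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- if (is.null(subset)) colnames(x$values) else subset
  if (!length(ids)) abort("no cells to gate", "tregsig_validation_error")
  vx <- gene_row(x, gene_x)[ids]
  vy <- gene_row(x, gene_y)[ids]
  n <- length(ids)
  counts <- c(
    double_pos = sum(vx > threshold & vy > threshold),
    x_only     = sum(vx > threshold & vy < threshold),
    y_only     = sum(vx < threshold & vy > threshold),
    double_neg = sum(vx < threshold & vy < threshold)
  )
  boundary <- n - sum(counts)
  structure(list(gene_x = gene_x, gene_y = gene_y, threshold = threshold,
                 counts = counts, percent = 100 * counts / n,
                 boundary = boundary, total = n),
            class = "quadrant_stats")
}

#' @export
print.quadrant_stats <- function(x, ...) {
  cat(sprintf("<quadrant_stats> %s x %s, cut-off %g, %d cells\n",
              x$gene_x, x$gene_y, x$threshold, x$total))
  tab <- data.frame(count = x$counts,
                    percent = sprintf("%.1f", x$percent))
  print(tab)
  if (x$boundary > 0)
    cat(sprintf("boundary cells (on a threshold): %d\n", x$boundary))
  invisible(x)
}

#' Fraction of a cell subset positive for a gene
#'
#' @param x an `expr_matrix`.
#' @param subset non-empty character vector of cell ids.
#' @param gene gene id.
#' @param threshold positivity cut-off (strict `>`), default 4.
#' @return Percentage in `[0, 100]`.
#' @examples
#' m <- expression_matrix(matrix(c(5, 5, 5, 1), 1, 4,
#'   dimnames = list("FOXP3", paste0("c", 1:4))))
#' fraction_positive(m, paste0("c", 1:4), "FOXP3")  # 75
#' @export
fraction_positive <- function(x, subset, gene, threshold = 4) {
  if (!length(subset))
    abort("subset is empty: positive fraction undefined",
          "tregsig_validation_error")
  v <- gene_row(x, gene)
  bad <- setdiff(subset, names(v))
  if (length(bad))
    abort(sprintf("unknown sample id(s) in subset: %s",
                  paste(head(bad, 5L), collapse = ", ")),
          "tregsig_validation_error")
  100 * sum(v[subset] > threshold) / length(subset)
}
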