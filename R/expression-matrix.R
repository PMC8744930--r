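#' Expression matrix container
#'
#' A light container for a genes x samples (or genes x cells) expression
#' matrix on a declared log2 scale. Row names are gene identifiers, column
#' names are sample/cell identifiers; both must be unique. Values on the
#' `log2_tpm_plus1` scale must be non-negative.
#'
#' @param values numeric matrix, genes in rows, samples/cells in columns.
#'   May be a dense base matrix or a `Matrix` sparse matrix (densified).
#' @param gene_ids,sample_ids character vectors; taken from `dimnames(values)`
#'   when `NULL`.
#' @param scale one of `"log2_tpm_plus1"` (single-cell TPM convention) or
#'   `"log2_intensity"` (bulk array/RNA-seq log2 values, may be negative
#'   after normalization).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (dense named matrix) and `scale`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("CD4", "LAIR2"), c("c1", "c2", "c3"))))
#' dim(m$values)
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              scale = c("log2_tpm_plus1", "log2_intensity")) {
  scale <- match.arg(scale)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix", "tregsig_format_error")
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("gene and sample identifiers are required", "tregsig_format_error")
  check_unique(rownames(values), "gene")
  check_unique(colnames(values), "sample")
  if (anyNA(values))
    abort("expression values must be complete (no NA)", "tregsig_format_error")
  if (scale == "log2_tpm_plus1" && any(values < 0))
    abort("negative values are not allowed on the log2(TPM+1) scale",
          "tregsig_format_error")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    abort(sprintf("duplicate %s id(s): %s", what,
                  paste(head(dup, 5L), collapse = ", ")),
          "tregsig_format_error")
  invisible(ids)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Read an expression matrix
#'
#' Readers never reorder genes or samples, never guess the orientation
#' (genes are always rows), and never guess the scale: `scale` is declared
#' by the caller.
#'
#' @param path file path. For `format = "mtx_triple"` this is the `.mtx`
#'   Matrix Market file; gene and barcode sidecars are looked up next to it
#'   (see `genes_file`, `barcodes_file`).
#' @param format `"tsv"`/`"csv"` (first column gene ids, header sample ids)
#'   or `"mtx_triple"`.
#' @param scale passed to [expression_matrix()].
#' @param genes_file,barcodes_file sidecar file names for the MTX triple,
#'   relative to `dirname(path)` unless absolute.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   format = c("tsv", "csv", "mtx_triple"),
                                   scale = c("log2_tpm_plus1", "log2_intensity"),
                                   genes_file = "genes.tsv",
                                   barcodes_file = "barcodes.tsv") {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals))
      abort("non-numeric expression values in table", "tregsig_format_error")
    rownames(vals) <- genes
    return(expression_matrix(vals, scale = scale))
  }
  # MTX triple
  locate <- function(f) if (basename(f) == f) file.path(dirname(path), f) else f
  gf <- locate(genes_file); bf <- locate(barcodes_file)
  for (f in c(path, gf, bf)) if (!file.exists(f))
    abort(sprintf("missing file: %s", f), "tregsig_format_error")
  m <- as.matrix(Matrix::readMM(path))
  genes <- read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  cells <- read.delim(bf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    abort(sprintf(
      "MTX dimensions %dx%d do not match sidecars (%d genes, %d barcodes)",
      nrow(m), ncol(m), length(genes), length(cells)),
      "tregsig_format_error")
  expression_matrix(m, gene_ids = genes, sample_ids = cells, scale = scale)
}

#' Write an expression matrix
#'
#' @param x an `expr_matrix`.
#' @inheritParams read_expression_matrix
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path,
                                    format = c("tsv", "csv", "mtx_triple"),
                                    genes_file = "genes.tsv",
                                    barcodes_file = "barcodes.tsv") {
  stopifnot(inherits(x, "expr_matrix"))
  format <- match.arg(format)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = rownames(x$values),
                     x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                path, sep = sep, quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  locate <- function(f) if (basename(f) == f) file.path(dirname(path), f) else f
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
  writeLines(rownames(x$values), locate(genes_file))
  writeLines(colnames(x$values), locate(barcodes_file))
  invisible(path)
}

# internal: fetch one gene's row, with a named error
gene_row <- function(x, gene) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene %in% rownames(x$values))
    abort(sprintf("gene not found in matrix: %s", gene),
          "tregsig_missing_gene_error")
  x$values[gene, ]
}
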