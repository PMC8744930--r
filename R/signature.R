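#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with the Welch-Satterthwaite degrees
#' of freedom. A small variance floor (`var_floor`) guards dropout-heavy
#' genes whose within-group variance is numerically zero. If both groups
#' are constant and equal the statistic is 0 and p = 1 by convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_floor lower bound applied to each group variance.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(a, b, var_floor = 1e-8) {
  if (length(a) < 2L || length(b) < 2L)
    abort("each group needs at least 2 values", "tregsig_validation_error")
  va <- var(a); vb <- var(b)
  if (va < var_floor && vb < var_floor && mean(a) == mean(b))
    return(list(t_stat = 0, df = length(a) + length(b) - 2, p_value = 1))
  va <- max(va, var_floor); vb <- max(vb, var_floor)
  sa <- va / length(a); sb <- vb / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t_stat = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

# internal: row-wise Welch t of mat[, idx_a] vs mat[, idx_b]
row_welch_t <- function(mat, idx_a, idx_b, var_floor = 1e-8) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(mat[, idx_a, drop = FALSE])
  mb <- rowMeans(mat[, idx_b, drop = FALSE])
  va <- rowSums((mat[, idx_a, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((mat[, idx_b, drop = FALSE] - mb)^2) / (nb - 1)
  degenerate <- va < var_floor & vb < var_floor & ma == mb
  va <- pmax(va, var_floor); vb <- pmax(vb, var_floor)
  sa <- va / na; sb <- vb / nb
  t_stat <- (ma - mb) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * pt(-abs(t_stat), df)
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(gene_id = rownames(mat), mean_pos = ma, mean_neg = mb,
             t_stat = t_stat, df = df, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate q-values by the step-up procedure
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    abort("p-values must lie in [0, 1]", "tregsig_validation_error")
  p.adjust(p_values, method = "BH")
}

#' Fold change from log2 means
#'
#' Linear-scale fold change `2^(mean_pos - mean_neg)` between two group
#' means given in log2 units.
#'
#' @param mean_pos,mean_neg finite group means, log2 units.
#' @return Linear ratio (> 0).
#' @export
fold_change <- function(mean_pos, mean_neg) {
  if (any(!is.finite(mean_pos)) || any(!is.finite(mean_neg)))
    abort("means must be finite", "tregsig_validation_error")
  2^(mean_pos - mean_neg)
}

#' Derive a gene signature by per-gene differential testing
#'
#' Tests every gene between a positive and a negative cell group with a
#' Welch t-test (Student's pooled-variance t available via `var_equal`),
#' adjusts p-values by Benjamini-Hochberg, and keeps up-regulated genes
#' passing `q < q_max` and fold change `>= fc_min` with
#' `mean_pos > mean_neg`. Fold change is `2^(difference of log2 means)`
#' by default; `fc_method = "linear_mean"` instead takes the ratio of
#' linear-scale group means `(2^x - 1)`.
#'
#' The returned gene order is deterministic: ascending q, then descending
#' fold change, then gene id — independent of the input cell and gene
#' ordering.
#'
#' @param x an `expr_matrix` (single cells in columns).
#' @param pos_cells,neg_cells disjoint non-empty character vectors of cell
#'   ids (e.g. CD4+LAIR2+ vs CD4+LAIR2- gated cells).
#' @param q_max BH-adjusted p-value cut-off (default 0.001).
#' @param fc_min minimum fold change (default 1.55).
#' @param var_equal use pooled-variance (Student) t instead of Welch.
#' @param fc_method `"log2_mean_diff"` (default) or `"linear_mean"`.
#' @return A `signature_gene_set`: `genes` (character), `table` (the full
#'   per-gene `DEResult` data.frame with q and fold change), `q_max`,
#'   `fc_min`.
#' @export
derive_signature <- function(x, pos_cells, neg_cells,
                             q_max = 0.001, fc_min = 1.55,
                             var_equal = FALSE,
                             fc_method = c("log2_mean_diff", "linear_mean")) {
  stopifnot(inherits(x, "expr_matrix"))
  fc_method <- match.arg(fc_method)
  if (q_max <= 0 || fc_min <= 0)
    abort("thresholds must be > 0", "tregsig_validation_error")
  if (!length(pos_cells) || !length(neg_cells))
    abort("both cell groups must be non-empty", "tregsig_validation_error")
  if (length(intersect(pos_cells, neg_cells)))
    abort("positive and negative cell sets overlap", "tregsig_validation_error")
  ids <- colnames(x$values)
  bad <- setdiff(c(pos_cells, neg_cells), ids)
  if (length(bad))
    abort(sprintf("unknown cell id(s): %s", paste(head(bad, 5L), collapse = ", ")),
          "tregsig_validation_error")
  if (length(pos_cells) < 2L || length(neg_cells) < 2L)
    abort("each cell group needs at least 2 cells", "tregsig_validation_error")

  de <- if (var_equal) {
    row_student_t(x$values, pos_cells, neg_cells)
  } else {
    row_welch_t(x$values, pos_cells, neg_cells)
  }
  de$q_value <- benjamini_hochberg(de$p_value)
  de$fold_change <- if (fc_method == "log2_mean_diff") {
    fold_change(de$mean_pos, de$mean_neg)
  } else {
    lin_pos <- rowMeans(2^x$values[, pos_cells, drop = FALSE] - 1)
    lin_neg <- rowMeans(2^x$values[, neg_cells, drop = FALSE] - 1)
    pmax(lin_pos, 1e-12) / pmax(lin_neg, 1e-12)
  }
  hit <- de$q_value < q_max & de$fold_change >= fc_min & de$mean_pos > de$mean_neg
  hits <- de[hit, , drop = FALSE]
  hits <- hits[order(hits$q_value, -hits$fold_change, hits$gene_id), ,
               drop = FALSE]
  structure(list(genes = hits$gene_id, table = de,
                 q_max = q_max, fc_min = fc_min,
                 n_pos = length(pos_cells), n_neg = length(neg_cells)),
            class = "signature_gene_set")
}

row_student_t <- function(mat, idx_a, idx_b, var_floor = 1e-8) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(mat[, idx_a, drop = FALSE])
  mb <- rowMeans(mat[, idx_b, drop = FALSE])
  va <- rowSums((mat[, idx_a, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((mat[, idx_b, drop = FALSE] - mb)^2) / (nb - 1)
  sp2 <- pmax(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2), var_floor)
  degenerate <- va < var_floor & vb < var_floor & ma == mb
  t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- rep(na + nb - 2, length(t_stat))
  p <- 2 * pt(-abs(t_stat), df)
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(gene_id = rownames(mat), mean_pos = ma, mean_neg = mb,
             t_stat = t_stat, df = df, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.signature_gene_set <- function(x, ...) {
  cat(sprintf("<signature_gene_set> %d genes (q < %g, FC >= %g; %d vs %d cells)\n",
              length(x$genes), x$q_max, x$fc_min, x$n_pos, x$n_neg))
  if (length(x$genes)) cat(paste(head(x$genes, 10L), collapse = ", "),
                           if (length(x$genes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Construct a signature gene set from a plain gene list
#'
#' For signatures taken from the literature or from files, without
#' per-gene test provenance.
#'
#' @param genes character vector of gene ids.
#' @return A `signature_gene_set` with an empty provenance table.
#' @export
signature_gene_set <- function(genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) abort("empty gene list", "tregsig_validation_error")
  structure(list(genes = genes, table = NULL, q_max = NA_real_,
                 fc_min = NA_real_, n_pos = NA_integer_, n_neg = NA_integer_),
            class = "signature_gene_set")
}

#' Correlation screen against an anchor gene
#'
#' Pearson correlation of every gene with an anchor gene across samples,
#' used to select the anchor's co-expression neighborhood (e.g. for gene
#' ontology analysis). Returns the top `top_k` genes with `r > r_min`,
#' ranked by decreasing r; the anchor is excluded from its own list.
#'
#' @param x an `expr_matrix` with >= 3 samples.
#' @param anchor_gene gene id present in `x`.
#' @param top_k maximum number of genes returned (default 500).
#' @param r_min minimum Pearson r (default 0.37, strict `>`).
#' @return data.frame with `gene_id`, `r`, `p_value` (t-approximation).
#' @export
correlation_screen <- function(x, anchor_gene, top_k = 500, r_min = 0.37) {
  stopifnot(inherits(x, "expr_matrix"))
  n <- ncol(x$values)
  if (n < 3L) abort("need >= 3 samples", "tregsig_validation_error")
  anchor <- gene_row(x, anchor_gene)
  if (sd(anchor) == 0)
    abort("anchor gene has zero variance", "tregsig_validation_error")
  keep_sd <- apply(x$values, 1L, sd) > 0
  r <- as.vector(cor(anchor, t(x$values[keep_sd, , drop = FALSE])))
  out <- data.frame(gene_id = rownames(x$values)[keep_sd], r = r,
                    stringsAsFactors = FALSE)
  out <- out[out$gene_id != anchor_gene & out$r > r_min, , drop = FALSE]
  out <- out[order(-out$r, out$gene_id), , drop = FALSE]
  out <- head(out, top_k)
  t_stat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p_value <- 2 * pt(-abs(t_stat), n - 2)
  rownames(out) <- NULL
  out
}
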