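#' Per-sample signature score
#'
#' The score of a sample is the unweighted mean, over the signature genes
#' present in the matrix, of that gene's across-sample normalized
#' expression: each gene is median-centered across samples
#' (`normalize = "median_center"`, the default) and optionally also
#' divided by its across-sample standard deviation
#' (`normalize = "zscore"`). Signature genes absent from the matrix are
#' dropped, never imputed; their ids are attached to the result.
#'
#' @param x an `expr_matrix` (bulk cohort, genes x samples, log2 scale).
#' @param signature a `signature_gene_set` or character vector of gene ids.
#' @param normalize `"median_center"` or `"zscore"`.
#' @return Named numeric vector of per-sample scores, with attributes
#'   `absent_genes` (signature genes not in the matrix) and `n_genes_used`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 2, 3, 4, 4, 10), 2, 3, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' signature_score(m, c("g1", "g2"))  # -0.5, 0, 3.5
#' @export
signature_score <- function(x, signature,
                            normalize = c("median_center", "zscore")) {
  stopifnot(inherits(x, "expr_matrix"))
  normalize <- match.arg(normalize)
  genes <- if (inherits(signature, "signature_gene_set")) signature$genes
           else as.character(signature)
  if (ncol(x$values) < 2L)
    abort("need >= 2 samples to score", "tregsig_validation_error")
  present <- intersect(genes, rownames(x$values))
  absent <- setdiff(genes, present)
  if (!length(present))
    abort("no signature gene present in the matrix", "tregsig_validation_error")
  sub <- x$values[present, , drop = FALSE]
  med <- apply(sub, 1L, median)
  centered <- sub - med
  if (normalize == "zscore") {
    s <- apply(sub, 1L, sd)
    zero <- s == 0
    if (any(zero)) {
      warning(sprintf("dropping %d zero-variance gene(s) from z-scored signature",
                      sum(zero)))
      centered <- centered[!zero, , drop = FALSE]
      s <- s[!zero]
      if (!nrow(centered))
        abort("no signature gene with positive variance", "tregsig_validation_error")
    }
    centered <- centered / s
  }
  scores <- colMeans(centered)
  attr(scores, "absent_genes") <- absent
  attr(scores, "n_genes_used") <- nrow(centered)
  if (length(absent))
    message(sprintf("signature_score: %d/%d signature genes absent from matrix",
                    length(absent), length(genes)))
  scores
}

#' Median-split risk stratification
#'
#' Splits samples into high- and low-risk groups at the cohort median
#' score. Tie rule: scores strictly above the median are `high`; scores
#' at or below it are `low` (deterministic, and conservative for the
#' high-risk hazard ratio). With an odd sample count the median sample is
#' therefore `low`.
#'
#' @param scores named numeric vector of per-sample scores (>= 2 samples).
#' @return A `risk_stratification`: data.frame with `sample_id`, `score`,
#'   `group` (factor low/high), plus attribute `cutoff`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L)
    abort("need >= 2 samples to stratify", "tregsig_validation_error")
  if (length(unique(scores)) == 1L)
    abort("all scores identical: no stratification possible",
          "tregsig_validation_error")
  cutoff <- median(scores)
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  out <- data.frame(sample_id = names(scores), score = as.numeric(scores),
                    group = group, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("risk_stratification", "data.frame")
  out
}

#' CD4-adjusted signature score
#'
#' Removes the linear component of the signature score explained by CD4
#' expression, as a proxy adjustment for overall CD4+ T-cell content:
#' the adjusted score is the least-squares residual of the score on
#' median-centered CD4 expression. This regression-residual
#' operationalization is one plausible reading of "taking the presence of
#' CD4+ T cells into consideration" and is flagged as non-canonical.
#'
#' @param scores named per-sample scores (from [signature_score()]).
#' @param x the same cohort's `expr_matrix`, containing `cd4_gene`.
#' @param cd4_gene gene id used as the CD4 abundance proxy.
#' @return Adjusted scores (named, same order). If CD4 is constant the
#'   unadjusted scores are returned with a warning.
#' @export
cd4_adjusted_score <- function(scores, x, cd4_gene = "CD4") {
  stopifnot(inherits(x, "expr_matrix"))
  cd4 <- gene_row(x, cd4_gene)
  bad <- setdiff(names(scores), names(cd4))
  if (length(bad))
    abort("scores contain samples absent from the matrix",
          "tregsig_validation_error")
  cd4 <- cd4[names(scores)]
  if (sd(cd4) == 0) {
    warning("CD4 expression is constant; returning unadjusted scores")
    return(scores)
  }
  fit <- lm(as.numeric(scores) ~ I(cd4 - median(cd4)))
  out <- setNames(resid(fit), names(scores))
  attr(out, "adjustment") <- "residual of score ~ median-centered CD4 (non-canonical)"
  out
}
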