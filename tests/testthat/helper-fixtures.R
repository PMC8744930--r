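# Small in-code fixtures shared across test files.

# 5 cells with (CD4, LAIR2) = (5,5),(5,3),(3,5),(3,3),(6,7)
five_cell_matrix <- function() {
  vals <- rbind(CD4 = c(5, 5, 3, 3, 6), LAIR2 = c(5, 3, 5, 3, 7))
  colnames(vals) <- paste0("c", 1:5)
  expression_matrix(vals)
}

# 2 genes x 3 samples scoring fixture: g1 = (1,2,3), g2 = (4,4,10)
score_fixture <- function() {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(4, 4, 10))
  colnames(vals) <- paste0("s", 1:3)
  expression_matrix(vals)
}

random_matrix <- function(n_genes = 8, n_samples = 6, seed = 42) {
  set.seed(seed)
  vals <- matrix(round(abs(rnorm(n_genes * n_samples, 4, 2)), 6),
                 n_genes, n_samples,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(vals)
}

small_clinical <- function() {
  clinical_table(data.frame(
    sample_id = c("a", "b", "c"),
    os_time = c(12, 30, 45),
    event = c(1, 0, 1),
    age = c(60, 70, 65),
    sex = c("female", "male", "female"),
    smoking = c("no", "yes", "yes"),
    stage = c("I", "II", "IV"),
    histology = c("solid", "acinar", "other"),
    stringsAsFactors = FALSE))
}
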