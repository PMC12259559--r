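# shared helpers: small matrices built in code and an independent brute-force
# oracle for single-gene threshold classifiers

toy_matrix <- function(values, genes, samples, scale = "identity") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expression_matrix(m, scale = scale)
}

# independent oracle: best accuracy of any threshold rule on one variable,
# trying every observed value as a cut in both orientations (plain loops on
# purpose; must not share code with the package)
oracle_best_threshold_acc <- function(v, y) {
  cuts <- c(min(v) - 1, sort(unique(v)), max(v) + 1)
  best <- 0
  for (t in cuts) {
    acc_gt <- mean((v > t) == y)
    acc_le <- mean((v <= t) == y)
    best <- max(best, acc_gt, acc_le)
  }
  best
}

# labelled two-class 1-gene dataset as (matrix, labels); log2 scale so that
# negative toy values are admissible
one_gene_data <- function(case_vals, ctrl_vals, gene = "G1") {
  n <- length(case_vals) + length(ctrl_vals)
  ids <- sprintf("s%02d", seq_len(n))
  m <- toy_matrix(c(case_vals, ctrl_vals), gene, ids, scale = "log2")
  lab <- sample_labels(ids, rep(c("case", "control"),
                                c(length(case_vals), length(ctrl_vals))),
                       "case", "control")
  list(matrix = m, labels = lab)
}
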