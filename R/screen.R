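#' Rank genes by single-gene separability
#'
#' Scores each gene by the best training accuracy attainable with a single
#' threshold on that gene alone (both orientations considered), a cheap and
#' fully deterministic stand-in for a differential-expression screen. Ties are
#' broken by absolute log fold change between class means, then by gene name.
#' A gene constant across all samples scores exactly 0.5 (chance).
#'
#' @param matrix An [expression_matrix()].
#' @param labels A [sample_labels()] over the matrix's samples, with at least
#'   two samples per class.
#' @param top_m Number of top-ranked genes to return; must not exceed the
#'   number of genes.
#' @return A data frame with columns `gene`, `score` (best-threshold
#'   accuracy), and `abs_lfc`, ordered best first, truncated to `top_m` rows.
#' @export
screen_genes <- function(matrix, labels, top_m) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(labels, "sample_labels"))
  if (!setequal(matrix$sample_ids, labels$sample_ids))
    stop("matrix and label sample sets differ", call. = FALSE)
  n_genes <- length(matrix$gene_ids)
  if (top_m > n_genes)
    stop(sprintf("top_m (%d) exceeds the number of genes (%d)", top_m, n_genes),
         call. = FALSE)
  if (min(table(labels$class)) < 2L)
    stop("need at least two samples per class to screen genes", call. = FALSE)
  y <- labels$class[match(matrix$sample_ids, labels$sample_ids)] ==
    labels$positive_class
  scores <- vapply(seq_len(n_genes), function(i)
    best_threshold_accuracy(matrix$values[i, ], y), numeric(1))
  # fold change on a log scale; identity-scale values are logged first
  lfc <- vapply(seq_len(n_genes), function(i) {
    v <- matrix$values[i, ]
    if (matrix$scale == "identity") v <- log2(v + 1)
    abs(mean(v[y]) - mean(v[!y]))
  }, numeric(1))
  ord <- order(-scores, -lfc, matrix$gene_ids)
  out <- data.frame(gene = matrix$gene_ids[ord], score = scores[ord],
                    abs_lfc = lfc[ord], stringsAsFactors = FALSE)
  utils::head(out, top_m)
}

# Best accuracy of a one-variable threshold rule, orientation-free.
# Constant vectors score 0.5 by convention (no threshold separates anything).
best_threshold_accuracy <- function(v, y) {
  if (length(unique(v)) == 1L) return(0.5)
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]; ys <- y[ord]
  # predict positive for v > t, with t scanning below the minimum and between
  # consecutive distinct values: positives above cut = P - cumsum at cut
  cum_pos <- cumsum(ys)
  P <- sum(ys); N <- n - P
  cuts <- c(0L, which(diff(vs) > 0), n)  # number of samples at or below t
  acc_gt <- vapply(cuts, function(k) {
    tp <- P - if (k == 0L) 0L else cum_pos[k]
    tn <- k - if (k == 0L) 0L else cum_pos[k]
    (tp + tn) / n
  }, numeric(1))
  # opposite orientation: predict positive for v <= t
  acc_le <- vapply(cuts, function(k) {
    tp <- if (k == 0L) 0L else cum_pos[k]
    tn <- (n - k) - (P - tp)
    (tp + tn) / n
  }, numeric(1))
  max(acc_gt, acc_le)
}
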