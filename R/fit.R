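#' Configuration for panel fitting
#'
#' @param max_genes_per_factor Largest gene subset considered for one
#'   competing factor (default 4).
#' @param max_factors Maximum number of competing factors in a panel
#'   (default 3).
#' @param screen_top_m Number of genes kept by the screening step when no
#'   explicit gene pool is supplied (default 50).
#' @param specificity_floor Training specificity every factor must reach in
#'   `specificity_first` mode (default 1.0; the intercept shift enforces it by
#'   construction).
#' @param margin Positive slack by which every control's factor value is kept
#'   below zero in `specificity_first` mode (default 1e-6).
#' @param mode `"specificity_first"` (default) shifts each factor's intercept
#'   so that no training control scores positive, then counts the cases
#'   captured; `"accuracy_first"` instead picks the intercept (and score
#'   orientation) maximizing training accuracy.
#' @param seed Integer seed recorded with the fit; the optimizer itself is
#'   deterministic and uses no randomness.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_genes_per_factor = 4L, max_factors = 3L,
                       screen_top_m = 50L, specificity_floor = 1.0,
                       margin = 1e-6,
                       mode = c("specificity_first", "accuracy_first"),
                       seed = 1L) {
  mode <- match.arg(mode)
  max_genes_per_factor <- as.integer(max_genes_per_factor)
  max_factors <- as.integer(max_factors)
  if (max_genes_per_factor < 1L || max_factors < 1L)
    stop("max_genes_per_factor and max_factors must be at least 1", call. = FALSE)
  if (margin <= 0) stop("`margin` must be positive", call. = FALSE)
  if (specificity_floor < 0 || specificity_floor > 1)
    stop("`specificity_floor` must lie in [0, 1]", call. = FALSE)
  structure(
    list(max_genes_per_factor = max_genes_per_factor,
         max_factors = max_factors, screen_top_m = as.integer(screen_top_m),
         specificity_floor = specificity_floor, margin = margin,
         mode = mode, seed = as.integer(seed)),
    class = "fit_config"
  )
}

#' Fit one competing factor on a fixed gene subset
#'
#' Coefficients come from a ridge-penalized (lambda = 1e-6) logistic fit on
#' the subset — penalization keeps the fit defined under the perfect
#' separation these factors are built to achieve. The intercept is then
#' re-chosen by mode: `specificity_first` shifts it so every control's factor
#' value is at most `-margin` (training specificity 1 by construction) while
#' sensitivity is as large as the fitted direction allows; `accuracy_first`
#' scans all score thresholds (both orientations) and takes the one maximizing
#' training accuracy, so on a single gene it attains exactly the best
#' single-threshold accuracy.
#'
#' @param matrix An [expression_matrix()].
#' @param labels A [sample_labels()] over the matrix's samples.
#' @param gene_subset Character vector of genes (size at most
#'   `config$max_genes_per_factor`).
#' @param config A [fit_config()].
#' @return A [competing_factor()]; its transform is `"log2_as_given"` for a
#'   log2-scale matrix and `"identity"` otherwise.
#' @export
fit_competing_factor <- function(matrix, labels, gene_subset, config = fit_config()) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(labels, "sample_labels"),
            inherits(config, "fit_config"))
  if (length(gene_subset) > config$max_genes_per_factor)
    stop("gene subset larger than max_genes_per_factor", call. = FALSE)
  if (!setequal(matrix$sample_ids, labels$sample_ids))
    stop("matrix and label sample sets differ", call. = FALSE)
  idx <- match_genes(gene_subset, matrix$gene_ids)
  X <- t(matrix$values[idx, , drop = FALSE])
  colnames(X) <- matrix$gene_ids[idx]
  y <- as.numeric(labels$class[match(matrix$sample_ids, labels$sample_ids)] ==
                    labels$positive_class)
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need both classes to fit a factor", call. = FALSE)
  fit <- ridge_logistic(X, y, lambda = 1e-6)
  if (all(fit$slopes == 0))
    stop("degenerate gene subset (no variation): ",
         paste(gene_subset, collapse = ", "), call. = FALSE)
  w <- fit$slopes
  s <- drop(X %*% w)
  if (config$mode == "specificity_first") {
    b <- -(max(s[y == 0]) + config$margin)
  } else {
    best <- best_intercept_accuracy(s, y)
    w <- best$sign * w
    b <- best$intercept
  }
  transform <- if (matrix$scale == "log2") "log2_as_given" else "identity"
  names(w) <- colnames(X)
  competing_factor(intercept = b, coefficients = w, transform = transform)
}

# choose sign and intercept of a linear score to maximize accuracy of the rule
# "positive iff sign*s + b > 0"; thresholds at midpoints between distinct
# score values (plus outside the range), first maximum wins, sign +1 preferred
best_intercept_accuracy <- function(s, y) {
  best <- list(acc = -Inf)
  for (sgn in c(1, -1)) {
    v <- sgn * s
    vs <- sort(unique(v))
    thr <- c(vs[1L] - 1, (vs[-1L] + vs[-length(vs)]) / 2, vs[length(vs)] + 1)
    for (t in thr) {
      acc <- mean((v > t) == (y == 1))
      if (acc > best$acc + 1e-12)
        best <- list(acc = acc, sign = sgn, intercept = -t)
    }
  }
  best
}

#' Fit a max-logistic panel by greedy factor addition
#'
#' Reproduces the construction that yields few-gene competing-factor panels:
#' an exhaustive search over gene subsets (sizes 1 to
#' `config$max_genes_per_factor`, drawn from the screened pool) picks the
#' factor capturing the most positive samples under the mode's constraint;
#' subsequent factors are refitted on the controls plus the still-missed
#' positives only, so each new factor specializes in the cases its
#' predecessors left behind. Fitting stops when all positives are captured,
#' `config$max_factors` is reached, or no candidate factor captures a new
#' positive. Subset ties go to fewer genes, then lexicographic gene order, so
#' the result is fully deterministic.
#'
#' @param matrix An [expression_matrix()].
#' @param labels A [sample_labels()] over the matrix's samples.
#' @param config A [fit_config()].
#' @param genes Optional explicit gene pool; when `NULL` the pool is the top
#'   `config$screen_top_m` genes from [screen_genes()].
#' @return A list of class `fit_result`: `panel` (the fitted
#'   [max_logistic_panel()]), `training_report` (a `classification_report` on
#'   the training matrix), `gene_subset_trace` (data frame of every subset
#'   examined per round with the positives it captured), and `config`.
#' @export
fit_panel <- function(matrix, labels, config = fit_config(), genes = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(labels, "sample_labels"),
            inherits(config, "fit_config"))
  if (!setequal(matrix$sample_ids, labels$sample_ids))
    stop("matrix and label sample sets differ", call. = FALSE)
  if (is.null(genes)) {
    screened <- screen_genes(matrix, labels,
                             min(config$screen_top_m, length(matrix$gene_ids)))
    pool <- screened$gene
  } else {
    pool <- matrix$gene_ids[match_genes(genes, matrix$gene_ids)]
  }
  if (!length(pool)) stop("empty gene pool", call. = FALSE)
  pool <- sort(pool)
  subsets <- enumerate_subsets(pool, config$max_genes_per_factor)

  cls <- labels$class[match(matrix$sample_ids, labels$sample_ids)]
  is_pos <- cls == labels$positive_class
  pos_ids <- matrix$sample_ids[is_pos]
  ctrl_ids <- matrix$sample_ids[!is_pos]

  factors <- list()
  trace <- list()
  missed <- pos_ids
  for (round in seq_len(config$max_factors)) {
    train_ids <- c(ctrl_ids, missed)
    sub_m <- restrict_matrix(matrix, samples = train_ids)
    sub_l <- sample_labels(train_ids, cls[match(train_ids, matrix$sample_ids)],
                           labels$positive_class, labels$control_class)
    best <- NULL
    round_trace <- vector("list", length(subsets))
    for (k in seq_along(subsets)) {
      subset <- subsets[[k]]
      cf <- tryCatch(fit_competing_factor(sub_m, sub_l, subset, config),
                     error = function(e) NULL)
      if (is.null(cf)) {
        round_trace[[k]] <- data.frame(round = round,
                                       subset = paste(subset, collapse = "+"),
                                       n_genes = length(subset),
                                       captured = NA_integer_)
        next
      }
      vals <- cf_values_matrix(cf, sub_m)
      captured <- sum(vals[sub_m$sample_ids %in% missed] > 0)
      round_trace[[k]] <- data.frame(round = round,
                                     subset = paste(subset, collapse = "+"),
                                     n_genes = length(subset),
                                     captured = captured)
      # strict improvement only: enumeration order encodes the tie-break
      # (fewer genes first, then lexicographic)
      if (is.null(best) || captured > best$captured)
        best <- list(cf = cf, captured = captured, subset = subset)
    }
    trace[[round]] <- do.call(rbind, round_trace)
    if (is.null(best))
      stop("no gene subset could be fitted (all degenerate)", call. = FALSE)
    if (round > 1L && best$captured == 0L) break  # no factor adds coverage
    factors[[length(factors) + 1L]] <- best$cf
    scores_all <- cf_values_matrix(best$cf, matrix)
    newly <- matrix$sample_ids[scores_all > 0]
    missed <- setdiff(missed, newly)
    if (!length(missed)) break
  }

  panel <- max_logistic_panel(factors,
                              positive_class = labels$positive_class,
                              control_class = labels$control_class)
  report <- apply_panel(panel, matrix, labels)
  structure(
    list(panel = panel, training_report = report,
         gene_subset_trace = do.call(rbind, trace), config = config),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  print(x$panel)
  print(x$training_report)
  invisible(x)
}

# all subsets of `pool` with sizes 1..max_size, smaller sizes first and
# lexicographic within a size (pool must already be sorted)
enumerate_subsets <- function(pool, max_size) {
  out <- list()
  for (size in seq_len(min(max_size, length(pool)))) {
    cmb <- utils::combn(pool, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
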