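#' Competing risk factor: a sparse linear combination of gene expressions
#'
#' One competing factor is `intercept + sum_g coefficient_g * t(expression_g)`,
#' where `t` is the factor's expression transform. Several factors "compete"
#' within a panel and the largest value drives the classification.
#'
#' @param intercept Finite scalar intercept.
#' @param coefficients Named numeric vector of gene weights; zero weights are
#'   dropped (a gene with weight zero is simply absent from the factor) and at
#'   least one non-zero weight must remain.
#' @param transform How expression values feed the linear combination:
#'   `"identity"` uses them as given, `"ln1p"` applies `log(x + 1)` first, and
#'   `"log2_as_given"` marks values already on a log2 platform scale (used as
#'   given, numerically identical to identity but kept as provenance).
#' @return An object of class `competing_factor`.
#' @examples
#' competing_factor(8.8323, c(CKAP4 = 11.1401, RNF4 = -8.24, NONO = -4.27))
#' @export
competing_factor <- function(intercept, coefficients,
                             transform = c("identity", "ln1p", "log2_as_given")) {
  transform <- match.arg(transform)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("`intercept` must be a finite scalar", call. = FALSE)
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients))))
    stop("`coefficients` must be a named numeric vector", call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("coefficients must all be finite", call. = FALSE)
  coefficients <- coefficients[coefficients != 0]
  if (!length(coefficients))
    stop("a competing factor needs at least one non-zero coefficient", call. = FALSE)
  check_unique_ids(names(coefficients), "gene")
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         transform = transform),
    class = "competing_factor"
  )
}

#' @export
print.competing_factor <- function(x, ...) {
  terms <- sprintf("%+.4f*%s", x$coefficients, names(x$coefficients))
  cat(sprintf("<competing_factor %s> %.4f %s\n", x$transform, x$intercept,
              paste(terms, collapse = " ")))
  invisible(x)
}

#' Max-logistic panel of competing factors
#'
#' The panel's score for a sample is the maximum over its competing factors,
#' and the risk of the positive class is the logistic of that maximum:
#' risk = exp(CF_max) / (1 + exp(CF_max)). A sample is called positive when
#' its risk strictly exceeds the threshold (at the default threshold 0.5 this
#' is exactly CF_max > 0); a sample sitting on the boundary is called control.
#'
#' @param factors A `competing_factor` or list of them (at least one).
#' @param positive_class,control_class Class names used in predictions.
#' @param risk_threshold Risk above which a sample is called positive;
#'   strictly between 0 and 1 (default 0.5).
#' @return An object of class `max_logistic_panel`.
#' @export
max_logistic_panel <- function(factors, positive_class = "case",
                               control_class = "control",
                               risk_threshold = 0.5) {
  if (inherits(factors, "competing_factor")) factors <- list(factors)
  if (!length(factors) || !all(vapply(factors, inherits, TRUE, "competing_factor")))
    stop("`factors` must be one or more competing_factor objects", call. = FALSE)
  if (!is.numeric(risk_threshold) || risk_threshold <= 0 || risk_threshold >= 1)
    stop("`risk_threshold` must lie strictly between 0 and 1", call. = FALSE)
  if (identical(positive_class, control_class))
    stop("positive and control class names must differ", call. = FALSE)
  structure(
    list(factors = factors, positive_class = positive_class,
         control_class = control_class, risk_threshold = risk_threshold),
    class = "max_logistic_panel"
  )
}

#' @export
print.max_logistic_panel <- function(x, ...) {
  cat(sprintf("<max_logistic_panel> %d factor(s), %s vs %s, threshold %.3g\n",
              length(x$factors), x$positive_class, x$control_class,
              x$risk_threshold))
  for (f in x$factors) print(f)
  invisible(x)
}

#' Genes referenced by a panel
#'
#' @param panel A [max_logistic_panel()].
#' @return Character vector of the distinct genes used across all factors.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "max_logistic_panel"))
  unique(unlist(lapply(panel$factors, function(f) names(f$coefficients))))
}

# apply a factor's expression transform to raw values
apply_transform <- function(x, transform) {
  switch(transform,
    identity = x,
    log2_as_given = x,
    ln1p = {
      if (any(x <= -1)) stop("ln1p transform undefined for values <= -1",
                             call. = FALSE)
      log1p(x)
    }
  )
}

#' Value of one competing factor for one sample
#'
#' @param cf A [competing_factor()].
#' @param sample_expression Named numeric vector of expression values covering
#'   every gene in the factor (gene matching is case-insensitive).
#' @return The scalar factor value `intercept + sum coefficient * t(expr)`.
#' @examples
#' cf <- competing_factor(-17.726, c(FCAR = 3.507))
#' cf_value(cf, c(FCAR = 6))  # 3.316
#' @export
cf_value <- function(cf, sample_expression) {
  stopifnot(inherits(cf, "competing_factor"))
  if (!is.numeric(sample_expression) || is.null(names(sample_expression)))
    stop("`sample_expression` must be a named numeric vector", call. = FALSE)
  idx <- match(tolower(names(cf$coefficients)),
               tolower(trimws(names(sample_expression))))
  if (anyNA(idx))
    stop("expression missing for gene(s): ",
         paste(names(cf$coefficients)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  x <- apply_transform(unname(sample_expression[idx]), cf$transform)
  cf$intercept + sum(cf$coefficients * x)
}

# factor values for all samples of an expr_matrix (internal, vectorized)
cf_values_matrix <- function(cf, matrix) {
  idx <- match_genes(names(cf$coefficients), matrix$gene_ids)
  x <- apply_transform(matrix$values[idx, , drop = FALSE], cf$transform)
  drop(cf$intercept + crossprod(x, cf$coefficients))
}

#' Per-sample CF_max scores for a panel
#'
#' @param panel A [max_logistic_panel()].
#' @param matrix An [expression_matrix()] containing every panel gene.
#' @return Named numeric vector: for each sample, the maximum competing-factor
#'   value.
#' @export
panel_scores <- function(panel, matrix) {
  stopifnot(inherits(panel, "max_logistic_panel"),
            inherits(matrix, "expr_matrix"))
  per_factor <- vapply(panel$factors, cf_values_matrix,
                       numeric(length(matrix$sample_ids)), matrix = matrix)
  per_factor <- matrix(per_factor, nrow = length(matrix$sample_ids))
  scores <- apply(per_factor, 1L, max)
  names(scores) <- matrix$sample_ids
  scores
}

#' Risk probability for a single sample
#'
#' Applies the logistic function to the maximum competing-factor value:
#' `risk = plogis(CF_max)`, always strictly inside (0, 1) and exactly 0.5 when
#' CF_max is 0.
#'
#' @param panel A [max_logistic_panel()].
#' @param sample_expression Named numeric expression vector.
#' @return Risk of the positive class, in (0, 1).
#' @export
panel_risk <- function(panel, sample_expression) {
  stopifnot(inherits(panel, "max_logistic_panel"))
  cf_max <- max(vapply(panel$factors, cf_value, numeric(1),
                       sample_expression = sample_expression))
  stats::plogis(cf_max)
}

#' Risk probabilities for all samples of a matrix
#'
#' @inheritParams panel_scores
#' @return Named numeric vector of risks in (0, 1).
#' @export
panel_risks <- function(panel, matrix) {
  stats::plogis(panel_scores(panel, matrix))
}

#' Classify every sample of an expression matrix
#'
#' A sample is called `positive_class` when its risk strictly exceeds the
#' panel threshold; a risk of exactly the threshold is a control call.
#'
#' @inheritParams panel_scores
#' @return Named character vector of predicted classes.
#' @export
classify <- function(panel, matrix) {
  risks <- panel_risks(panel, matrix)
  ifelse(risks > panel$risk_threshold, panel$positive_class,
         panel$control_class)
}

#' Confusion counts and summary metrics for a set of predictions
#'
#' @param predictions Named character vector of predicted classes (as from
#'   [classify()]).
#' @param labels A [sample_labels()] object over the same sample set.
#' @param risks Optional named numeric vector of per-sample risks, stored in
#'   the report.
#' @return An object of class `classification_report` with fields `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `sensitivity`, `specificity` and
#'   `per_sample_risk`.
#' @export
evaluate <- function(predictions, labels, risks = NULL) {
  stopifnot(inherits(labels, "sample_labels"))
  if (is.null(names(predictions)))
    stop("`predictions` must be named by sample id", call. = FALSE)
  if (!setequal(names(predictions), labels$sample_ids))
    stop("prediction and label sample sets differ", call. = FALSE)
  pred <- predictions[labels$sample_ids]
  truth_pos <- labels$class == labels$positive_class
  pred_pos <- pred == labels$positive_class
  tp <- sum(truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  classification_report(tp = tp, fp = fp, tn = tn, fn = fn,
                        per_sample_risk = risks)
}

#' Build a classification report from confusion counts
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @param per_sample_risk Optional named numeric vector of risks.
#' @return A `classification_report`; `sensitivity` (`specificity`) is `NaN`
#'   when there are no positives (negatives).
#' @export
classification_report <- function(tp, fp, tn, fn, per_sample_risk = NULL) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  total <- tp + fp + tn + fn
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         total = total,
         accuracy = (tp + tn) / total,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         per_sample_risk = per_sample_risk),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> n=%d tp=%d fp=%d tn=%d fn=%d | acc %.2f%% sens %.2f%% spec %.2f%%\n",
    x$total, x$tp, x$fp, x$tn, x$fn,
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Score a panel against a labelled expression matrix
#'
#' Convenience wrapper: classify, then evaluate against the labels.
#'
#' @inheritParams panel_scores
#' @param labels A [sample_labels()] over the matrix's samples.
#' @return A `classification_report` including per-sample risks.
#' @export
apply_panel <- function(panel, matrix, labels) {
  risks <- panel_risks(panel, matrix)
  preds <- ifelse(risks > panel$risk_threshold, panel$positive_class,
                  panel$control_class)
  evaluate(preds, labels, risks = risks)
}

#' Serialize a panel to JSON
#'
#' Coefficients are written with full double precision so that
#' `panel_from_json(panel_to_json(p))` is bit-exact.
#'
#' @param panel A [max_logistic_panel()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
panel_to_json <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "max_logistic_panel"))
  obj <- list(
    positive_class = panel$positive_class,
    control_class = panel$control_class,
    risk_threshold = panel$risk_threshold,
    factors = lapply(panel$factors, function(f)
      list(intercept = f$intercept, transform = f$transform,
           coefficients = as.list(f$coefficients)))
  )
  # digits = I(17): significant digits sufficient for an exact double round trip
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a panel from JSON
#'
#' @param source A file path or a JSON string produced by [panel_to_json()].
#' @return A [max_logistic_panel()].
#' @export
panel_from_json <- function(source) {
  obj <- if (file.exists(source)) jsonlite::read_json(source)
         else jsonlite::parse_json(source)
  factors <- lapply(obj$factors, function(f)
    competing_factor(f$intercept, unlist(f$coefficients), f$transform))
  max_logistic_panel(factors,
                     positive_class = obj$positive_class,
                     control_class = obj$control_class,
                     risk_threshold = obj$risk_threshold %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a classification report to disk
#'
#' Writes a TSV of per-sample risks (when present) plus a JSON summary of the
#' confusion counts and metrics.
#'
#' @param report A `classification_report`.
#' @param risk_path Path for the per-sample risk TSV (skipped when the report
#'   carries no risks or `risk_path` is `NULL`).
#' @param summary_path Path for the JSON summary.
#' @return `summary_path`, invisibly.
#' @export
write_report <- function(report, summary_path, risk_path = NULL) {
  stopifnot(inherits(report, "classification_report"))
  if (!is.null(risk_path) && !is.null(report$per_sample_risk)) {
    utils::write.table(
      data.frame(sample_id = names(report$per_sample_risk),
                 risk = unname(report$per_sample_risk)),
      risk_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    report[c("tp", "fp", "tn", "fn", "total",
             "accuracy", "sensitivity", "specificity")],
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(summary_path)
}
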