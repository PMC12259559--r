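#' Expression matrix container
#'
#' A minimal genes-by-samples container for non-negative expression values with
#' a declared measurement scale. The scale tag records how the numbers are to
#' be read: `"identity"` for values on the natural (multiplicative) scale such
#' as qPCR relative copy counts, `"log2"` for log2 intensities as delivered by
#' microarray platforms, and `"ln1p"` for values already transformed by
#' `log(x + 1)`.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   row and column names giving gene and sample identifiers.
#' @param scale One of `"identity"`, `"ln1p"`, `"log2"`.
#' @return An object of class `expr_matrix` with fields `gene_ids`,
#'   `sample_ids`, `values` and `scale`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' expression_matrix(m, scale = "identity")
#' @export
expression_matrix <- function(values, scale = c("identity", "ln1p", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must carry gene row names and sample column names", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must all be finite; missing values are not imputed",
         call. = FALSE)
  if (scale == "identity" && any(values < 0))
    stop("identity-scale expression values must be non-negative", call. = FALSE)
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(sample_ids, "sample")
  structure(
    list(gene_ids = gene_ids, sample_ids = sample_ids,
         values = values, scale = scale),
    class = "expr_matrix"
  )
}

# duplicate detection is case-insensitive: user tables mix Fcar/FCAR etc.
check_unique_ids <- function(ids, what) {
  folded <- tolower(trimws(ids))
  if (anyDuplicated(folded)) {
    dup <- ids[duplicated(folded)]
    stop(sprintf("duplicate %s identifiers (case-insensitive): %s",
                 what, paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              length(x$gene_ids), length(x$sample_ids), x$scale))
  cat("genes:", paste(utils::head(x$gene_ids, 8), collapse = ", "),
      if (length(x$gene_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Restrict an expression matrix to a subset of genes and/or samples
#'
#' Gene matching is case-insensitive and ignores surrounding whitespace;
#' requesting an absent gene or sample is an error.
#'
#' @param matrix An [expression_matrix()].
#' @param genes Character vector of gene identifiers, or `NULL` to keep all.
#' @param samples Character vector of sample identifiers, or `NULL` to keep all.
#' @return An `expr_matrix` restricted to the requested rows/columns, in the
#'   requested order.
#' @export
restrict_matrix <- function(matrix, genes = NULL, samples = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (!is.null(genes)) {
    idx <- match_genes(genes, matrix$gene_ids)
    v <- v[idx, , drop = FALSE]
  }
  if (!is.null(samples)) {
    sidx <- match(samples, matrix$sample_ids)
    if (anyNA(sidx))
      stop("unknown sample(s): ", paste(samples[is.na(sidx)], collapse = ", "),
           call. = FALSE)
    v <- v[, sidx, drop = FALSE]
  }
  expression_matrix(v, scale = matrix$scale)
}

# case/whitespace-insensitive gene lookup; errors name the missing genes
match_genes <- function(genes, gene_ids) {
  idx <- match(tolower(trimws(genes)), tolower(trimws(gene_ids)))
  if (anyNA(idx))
    stop("gene(s) not found in matrix: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Binary phenotype labels for a set of samples
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param class Character vector, same length, giving each sample's class;
#'   every entry must equal `positive_class` or `control_class`.
#' @param positive_class Name of the positive (case) class, e.g. `"sepsis"`.
#' @param control_class Name of the control class, e.g. `"healthy"`.
#' @return An object of class `sample_labels`.
#' @export
sample_labels <- function(sample_ids, class, positive_class, control_class) {
  sample_ids <- as.character(sample_ids)
  class <- as.character(class)
  stopifnot(length(sample_ids) == length(class))
  check_unique_ids(sample_ids, "sample")
  bad <- setdiff(unique(class), c(positive_class, control_class))
  if (length(bad))
    stop("labels contain classes other than '", positive_class, "'/'",
         control_class, "': ", paste(bad, collapse = ", "), call. = FALSE)
  if (!any(class == positive_class) || !any(class == control_class))
    stop("need at least one sample of each class", call. = FALSE)
  structure(
    list(sample_ids = sample_ids, class = class,
         positive_class = positive_class, control_class = control_class),
    class = "sample_labels"
  )
}

#' @export
print.sample_labels <- function(x, ...) {
  cat(sprintf("<sample_labels> %d samples: %d %s / %d %s\n",
              length(x$sample_ids),
              sum(x$class == x$positive_class), x$positive_class,
              sum(x$class == x$control_class), x$control_class))
  invisible(x)
}

#' Cohort metadata record
#'
#' @param cohort_id Short cohort identifier.
#' @param accession Public accession, or `"self-collected"`.
#' @param tissue One of `"whole_blood"`, `"plasma"`, `"pbmc"`.
#' @param population Free-text population description.
#' @param n_case,n_control Class sizes (each at least 1).
#' @return An object of class `cohort_meta`.
#' @export
cohort_meta <- function(cohort_id, accession, tissue = c("whole_blood", "plasma", "pbmc"),
                        population = "", n_case, n_control) {
  tissue <- match.arg(tissue)
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  if (n_case < 1L || n_control < 1L)
    stop("n_case and n_control must each be at least 1", call. = FALSE)
  structure(
    list(cohort_id = cohort_id, accession = accession, tissue = tissue,
         population = population, n_case = n_case, n_control = n_control),
    class = "cohort_meta"
  )
}

#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table (delimiter auto-detected from the file
#' extension, `.csv` meaning comma and anything else tab) into an
#' [expression_matrix()]. The first column (for `genes_in_rows`) or the header
#' row (for `samples_in_rows`) holds identifiers; the numeric body must be
#' complete — any missing or non-numeric cell is an error naming its position,
#' never silently imputed.
#'
#' @param path Path to the delimited file.
#' @param orientation `"genes_in_rows"` (default) if rows are genes, or
#'   `"samples_in_rows"` if rows are samples.
#' @param scale Measurement scale tag, attached verbatim; see
#'   [expression_matrix()].
#' @return An `expr_matrix` in genes-by-samples orientation regardless of the
#'   input orientation.
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_in_rows", "samples_in_rows"),
                                  scale = c("identity", "ln1p", "log2")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  raw <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression table needs an id column plus data", call. = FALSE)
  ids <- trimws(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  num <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row '%s', column '%s' in %s",
                   ids[bad[1L]], colnames(body)[j], path), call. = FALSE)
    num[, j] <- v
  }
  if (orientation == "samples_in_rows") num <- t(num)
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' Values are written with full double precision (17 significant digits) so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path; `.csv` writes comma-separated, else tab-separated.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  body <- format(matrix$values, digits = 17, trim = TRUE, scientific = FALSE)
  out <- cbind(gene_id = matrix$gene_ids, body)
  utils::write.table(out, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label file
#'
#' The file must have a header and two columns, `sample_id` and `label`.
#'
#' @param path Path to a TSV/CSV file.
#' @param positive_class,control_class Class names; every label must be one of
#'   the two.
#' @return A [sample_labels()] object.
#' @export
read_labels <- function(path, positive_class, control_class) {
  raw <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("label file must have columns sample_id,label", call. = FALSE)
  sample_labels(trimws(raw[[1L]]), trimws(raw[[2L]]),
                positive_class = positive_class, control_class = control_class)
}

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
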