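#' Bundle a cohort's metadata, expression matrix and labels
#'
#' @param meta A [cohort_meta()].
#' @param matrix An [expression_matrix()].
#' @param labels A [sample_labels()] with exactly the matrix's samples.
#' @return An object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(meta, matrix, labels) {
  stopifnot(inherits(meta, "cohort_meta"), inherits(matrix, "expr_matrix"),
            inherits(labels, "sample_labels"))
  if (!setequal(matrix$sample_ids, labels$sample_ids))
    stop("matrix and label sample sets differ for cohort ", meta$cohort_id,
         call. = FALSE)
  structure(list(meta = meta, matrix = matrix, labels = labels),
            class = "cohort_bundle")
}

#' Cohort-to-cohort cross-validation of a gene set
#'
#' Validates a fixed gene panel the way the unpooled multi-cohort design
#' prescribes: cohorts are never concatenated; instead the panel's
#' coefficients are refitted independently within every cohort (so what is
#' validated is the gene set, not any one cohort's coefficients) and each
#' cohort is scored on its own refit. Per-cohort coefficient signs are
#' recorded for consistency analysis. Because every fit sees only one
#' cohort's data, cohort-level batch effects (global shifts or rescalings)
#' cannot leak between cohorts.
#'
#' @param cohorts List of [cohort_bundle()] objects (at least one).
#' @param gene_panel Character vector of genes; every cohort's matrix must
#'   contain all of them.
#' @param config A [fit_config()] governing the per-cohort refits.
#' @return An object of class `crossval_report`: `per_cohort` (named list with
#'   `panel` and `report` per cohort), `pooled` (summed-count totals from
#'   [pooled_metrics()]), and `sign_table` (genes x cohorts matrix of
#'   aggregated coefficient signs: +1, -1, 0 for mixed, NA for absent).
#' @export
cross_cohort_validate <- function(cohorts, gene_panel, config = fit_config()) {
  if (!length(cohorts) || !all(vapply(cohorts, inherits, TRUE, "cohort_bundle")))
    stop("`cohorts` must be a non-empty list of cohort_bundle objects",
         call. = FALSE)
  ids <- vapply(cohorts, function(b) b$meta$cohort_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated cohort ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  for (b in cohorts) {
    missing <- gene_panel[is.na(match(tolower(gene_panel),
                                      tolower(trimws(b$matrix$gene_ids))))]
    if (length(missing))
      stop(sprintf("cohort %s lacks panel gene(s): %s", b$meta$cohort_id,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  per_cohort <- lapply(cohorts, function(b) {
    fit <- fit_panel(b$matrix, b$labels, config, genes = gene_panel)
    list(panel = fit$panel, report = fit$training_report)
  })
  names(per_cohort) <- ids
  sign_table <- vapply(per_cohort, function(pc)
    panel_coefficient_signs(pc$panel, gene_panel), numeric(length(gene_panel)))
  sign_table <- matrix(sign_table, nrow = length(gene_panel),
                       dimnames = list(gene_panel, ids))
  structure(
    list(per_cohort = per_cohort,
         pooled = pooled_metrics(lapply(per_cohort, `[[`, "report")),
         sign_table = sign_table),
    class = "crossval_report"
  )
}

# aggregated sign of a gene over a panel's factors: +1/-1 if all its non-zero
# coefficients agree, 0 if mixed, NA if the gene appears in no factor
panel_coefficient_signs <- function(panel, genes) {
  vapply(genes, function(g) {
    s <- unlist(lapply(panel$factors, function(f) {
      hit <- tolower(names(f$coefficients)) == tolower(g)
      sign(f$coefficients[hit])
    }))
    if (!length(s)) return(NA_real_)
    if (all(s > 0)) 1 else if (all(s < 0)) -1 else 0
  }, numeric(1))
}

#' Apply one frozen panel across cohorts (transfer mode)
#'
#' The complement of [cross_cohort_validate()]: coefficients fitted in one
#' cohort are applied unchanged to others. Provided for users probing
#' coefficient transferability; unpooled refitting is the validation method of
#' record because cohort-specific scales make frozen coefficients
#' systematically miscalibrated across platforms.
#'
#' @param panel A [max_logistic_panel()].
#' @param cohorts List of [cohort_bundle()] objects.
#' @return Named list of `classification_report`s, one per cohort.
#' @export
cross_cohort_transfer <- function(panel, cohorts) {
  reports <- lapply(cohorts, function(b) apply_panel(panel, b$matrix, b$labels))
  names(reports) <- vapply(cohorts, function(b) b$meta$cohort_id, character(1))
  reports
}

#' Pool classification reports by summed confusion counts
#'
#' Pooled accuracy is (sum tp + sum tn) / (sum total); sensitivity and
#' specificity analogously, i.e. sample-size-weighted pooling. Invariant to
#' report order.
#'
#' @param reports A non-empty list of `classification_report`s.
#' @return A `classification_report` holding the summed counts.
#' @export
pooled_metrics <- function(reports) {
  if (!length(reports) ||
      !all(vapply(reports, inherits, TRUE, "classification_report")))
    stop("`reports` must be a non-empty list of classification_report objects",
         call. = FALSE)
  sums <- function(f) sum(vapply(reports, `[[`, numeric(1), f))
  classification_report(tp = sums("tp"), fp = sums("fp"),
                        tn = sums("tn"), fn = sums("fn"))
}

#' Coefficient-sign consistency across cohorts, by tissue
#'
#' For every gene and tissue group, checks whether all of the gene's non-zero
#' coefficients (across all panels and factors of that tissue) share one sign,
#' and flags genes whose sign is consistent within two tissue groups but
#' opposite between them — the whole-blood versus plasma reversal pattern.
#'
#' @param panels Named list of [max_logistic_panel()] objects keyed by cohort.
#' @param tissue Named character vector mapping each cohort id in `panels` to
#'   its tissue group.
#' @param first_factor_only When `TRUE`, only each panel's leading factor is
#'   inspected. The leading factor is the dominant gene-disease association;
#'   later factors adjust for residual case subgroups and may legitimately
#'   carry opposite signs, so cross-tissue comparisons are usually made on
#'   leading factors.
#' @return A list with `per_tissue` (data frame: gene, tissue, n_panels,
#'   consistent, sign as "+", "-" or "mixed") and `reversals` (data frame of
#'   gene/tissue pairs with consistent but opposite signs).
#' @export
sign_consistency <- function(panels, tissue, first_factor_only = FALSE) {
  if (first_factor_only)
    panels <- lapply(panels, function(p) {
      p$factors <- p$factors[1L]
      p
    })
  if (!length(panels)) stop("`panels` must be non-empty", call. = FALSE)
  if (is.null(names(panels)) || !all(names(panels) %in% names(tissue)))
    stop("every panel needs a tissue assignment", call. = FALSE)
  genes <- sort(unique(unlist(lapply(panels, panel_genes))))
  rows <- list()
  for (tis in unique(tissue[names(panels)])) {
    in_group <- names(panels)[tissue[names(panels)] == tis]
    for (g in genes) {
      signs <- unlist(lapply(panels[in_group], function(p) {
        s <- panel_coefficient_signs(p, g)
        if (is.na(s)) NULL else s
      }))
      if (is.null(signs) || !length(signs)) next  # gene absent in this tissue
      consistent <- all(signs == 1) || all(signs == -1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, tissue = tis, n_panels = length(signs),
        consistent = consistent,
        sign = if (all(signs == 1)) "+" else if (all(signs == -1)) "-" else "mixed",
        stringsAsFactors = FALSE)
    }
  }
  per_tissue <- do.call(rbind, rows)
  reversals <- NULL
  if (!is.null(per_tissue)) {
    for (g in unique(per_tissue$gene)) {
      sub <- per_tissue[per_tissue$gene == g & per_tissue$consistent, ]
      if (nrow(sub) >= 2L) {
        pairs <- utils::combn(seq_len(nrow(sub)), 2L, simplify = FALSE)
        for (pr in pairs) {
          if (sub$sign[pr[1L]] != sub$sign[pr[2L]]) {
            reversals <- rbind(reversals, data.frame(
              gene = g, tissue_a = sub$tissue[pr[1L]],
              sign_a = sub$sign[pr[1L]], tissue_b = sub$tissue[pr[2L]],
              sign_b = sub$sign[pr[2L]], stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  list(per_tissue = per_tissue, reversals = reversals)
}
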