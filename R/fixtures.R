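#' Load a bundled fixture
#'
#' The package ships the printed data needed to reproduce the published
#' classifiers: the self-collected plasma qPCR cohort (50 subjects, 6 genes),
#' the competing-factor classifier coefficients for all cohorts and
#' progression comparisons, the cohort metadata table, and the PBMC-cohort
#' classifiers on the LN(x+1) scale.
#'
#' @param name One of:
#' \describe{
#'   \item{`"table2_cohort"`}{list with `matrix` (6 genes x 50 samples,
#'     identity scale), `labels` (32 sepsis vs 18 healthy),
#'     `progression_labels` (the 32 patients relabelled 11 septic_shock vs
#'     21 sepsis), and `subjects` (per-subject metadata data frame).}
#'   \item{`"table4_panels"`}{named list of [max_logistic_panel()] objects
#'     keyed by cohort id (progression comparisons carry a
#'     `_shock_vs_sepsis` / `_severe_vs_sepsis` suffix); each panel has a
#'     `reported` attribute with the published accuracy/sensitivity/
#'     specificity in percent.}
#'   \item{`"table1_meta"`}{list of 12 [cohort_meta()] records.}
#'   \item{`"pbmc_panels"`}{named list of panels on the `ln1p` transform.}
#' }
#' @return The fixture object described above.
#' @examples
#' fx <- load_fixture("table2_cohort")
#' fx$matrix
#' @export
load_fixture <- function(name) {
  valid <- c("table2_cohort", "table4_panels", "table1_meta", "pbmc_panels")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  switch(name,
    table2_cohort = load_table2(),
    table4_panels = load_panel_file("table4_panels.json"),
    table1_meta = load_table1(),
    pbmc_panels = load_panel_file("pbmc_panels.json")
  )
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "maxlogit")
  if (path == "") stop("bundled file missing: ", file, call. = FALSE)
  path
}

load_table2 <- function() {
  subjects <- utils::read.delim(extdata("table2_subjects.tsv"),
                                check.names = FALSE, stringsAsFactors = FALSE)
  mat <- read_expression_table(extdata("table2_expression.tsv"),
                               orientation = "genes_in_rows",
                               scale = "identity")
  labels <- sample_labels(subjects$sample_id, subjects$group,
                          positive_class = "sepsis", control_class = "healthy")
  patients <- subjects[subjects$group == "sepsis", ]
  progression <- sample_labels(patients$sample_id, patients$stage,
                               positive_class = "septic_shock",
                               control_class = "sepsis")
  list(matrix = mat, labels = labels, progression_labels = progression,
       subjects = subjects)
}

load_table1 <- function() {
  tab <- utils::read.delim(extdata("table1_meta.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    cohort_meta(tab$cohort_id[i], tab$accession[i], tab$tissue[i],
                tab$population[i], tab$n_case[i], tab$n_control[i]))
}

load_panel_file <- function(file) {
  raw <- jsonlite::read_json(extdata(file))
  out <- lapply(raw, function(entry) {
    factors <- lapply(entry$factors, function(f)
      competing_factor(intercept = f$intercept,
                       coefficients = unlist(f$coefficients),
                       transform = f$transform))
    panel <- max_logistic_panel(factors,
                                positive_class = entry$positive_class,
                                control_class = entry$control_class)
    attr(panel, "reported") <- entry$reported
    attr(panel, "tissue") <- entry$tissue
    attr(panel, "comparison") <- entry$comparison
    attr(panel, "n_case") <- entry$n_case
    attr(panel, "n_control") <- entry$n_control
    panel
  })
  names(out) <- names(raw)
  out
}
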