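#' Describe a synthetic case/control expression cohort
#'
#' The generator draws log2-scale expression: for gene g and sample s,
#' `value = mu_g + batch_shift + [case] * delta_{g, subgroup(s)} + noise`,
#' with gene baselines `mu_g ~ Normal(6, 1)` fixed by the seed and
#' `noise ~ Normal(0, noise_sd^2)`. Case-subgroup heterogeneity — disjoint
#' case subpopulations carrying different signal genes, the situation a
#' single linear factor cannot cover — enters through `subgroups`. A plasma
#' cohort flips the sign of every effect, emulating the whole-blood versus
#' plasma reversal of differential-expression direction. `identity_power`
#' output exponentiates to the positive 2^value scale, matching multiplicative
#' qPCR-style relative copy counts.
#'
#' @param cohort_id Cohort identifier.
#' @param n_case,n_control Class sizes.
#' @param n_genes Total gene count (at least the number of signal genes).
#' @param signal_genes Named numeric vector of per-gene case effects delta in
#'   log2 units (may be empty for pure-noise cohorts).
#' @param subgroups Optional list of case subgroups, each a
#'   `list(weight =, effects =)` where `effects` is a named numeric vector
#'   overriding `signal_genes` for that subgroup; weights must be
#'   non-negative and sum to 1. `NULL` means one homogeneous case group.
#' @param batch_shift Cohort-wide additive shift in log2 units (default 0).
#' @param noise_sd Residual standard deviation in log2 units (default 1).
#' @param tissue `"whole_blood"` (default), `"plasma"` (flips every effect
#'   sign) or `"pbmc"`.
#' @param output_scale `"log2"` (default) or `"identity_power"` (2^value).
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(cohort_id = "cohort1", n_case, n_control,
                                  n_genes, signal_genes = numeric(0),
                                  subgroups = NULL, batch_shift = 0,
                                  noise_sd = 1,
                                  tissue = c("whole_blood", "plasma", "pbmc"),
                                  output_scale = c("log2", "identity_power"),
                                  seed = 1L) {
  tissue <- match.arg(tissue)
  output_scale <- match.arg(output_scale)
  if (length(signal_genes) && is.null(names(signal_genes)))
    stop("`signal_genes` must be named by gene", call. = FALSE)
  if (n_genes < length(signal_genes))
    stop("n_genes must be at least the number of signal genes", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (!is.null(subgroups)) {
    w <- vapply(subgroups, function(s) s$weight, numeric(1))
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("subgroup weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(cohort_id = cohort_id, n_case = as.integer(n_case),
         n_control = as.integer(n_control), n_genes = as.integer(n_genes),
         signal_genes = signal_genes, subgroups = subgroups,
         batch_shift = batch_shift, noise_sd = noise_sd, tissue = tissue,
         output_scale = output_scale, seed = as.integer(seed)),
    class = "synthetic_cohort_spec"
  )
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate one synthetic cohort
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A list with `matrix` (an [expression_matrix()], `n_genes` x
#'   `n_case + n_control`), `labels` (a [sample_labels()] with classes
#'   `"case"`/`"control"`), and `truth` (class `ground_truth`: realized
#'   per-gene effects after any tissue sign flip, their signs, the subgroup
#'   assignment of every case sample, and the generating spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- spec$n_case + spec$n_control
  signal_names <- names(spec$signal_genes)
  extra <- setdiff(unique(unlist(lapply(spec$subgroups, function(s) names(s$effects)))),
                   signal_names)
  named <- c(signal_names, extra)
  if (length(named) > spec$n_genes)
    stop("n_genes too small for the named signal genes", call. = FALSE)
  filler <- sprintf("G%04d", seq_len(spec$n_genes - length(named)))
  genes <- c(named, filler)
  sample_ids <- c(sprintf("%s_case_%03d", spec$cohort_id, seq_len(spec$n_case)),
                  sprintf("%s_ctrl_%03d", spec$cohort_id, seq_len(spec$n_control)))
  flip <- if (spec$tissue == "plasma") -1 else 1

  with_seed(spec$seed, {
    mu <- stats::rnorm(spec$n_genes, mean = 6, sd = 1)
    subgroup <- if (is.null(spec$subgroups)) rep(1L, spec$n_case)
                else sample(seq_along(spec$subgroups), spec$n_case,
                            replace = TRUE,
                            prob = vapply(spec$subgroups, `[[`, numeric(1), "weight"))
    # per-subgroup effect vector over all genes
    n_groups <- if (is.null(spec$subgroups)) 1L else length(spec$subgroups)
    delta <- matrix(0, spec$n_genes, n_groups, dimnames = list(genes, NULL))
    delta[signal_names, ] <- spec$signal_genes
    if (!is.null(spec$subgroups)) {
      for (j in seq_along(spec$subgroups)) {
        ov <- spec$subgroups[[j]]$effects
        if (length(ov)) delta[names(ov), j] <- ov
      }
    }
    delta <- flip * delta
    vals <- matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
                   spec$n_genes, n)
    vals <- vals + mu + spec$batch_shift
    for (i in seq_len(spec$n_case)) {
      vals[, i] <- vals[, i] + delta[, subgroup[i]]
    }
    dimnames(vals) <- list(genes, sample_ids)
    if (spec$output_scale == "identity_power") {
      mat <- expression_matrix(2^vals, scale = "identity")
    } else {
      mat <- expression_matrix(vals, scale = "log2")
    }
    labels <- sample_labels(sample_ids,
                            rep(c("case", "control"),
                                c(spec$n_case, spec$n_control)),
                            positive_class = "case", control_class = "control")
    realized <- delta
    truth <- structure(
      list(signal_genes = genes[rowSums(realized != 0) > 0],
           effects = realized[rowSums(realized != 0) > 0, , drop = FALSE],
           signs = sign(realized[rowSums(realized != 0) > 0, , drop = FALSE]),
           subgroup = stats::setNames(subgroup, sample_ids[seq_len(spec$n_case)]),
           spec = spec),
      class = "ground_truth")
    list(matrix = mat, labels = labels, truth = truth)
  })
}

#' Generate several cohorts sharing one signal
#'
#' Each cohort is generated independently — its own seed, batch shift and
#' noise level — but all carry the same named signal effects, with the sign
#' flipped for plasma cohorts by [generate_cohort()]. This is the structure
#' the unpooled cross-validation design assumes: a biological signal shared
#' across cohorts, confounded per cohort by batch scale.
#'
#' @param specs List of [synthetic_cohort_spec()] with distinct `cohort_id`s.
#' @param shared_signal Named numeric vector of effects imposed on every
#'   cohort (replacing each spec's `signal_genes`); may be empty for
#'   pure-noise cohorts.
#' @return A list with `cohorts` (list of [cohort_bundle()]) and `truths`
#'   (named list of per-cohort ground truth).
#' @export
generate_multi_cohort <- function(specs, shared_signal = numeric(0)) {
  if (!length(specs) ||
      !all(vapply(specs, inherits, TRUE, "synthetic_cohort_spec")))
    stop("`specs` must be a non-empty list of synthetic_cohort_spec",
         call. = FALSE)
  ids <- vapply(specs, `[[`, character(1), "cohort_id")
  if (anyDuplicated(ids))
    stop("duplicated cohort_ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  out <- lapply(specs, function(sp) {
    sp$signal_genes <- shared_signal
    if (length(shared_signal) && sp$n_genes < length(shared_signal))
      stop("n_genes too small for shared signal in cohort ", sp$cohort_id,
           call. = FALSE)
    g <- generate_cohort(sp)
    meta <- cohort_meta(sp$cohort_id, "synthetic", sp$tissue,
                        population = "synthetic",
                        n_case = sp$n_case, n_control = sp$n_control)
    list(bundle = cohort_bundle(meta, g$matrix, g$labels), truth = g$truth)
  })
  list(cohorts = lapply(out, `[[`, "bundle"),
       truths = stats::setNames(lapply(out, `[[`, "truth"), ids))
}
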