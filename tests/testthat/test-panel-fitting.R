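test_that("screening ranks a shifted signal gene first, scored as the oracle does", {
  set.seed(7)
  n_genes <- 21; n <- 80
  ids <- sprintf("s%02d", 1:n)
  vals <- matrix(rnorm(n_genes * n, 6, 1), n_genes, n,
                 dimnames = list(c("SIG", sprintf("N%02d", 1:20)), ids))
  y <- rep(c(TRUE, FALSE), each = 40)
  vals["SIG", y] <- vals["SIG", y] + 4  # +4 SD case shift
  m <- expression_matrix(vals, "log2")
  lab <- sample_labels(ids, ifelse(y, "case", "control"), "case", "control")

  ranked <- screen_genes(m, lab, top_m = n_genes)
  expect_identical(ranked$gene[1], "SIG")
  # every reported score equals the independent brute-force threshold score
  for (i in seq_len(n_genes)) {
    g <- ranked$gene[i]
    expect_equal(ranked$score[i],
                 oracle_best_threshold_acc(vals[g, ], y),
                 info = g)
  }
  expect_equal(nrow(screen_genes(m, lab, top_m = 5)), 5L)
  expect_error(screen_genes(m, lab, top_m = n_genes + 1), "exceeds")
})

test_that("a constant gene screens at exactly chance", {
  d <- one_gene_data(c(5, 6, 7), c(1, 2))
  m2 <- d$matrix
  m2$values <- rbind(m2$values, FLAT = rep(3, 5))
  m2 <- expression_matrix(m2$values, "identity")
  ranked <- screen_genes(m2, d$labels, top_m = 2)
  expect_equal(ranked$score[ranked$gene == "FLAT"], 0.5)
})

test_that("a separable one-gene problem fits a positive factor with perfect accuracy", {
  d <- one_gene_data(c(10, 12), c(1, 2))
  cf <- fit_competing_factor(d$matrix, d$labels, "G1", fit_config())
  expect_gt(cf$coefficients[["G1"]], 0)
  panel <- max_logistic_panel(cf, "case", "control")
  rep <- apply_panel(panel, d$matrix, d$labels)
  expect_equal(rep$accuracy, 1.0)
})

test_that("specificity-first fitting pins training specificity at 1 on overlap", {
  d <- one_gene_data(case_vals = c(3, 5, 7, 9, 2.0), ctrl_vals = c(1, 2, 4, 6))
  cf <- fit_competing_factor(d$matrix, d$labels, "G1",
                             fit_config(mode = "specificity_first"))
  rep <- apply_panel(max_logistic_panel(cf, "case", "control"),
                     d$matrix, d$labels)
  expect_identical(rep$specificity, 1.0)
  expect_lt(rep$sensitivity, 1.0)
})

test_that("fitted coefficient signs recover the generating signs", {
  spec <- synthetic_cohort_spec("sgn", n_case = 100, n_control = 100,
                                n_genes = 3,
                                signal_genes = c(A = 2, B = 2, C = -2),
                                noise_sd = 1, seed = 11)
  g <- generate_cohort(spec)
  cf <- fit_competing_factor(g$matrix, g$labels, c("A", "B", "C"), fit_config())
  expect_gt(cf$coefficients[["A"]], 0)
  expect_gt(cf$coefficients[["B"]], 0)
  expect_lt(cf$coefficients[["C"]], 0)
})

test_that("degenerate all-constant subsets are a fit error", {
  m <- toy_matrix(rep(2, 6), c("F1", "F2"), c("s1", "s2", "s3"))
  lab <- sample_labels(c("s1", "s2", "s3"), c("case", "case", "control"),
                       "case", "control")
  expect_error(fit_competing_factor(m, lab, c("F1", "F2"), fit_config()),
               "degenerate")
})

test_that("accuracy-first one-gene fits attain the brute-force threshold optimum", {
  set.seed(19)
  for (rep_i in 1:20) {
    n <- sample(6:20, 1)
    n_case <- sample(2:(n - 2), 1)
    v <- round(rnorm(n, 5, 2), 2)
    y <- c(rep(TRUE, n_case), rep(FALSE, n - n_case))
    d <- one_gene_data(v[y], v[!y])
    cf <- fit_competing_factor(d$matrix, d$labels, "G1",
                               fit_config(mode = "accuracy_first"))
    got <- apply_panel(max_logistic_panel(cf, "case", "control"),
                       d$matrix, d$labels)$accuracy
    expect_equal(got, oracle_best_threshold_acc(v, y), info = paste("rep", rep_i))
  }
})

test_that("greedy fitting adds a second factor for opposite-sign case subgroups", {
  spec <- synthetic_cohort_spec(
    "xor", n_case = 30, n_control = 30, n_genes = 2,
    signal_genes = c(A = 0, B = 0),
    subgroups = list(list(weight = 0.5, effects = c(A = 5, B = -5)),
                     list(weight = 0.5, effects = c(A = -5, B = 5))),
    noise_sd = 0.5, seed = 21)
  g <- generate_cohort(spec)
  cfg1 <- fit_config(max_genes_per_factor = 2, max_factors = 1)
  single <- fit_panel(g$matrix, g$labels, cfg1, genes = c("A", "B"))
  expect_lt(single$training_report$sensitivity, 1.0)

  cfg2 <- fit_config(max_genes_per_factor = 2, max_factors = 3)
  multi <- fit_panel(g$matrix, g$labels, cfg2, genes = c("A", "B"))
  expect_gte(length(multi$panel$factors), 2L)
  expect_equal(multi$training_report$accuracy, 1.0)
})

test_that("a homogeneous case cluster needs exactly one factor", {
  spec <- synthetic_cohort_spec("one", n_case = 40, n_control = 40,
                                n_genes = 5, signal_genes = c(A = 6),
                                noise_sd = 0.5, seed = 31)
  g <- generate_cohort(spec)
  fit <- fit_panel(g$matrix, g$labels, fit_config(max_genes_per_factor = 2),
                   genes = c("A", "G0001", "G0002"))
  expect_length(fit$panel$factors, 1L)
  expect_equal(fit$training_report$accuracy, 1.0)
})

test_that("fitting is deterministic and every factor meets the specificity floor", {
  spec <- synthetic_cohort_spec("det", n_case = 50, n_control = 50,
                                n_genes = 30, signal_genes = c(A = 2, B = -2),
                                noise_sd = 1, seed = 5)
  g <- generate_cohort(spec)
  cfg <- fit_config(max_genes_per_factor = 2, max_factors = 3,
                    screen_top_m = 8, seed = 99)
  f1 <- fit_panel(g$matrix, g$labels, cfg)
  f2 <- fit_panel(g$matrix, g$labels, cfg)
  expect_identical(panel_to_json(f1$panel), panel_to_json(f2$panel))

  ctrl_ids <- g$labels$sample_ids[g$labels$class == "control"]
  for (cf in f1$panel$factors) {
    vals <- vapply(ctrl_ids, function(s)
      cf_value(cf, g$matrix$values[, s]), numeric(1))
    expect_true(all(vals <= 0))  # specificity 1 per factor, by construction
  }
})

test_that("refitting the progression panel matches or beats the printed accuracy", {
  fx <- load_fixture("table2_cohort")
  pm <- restrict_matrix(fx$matrix, samples = fx$progression_labels$sample_ids)
  fit <- fit_panel(pm, fx$progression_labels,
                   fit_config(max_genes_per_factor = 4, max_factors = 3),
                   genes = c("NONO", "CKAP4", "FCAR", "PLEKHO1", "BMP6"))
  expect_gte(fit$training_report$accuracy, 0.9375)
  expect_identical(fit$training_report$specificity, 1.0)
})

test_that("the exhaustive search over a printed gene pool reaches perfect training accuracy", {
  fx <- load_fixture("table2_cohort")
  fit <- fit_panel(fx$matrix, fx$labels, fit_config(max_genes_per_factor = 3),
                   genes = c("RNF4", "NONO", "PLEKHO1"))
  expect_equal(fit$training_report$accuracy, 1.0)
})

test_that("empty gene pools are rejected", {
  d <- one_gene_data(c(5, 6), c(1, 2))
  expect_error(fit_panel(d$matrix, d$labels, fit_config(), genes = character(0)),
               "empty|not found")
})
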