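test_that("competing-factor values reproduce direct arithmetic on printed inputs", {
  cf11 <- competing_factor(-2.7514,
                           c(RNF4 = 1.0879, NONO = -6.5770, PLEKHO1 = -9.6589))
  # first healthy control and first sepsis patient of the bundled cohort
  ctrl <- c(RNF4 = 1.105730653, NONO = 0.444421341, PLEKHO1 = 0.323088208)
  case <- c(RNF4 = 348.4964138, NONO = 19.22617679, PLEKHO1 = 0.858565436)
  exp_ctrl <- -2.7514 + 1.0879 * ctrl[["RNF4"]] - 6.5770 * ctrl[["NONO"]] -
    9.6589 * ctrl[["PLEKHO1"]]
  exp_case <- -2.7514 + 1.0879 * case[["RNF4"]] - 6.5770 * case[["NONO"]] -
    9.6589 * case[["PLEKHO1"]]
  expect_equal(cf_value(cf11, ctrl), exp_ctrl)
  expect_equal(cf_value(cf11, case), exp_case)
  expect_equal(round(exp_ctrl, 3), -7.592)
  expect_equal(round(exp_case, 2), 241.63)

  single <- competing_factor(-17.726, c(FCAR = 3.507))
  expect_equal(cf_value(single, c(FCAR = 6)), -17.726 + 3.507 * 6)
  expect_equal(cf_value(single, c(FCAR = 6)), 3.316)

  ident <- competing_factor(0, c(G1 = 1))
  expect_equal(cf_value(ident, c(G1 = 5)), 5)
})

test_that("factor construction and evaluation reject bad inputs", {
  expect_error(competing_factor(0, c(G1 = 0)), "non-zero")
  expect_error(competing_factor(0, c(G1 = Inf)), "finite")
  cf <- competing_factor(1, c(G1 = 2, G2 = -1))
  expect_error(cf_value(cf, c(G1 = 1)), "G2")
  ln <- competing_factor(0, c(G1 = 1), transform = "ln1p")
  expect_error(cf_value(ln, c(G1 = -2)), "ln1p")
  expect_equal(cf_value(ln, c(G1 = exp(1) - 1)), 1)
})

test_that("gene matching in scoring is case-insensitive", {
  cf <- competing_factor(0, c(Fcar = 2))
  expect_equal(cf_value(cf, c(FCAR = 3)), 6)
})

test_that("panel risk is the logistic of the factor maximum", {
  f0 <- competing_factor(0, c(G1 = 1))
  expect_identical(panel_risk(max_logistic_panel(f0), c(G1 = 0)), 0.5)

  lone <- max_logistic_panel(competing_factor(-7.592, c(G1 = 1)))
  expect_equal(panel_risk(lone, c(G1 = 0)), plogis(-7.592))
  expect_lt(panel_risk(lone, c(G1 = 0)), 6e-4)

  two <- max_logistic_panel(list(competing_factor(-5, c(G1 = 1)),
                                 competing_factor(2, c(G2 = 1))))
  expect_equal(panel_risk(two, c(G1 = 0, G2 = 0)), plogis(2))

  # strictly increasing in CF_max, always inside (0,1)
  risks <- vapply(seq(-30, 30, by = 3), function(b)
    panel_risk(max_logistic_panel(competing_factor(b, c(G1 = 1))), c(G1 = 0)),
    numeric(1))
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks > 0 & risks < 1))
})

test_that("classification uses a strict risk threshold with ties to control", {
  m <- toy_matrix(c(0, 1, -1), "G1", c("s1", "s2", "s3"), scale = "log2")
  panel <- max_logistic_panel(competing_factor(0, c(G1 = 1)),
                              positive_class = "sepsis",
                              control_class = "healthy")
  got <- classify(panel, m)
  expect_identical(unname(got), c("healthy", "sepsis", "healthy"))

  always <- max_logistic_panel(competing_factor(10, c(G1 = 1e-12)),
                               positive_class = "sepsis",
                               control_class = "healthy")
  expect_true(all(classify(always, m) == "sepsis"))
})

test_that("evaluate computes confusion counts and self-consistent metrics", {
  labels <- sample_labels(c("a", "b", "c", "d"),
                          c("case", "case", "control", "control"),
                          "case", "control")
  preds <- c(a = "case", b = "case", c = "control", d = "case")
  rep <- evaluate(preds, labels)
  expect_equal(c(rep$tp, rep$fn, rep$tn, rep$fp), c(2, 0, 1, 1))
  expect_equal(rep$accuracy, 0.75)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 0.5)

  perfect <- evaluate(c(a = "case", b = "case", c = "control", d = "control"),
                      labels)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))

  # metrics recomputed from the report's own counts agree to 1e-12
  with(rep, {
    expect_equal(accuracy, (tp + tn) / (tp + tn + fp + fn), tolerance = 1e-12)
    expect_equal(sensitivity, tp / (tp + fn), tolerance = 1e-12)
    expect_equal(specificity, tn / (tn + fp), tolerance = 1e-12)
  })

  expect_error(evaluate(c(a = "case"), labels), "differ")
})

test_that("the bundled plasma classifier reproduces its printed 100% row", {
  fx <- load_fixture("table2_cohort")
  panel <- load_fixture("table4_panels")$selfcollected
  preds <- classify(panel, fx$matrix)
  expect_equal(sum(preds == "sepsis"), 32L)
  expect_equal(sum(preds == "healthy"), 18L)
  rep <- apply_panel(panel, fx$matrix, fx$labels)
  expect_identical(c(rep$accuracy, rep$sensitivity, rep$specificity), c(1, 1, 1))
})

test_that("appending a factor never lowers any sample's risk", {
  set.seed(42)
  m <- toy_matrix(runif(40, 0, 10), paste0("G", 1:4), paste0("s", 1:10))
  base <- list(competing_factor(-3, c(G1 = 0.5, G2 = -0.2)))
  extra <- competing_factor(-1, c(G3 = 0.3, G4 = 0.1))
  r1 <- panel_risks(max_logistic_panel(base), m)
  r2 <- panel_risks(max_logistic_panel(c(base, list(extra))), m)
  expect_true(all(r2 >= r1))

  # hence sensitivity cannot drop and specificity cannot rise
  labels <- sample_labels(paste0("s", 1:10),
                          rep(c("case", "control"), each = 5), "case", "control")
  e1 <- apply_panel(max_logistic_panel(base, "case", "control"), m, labels)
  e2 <- apply_panel(max_logistic_panel(c(base, list(extra)), "case", "control"),
                    m, labels)
  expect_gte(e2$sensitivity, e1$sensitivity)
  expect_lte(e2$specificity, e1$specificity)
})

test_that("samples built on a factor's boundary score risk 0.5", {
  all_panels <- c(load_fixture("table4_panels"), load_fixture("pbmc_panels"))
  for (panel in all_panels) {
    for (cf in panel$factors) {
      genes <- names(cf$coefficients)
      x <- setNames(rep(0, length(genes)), genes)
      target <- -cf$intercept  # remaining genes sit at 0, which transforms to 0
      # under ln1p pick a gene putting the solution on the positive branch,
      # where expm1/log1p invert each other at full precision
      g1 <- if (cf$transform == "ln1p")
        genes[sign(cf$coefficients) == sign(target)][1L] else genes[1L]
      val <- target / cf$coefficients[[g1]]
      x[g1] <- if (cf$transform == "ln1p") expm1(val) else val
      risk <- panel_risk(max_logistic_panel(cf, panel$positive_class,
                                            panel$control_class), x)
      expect_equal(risk, 0.5, tolerance = 1e-9)
    }
  }
})

test_that("panels round-trip through JSON bit-exactly", {
  panel <- max_logistic_panel(
    list(competing_factor(-2.7514 + 1e-13,
                          c(RNF4 = 1.0879, NONO = -6.577, PLEKHO1 = -9.6589)),
         competing_factor(1 / 3, c(G1 = pi), transform = "ln1p")),
    positive_class = "sepsis", control_class = "healthy",
    risk_threshold = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  panel_to_json(panel, path)
  back <- panel_from_json(path)
  expect_identical(back$factors[[1]]$coefficients, panel$factors[[1]]$coefficients)
  expect_identical(back$factors[[1]]$intercept, panel$factors[[1]]$intercept)
  expect_identical(back$factors[[2]]$coefficients, panel$factors[[2]]$coefficients)
  expect_identical(back$factors[[2]]$transform, "ln1p")
  expect_identical(back$risk_threshold, 0.25)
  expect_identical(back$positive_class, "sepsis")
})
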