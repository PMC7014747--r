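test_that("binarization follows the boundary conventions", {
  rec <- patient_row("x", age = 70, he4 = 800, ca125 = 200,
                     histology = "serous", grade = 3, figo_stage = "III",
                     ecog = 0, asa = "2")
  ind <- binarize_cohort(rec)
  expect_equal(
    unlist(ind[1, c("age", "figo_stage", "histology", "grade", "ca125",
                    "he4", "ecog", "asa")]),
    c(age = 1, figo_stage = 0, histology = 0, grade = 1, ca125 = 0,
      he4 = 1, ecog = 0, asa = 0)
  )

  benign <- binarize_cohort(patient_row("y"))
  expect_equal(sum(benign[1, -(1:2)]), 0)

  # closed boundary on the markers, strict on age and ECOG
  edge <- binarize_cohort(patient_row("z", he4 = 777.10, ca125 = 313.60,
                                      age = 68.5, ecog = 0))
  expect_equal(edge$he4, 1L)
  expect_equal(edge$ca125, 1L)
  expect_equal(edge$age, 0L)
  expect_equal(edge$ecog, 0L)
})

test_that("parameter diagnostics equal hand-computed confusion tables", {
  tab <- parameter_diagnostics(toy_cohort())
  he4_row <- tab[tab$parameter == "he4", ]
  # by hand: suboptimal a,b high / c low; optimal e high / d,f low
  expect_equal(
    unlist(he4_row[c("tp", "fp", "fn", "tn")]),
    c(tp = 2, fp = 1, fn = 1, tn = 2)
  )
  expect_equal(he4_row$sensitivity, 2 / 3)
  expect_equal(he4_row$specificity, 2 / 3)
  expect_equal(he4_row$ppv, 2 / 3)

  age_row <- tab[tab$parameter == "age", ]
  expect_equal(unlist(age_row[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 2, tn = 3))
  expect_equal(age_row$ppv, 1)

  expect_error(
    parameter_diagnostics(dplyr::filter(toy_cohort(), outcome == "optimal")),
    "single outcome class"
  )
})

test_that("an indicator identical to the outcome scores perfectly", {
  cohort <- toy_cohort()
  spec <- default_cutoff_spec()
  spec$asa <- function(r) r$outcome == "suboptimal"
  tab <- parameter_diagnostics(cohort, spec)
  asa_row <- tab[tab$parameter == "asa", ]
  expect_equal(asa_row$sensitivity, 1)
  expect_equal(asa_row$specificity, 1)
  expect_equal(asa_row$auc, 1)
})

test_that("PPV weighting reproduces the published point column", {
  model <- build_piv_model(published_parameter_metrics())
  expect_equal(model$weights$weight, c(2L, 1L, 2L, 1L, 1L, 2L, 2L, 1L))
  expect_equal(model$weights$weight, published_parameter_metrics()$point)
  expect_equal(model$max_score, 12)
})

test_that("selected-only weighting recovers the 0-8 score range", {
  model <- build_piv_model(published_parameter_metrics(),
                           mode = "selected_only")
  expect_setequal(model$weights$parameter,
                  c("age", "histology", "he4", "ecog"))
  expect_equal(model$max_score, 8)
  expect_error(
    build_piv_model(published_parameter_metrics(), mode = "selected_only",
                    ppv_min = 1.01),
    "no parameters selected"
  )
})

test_that("PIV scores are weight sums and the histogram conserves counts", {
  model <- build_piv_model(published_parameter_metrics())
  # positives on age (2), he4 (2), ca125 (1) -> PIV 5
  rec <- patient_row("x", outcome = "suboptimal", age = 70, he4 = 800,
                     ca125 = 400)
  two <- dplyr::bind_rows(rec, patient_row("y"))
  scored <- piv_scores(two, model)
  expect_equal(scored$piv, c(5L, 0L))

  all_pos <- patient_row("z", outcome = "suboptimal", age = 70,
                         figo_stage = "IV", histology = "other", grade = 3,
                         ca125 = 400, he4 = 800, ecog = 2, asa = "3plus")
  expect_equal(piv_scores(all_pos, model)$piv, 12L)

  cohort <- shared_cohort(n = 150)
  scored <- piv_scores(cohort, model)
  hist <- attr(scored, "histogram")
  expect_equal(hist$piv, 0:model$max_score)
  expect_equal(sum(hist$optimal) + sum(hist$suboptimal), 150)
  expect_equal(sum(hist$optimal), sum(cohort$outcome == "optimal"))
})

test_that("threshold sweep matches hand-enumerated tables and is monotone", {
  # scores where exactly 7 of 31 suboptimal reach 6; all 52 optimal below
  scores <- c(rep(6L, 7), rep(0L, 24), rep(0L, 52))
  truth <- c(rep("suboptimal", 31), rep("optimal", 52))
  sweep <- threshold_sweep(scores, truth, max_score = 8)
  row6 <- sweep[sweep$threshold == 6, ]
  expect_equal(row6$sensitivity, 7 / 31)
  expect_equal(row6$specificity, 1)
  expect_equal(row6$accuracy, 59 / 83)
  expect_equal(row6$npv, 52 / 76)
  expect_equal(round(100 * c(row6$accuracy, row6$specificity, row6$npv)),
               c(71, 100, 68))

  # hand-built toy sweep under the unit-weight model on he4 only
  toy <- threshold_sweep(c(1, 1, 0, 0, 1, 0), toy_cohort()$outcome, 1)
  expect_equal(unlist(toy[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 2))

  expect_error(threshold_sweep(1:3, c("optimal", "optimal", "optimal")),
               "both outcome classes")
})

test_that("sweep monotonicity holds on random synthetic cohorts", {
  model <- build_piv_model(published_parameter_metrics())
  for (seed in c(101, 202, 303)) {
    cohort <- generate_cohort(seed = seed, n = 120)
    scored <- piv_scores(cohort, model)
    sweep <- threshold_sweep(scored$piv, scored$outcome, model$max_score)
    expect_true(all(diff(sweep$sensitivity) <= 1e-12))
    expect_true(all(diff(sweep$specificity) >= -1e-12))
  }
})

test_that("PIV ranks suboptimal outcomes above optimal on large cohorts", {
  cohort <- generate_cohort(seed = 77, n = 2000)
  model <- build_piv_model(published_parameter_metrics())
  scored <- piv_scores(cohort, model)
  rho <- spearman_rho(scored$piv, as.integer(scored$outcome == "suboptimal"))
  expect_gt(rho, 0)
})
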