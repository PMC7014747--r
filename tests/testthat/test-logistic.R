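test_that("split_cohort gives round(n*fraction) sizes, disjoint and exhaustive", {
  cohort <- shared_cohort(n = 83)
  sp <- split_cohort(cohort, train_fraction = 43 / 83, seed = 4)
  expect_equal(nrow(sp$train), 43)
  expect_equal(nrow(sp$validation), 40)
  expect_length(intersect(sp$train$patient_id, sp$validation$patient_id), 0)
  expect_setequal(c(sp$train$patient_id, sp$validation$patient_id),
                  cohort$patient_id)

  again <- split_cohort(cohort, train_fraction = 43 / 83, seed = 4)
  expect_identical(sp$train$patient_id, again$train$patient_id)
  expect_error(split_cohort(cohort, train_fraction = 1.2), "\\(0, 1\\)")

  strat <- split_cohort(cohort, 0.5, seed = 4, stratify = TRUE)
  n_sub <- sum(cohort$outcome == "suboptimal")
  expect_equal(sum(strat$train$outcome == "suboptimal"),
               floor(n_sub * 0.5 + 0.5))
})

test_that("IRLS matches glm and the intercept-only closed form", {
  # intercept-only on balanced outcomes: logit(0.5) = 0
  fit0 <- fit_logistic_irls(NULL, rep(c(0, 1), 25))
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-10)

  set.seed(8)
  n <- 300
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, "a"] - 1.2 * x[, "b"]))
  ours <- fit_logistic_irls(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # glm stops on a looser deviance criterion, so SEs agree a bit less tightly
  expect_equal(unname(ours$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
  expect_equal(tail(ours$loglik, 1), as.numeric(logLik(ref)),
               tolerance = 1e-8)
})

test_that("IRLS log-likelihood is non-decreasing across iterations", {
  set.seed(15)
  for (i in 1:10) {
    n <- 120
    x <- matrix(rnorm(n * 2), ncol = 2)
    y <- rbinom(n, 1, plogis(x %*% c(1, -1)))
    fit <- fit_logistic_irls(x, y)
    expect_true(all(diff(fit$loglik) >= -1e-8))
  }
})

test_that("separation and degenerate designs raise explicit errors", {
  y <- rep(c(0, 1), each = 20)
  x_sep <- matrix(y * 2 - 1, ncol = 1)
  expect_error(fit_logistic_irls(x_sep, y), "separation")
  x_const <- matrix(1, nrow = 40, ncol = 1)
  expect_error(fit_logistic_irls(x_const, y), "zero-variance")
  expect_error(fit_logistic_irls(matrix(rnorm(4), 2), c(0, 1)),
               "more observations")
})

test_that("a single binary predictor reproduces the 2x2 cross-product ratio", {
  # table a=10 (x=1,y=1), b=5 (x=1,y=0), c=5 (x=0,y=1), d=10 (x=0,y=0)
  x <- matrix(rep(c(1, 1, 0, 0), c(10, 5, 5, 10)), ncol = 1)
  y <- rep(c(1, 0, 1, 0), c(10, 5, 5, 10))
  fit <- fit_logistic_irls(x, y)
  expect_equal(exp(fit$coefficients[[2]]), 4.0, tolerance = 1e-6)
  expect_equal(fit$se[[2]], sqrt(1 / 10 + 1 / 5 + 1 / 5 + 1 / 10),
               tolerance = 1e-6)
})

test_that("univariate screens behave on independent and separated predictors", {
  set.seed(33)
  cohort <- generate_cohort(seed = 33, n = 4000)
  # shuffle outcomes so every predictor is independent of outcome
  shuffled <- dplyr::mutate(cohort, outcome = sample(outcome))
  screen <- univariate_screen(shuffled)
  ors <- screen$odds.ratio[screen$term != "age"]
  expect_true(all(abs(log(ors)) < 0.3))

  sep <- dplyr::mutate(
    cohort[1:40, ],
    he4 = ifelse(outcome == "suboptimal", 1000, 10)
  )
  expect_error(univariate_screen(sep), "separation|converge")
})

test_that("the published equation is applied verbatim", {
  model <- published_model()
  base <- patient_row("p", age = 50, histology = "other")
  enc <- encode_covariates(base)
  expect_equal(enc$ca125_high, 0L)
  # zero out every covariate contribution except the intercept
  zero_like <- published_model_predict(base,
    model = structure(c(`(Intercept)` = -3.37, age = 0, ca125_high = -2.38,
                        he4_high = -1.86, histology_serous = -2.74),
                      class = "published_model"))
  expect_equal(zero_like$linear_predictor, -3.37)
  expect_equal(zero_like$probability, plogis(-3.37), tolerance = 1e-12)
  expect_equal(zero_like$probability, 0.0333, tolerance = 2e-3)

  # age 69, all three indicators 1
  loaded <- patient_row("q", age = 69, ca125 = 400, he4 = 800,
                        histology = "serous")
  pred <- published_model_predict(loaded)
  expect_equal(pred$linear_predictor, 0.12 * 69 - 2.38 - 1.86 - 2.74 - 3.37,
               tolerance = 1e-12)
  expect_equal(pred$linear_predictor, -2.07, tolerance = 1e-10)
  expect_equal(pred$probability, 0.112, tolerance = 1e-3)

  # the printed age coefficient is consistent with its printed odds ratio
  expect_equal(round(log(1.13), 2), unname(model["age"]))
})

test_that("Hosmer-Lemeshow matches hand-computed group chi-squares", {
  # calibrated by construction: statistic 0
  p <- rep(c(0.2, 0.8), each = 10)
  y <- rep(c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2)), 1)
  hl <- hosmer_lemeshow(p, y, groups = 2)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$df, 0)

  # 4 events in the low group: (4-2)^2/2 + (6-8)^2/8 = 2.5 contribution
  y2 <- c(rep(1, 4), rep(0, 6), rep(1, 8), rep(0, 2))
  hl2 <- hosmer_lemeshow(p, y2, groups = 2)
  expect_equal(hl2$statistic, 2.5, tolerance = 1e-12)

  expect_error(hosmer_lemeshow(rep(0.5, 40), rbinom(40, 1, 0.5)),
               "distinct probabilities")
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), groups = 10),
               "too few observations")
})

test_that("validation evaluation agrees with a brute-force all-pairs oracle", {
  perfect <- evaluate_validation(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(1, 1))

  probs <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.2)
  truth <- c(0, 1, 0, 1, 0, 1)
  res <- evaluate_validation(probs, truth)
  pos <- probs[truth == 1]
  neg <- probs[truth == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(res$auc, mean(pairs), tolerance = 1e-12)

  set.seed(5)
  big <- rbinom(4000, 1, 0.4)
  noise <- runif(4000)
  expect_equal(evaluate_validation(noise, big)$auc, 0.5, tolerance = 0.03)
})
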