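#' Encode cohort covariates for logistic modelling
#'
#' Builds the covariate encoding used by the logistic pathway: continuous
#' age in years, indicators for CA125 and HE4 above their cutoffs, a serous-
#' histology indicator, and the outcome coded suboptimal = 1.
#'
#' @param cohort A cohort data frame.
#' @param ca125_cutoff,he4_cutoff Marker cutoffs; defaults are the published
#'   values (313.60 U/ml, 777.10 pmol/L).
#' @return A tibble with `patient_id`, `age`, `ca125_high`, `he4_high`,
#'   `histology_serous`, and `outcome` (0/1).
#' @export
encode_covariates <- function(cohort, ca125_cutoff = 313.60,
                              he4_cutoff = 777.10) {
  cohort <- validate_cohort(cohort)
  tibble::tibble(
    patient_id = cohort$patient_id,
    age = cohort$age,
    ca125_high = as.integer(cohort$ca125 >= ca125_cutoff),
    he4_high = as.integer(cohort$he4 >= he4_cutoff),
    histology_serous = as.integer(cohort$histology == "serous"),
    outcome = as.integer(cohort$outcome == "suboptimal")
  )
}

#' Split a cohort into training and validation sets
#'
#' Random, disjoint and exhaustive split, reproducible by seed. The training
#' size is `round(n * train_fraction)` with half-up rounding; the remainder
#' forms the validation set. Optionally stratified by outcome.
#'
#' @param cohort A cohort data frame with at least 4 rows.
#' @param train_fraction Fraction in (0, 1); `43/83` reproduces a 43/40
#'   split of an 83-patient cohort.
#' @param seed Integer RNG seed.
#' @param stratify If `TRUE`, split each outcome group separately so both
#'   sets keep the cohort's class balance.
#' @return A list with cohorts `train` and `validation`.
#' @export
split_cohort <- function(cohort, train_fraction = 0.5, seed = 1L,
                         stratify = FALSE) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) < 4) abort("cohort too small to split (need >= 4)")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1)")
  }
  with_seed(seed, {
    if (stratify) {
      idx <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$outcome),
        function(g) sample(g, round_half_up(length(g) * train_fraction))
      ), use.names = FALSE)
    } else {
      idx <- sample(seq_len(nrow(cohort)),
                    round_half_up(nrow(cohort) * train_fraction))
    }
    idx <- sort(idx)
    list(
      train = cohort[idx, , drop = FALSE],
      validation = cohort[-idx, , drop = FALSE]
    )
  })
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted with Newton/IRLS updates.
#' Convergence is declared when the maximum absolute score (gradient of the
#' log-likelihood) falls below `tol`. Complete or quasi-complete separation
#' is reported as an explicit error (diverging coefficients with fitted
#' probabilities collapsing to 0/1), never returned as a silent fit.
#'
#' @param x Numeric design matrix (no intercept column; one is added). May
#'   have zero columns for an intercept-only fit.
#' @param y 0/1 outcome vector (1 = suboptimal cytoreduction).
#' @param tol Convergence tolerance on the score, default 1e-8.
#' @param max_iter Maximum IRLS iterations, default 50.
#' @return An object of class `logistic_fit`: coefficients, standard errors,
#'   odds ratios with 95% Wald intervals, log-likelihood trace, and fitted
#'   probabilities. Access tidily via `tidy()` / `glance()`.
#' @export
fit_logistic_irls <- function(x, y, tol = 1e-8, max_iter = 50) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be a 0/1 vector")
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort("`x` and `y` sizes disagree")
  if (ncol(x) > 0 && any(apply(x, 2, sd) == 0)) {
    abort("design matrix has a zero-variance column")
  }
  X <- cbind(`(Intercept)` = 1, x)
  p_terms <- ncol(X)
  if (length(y) <= p_terms) abort("need more observations than model terms")

  beta <- rep(0, p_terms)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    # numerically stable Bernoulli log-likelihood
    loglik <- c(loglik, sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta)))))
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 1e3 || all(w < 1e-10)) {
      abort(paste(
        "logistic fit did not converge: coefficients are diverging,",
        "which indicates complete or quasi-complete separation"
      ))
    }
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) {
      abort("singular information matrix: rank-deficient design or separation")
    })
    beta <- beta + step
  }
  if (!converged) {
    abort(paste(
      "logistic fit did not converge within", max_iter,
      "iterations (possible separation)"
    ))
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * w, X)
  vcov <- tryCatch(solve(info), error = function(e) {
    abort("singular information matrix at the optimum (separation)")
  })
  se <- sqrt(diag(vcov))
  if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
    abort("fitted probabilities numerically 0 or 1: complete separation")
  }
  structure(
    list(
      coefficients = setNames(drop(beta), colnames(X)),
      se = setNames(se, colnames(X)),
      vcov = vcov,
      fitted = mu,
      loglik = loglik,
      iterations = iter,
      converged = converged,
      n = length(y)
    ),
    class = "logistic_fit"
  )
}

#' Fit the suboptimal-cytoreduction logistic model on a cohort
#'
#' Convenience wrapper: encodes the cohort via [encode_covariates()] and
#' fits outcome ~ age + ca125_high + he4_high + histology_serous by IRLS.
#'
#' @inheritParams encode_covariates
#' @param ... Passed to [fit_logistic_irls()].
#' @return A `logistic_fit`.
#' @export
fit_cohort_logistic <- function(cohort, ca125_cutoff = 313.60,
                                he4_cutoff = 777.10, ...) {
  enc <- encode_covariates(cohort, ca125_cutoff, he4_cutoff)
  x <- as.matrix(enc[c("age", "ca125_high", "he4_high", "histology_serous")])
  fit_logistic_irls(x, enc$outcome, ...)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit (IRLS, %d iterations, n = %d)\n", x$iterations, x$n
  ))
  print(tidy(x))
  invisible(x)
}

#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- x$coefficients
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(est / x$se),
    p.value = 2 * pnorm(-abs(unname(est / x$se))),
    odds.ratio = exp(unname(est)),
    conf.low = exp(unname(est - z * x$se)),
    conf.high = exp(unname(est + z * x$se))
  )
}

#' @method glance logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  ll <- tail(x$loglik, 1)
  tibble::tibble(
    logLik = ll,
    AIC = -2 * ll + 2 * length(x$coefficients),
    nobs = x$n,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Univariate logistic screens
#'
#' Fits one single-predictor logistic model per encoded covariate. For a
#' binary predictor the fitted odds ratio equals the 2x2 cross-product
#' ratio.
#'
#' @inheritParams encode_covariates
#' @return A tibble of tidied single-predictor fits (non-intercept rows),
#'   one per covariate.
#' @export
univariate_screen <- function(cohort, ca125_cutoff = 313.60,
                              he4_cutoff = 777.10) {
  enc <- encode_covariates(cohort, ca125_cutoff, he4_cutoff)
  vars <- c("age", "ca125_high", "he4_high", "histology_serous")
  purrr::map_dfr(vars, function(v) {
    fit <- fit_logistic_irls(as.matrix(enc[v]), enc$outcome)
    tidy(fit) |> dplyr::filter(.data$term != "(Intercept)")
  })
}

#' The published logistic scoring equation
#'
#' The fixed coefficient vector of the originally reported model:
#' `logit p = 0.12 age - 2.38 ca125_high - 1.86 he4_high -
#' 2.74 histology_serous - 3.37`, with age in years and the three
#' indicators per [encode_covariates()]. The printed equation is applied
#' verbatim as a scorer; its sign conventions are internally inconsistent
#' in the source, so the raw linear predictor is exposed rather than
#' reinterpreted.
#'
#' @return A named numeric coefficient vector of class `published_model`.
#' @export
published_model <- function() {
  structure(
    c(
      `(Intercept)` = -3.37, age = 0.12, ca125_high = -2.38,
      he4_high = -1.86, histology_serous = -2.74
    ),
    class = "published_model"
  )
}

#' Score patients with the published equation
#'
#' @param cohort A cohort data frame.
#' @param model A `published_model` (default) or any named coefficient
#'   vector over the same terms.
#' @inheritParams encode_covariates
#' @return A tibble with `patient_id`, `linear_predictor` and `probability`
#'   (inverse-logit of the linear predictor).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' published_model_predict(cohort)
published_model_predict <- function(cohort, model = published_model(),
                                    ca125_cutoff = 313.60,
                                    he4_cutoff = 777.10) {
  enc <- encode_covariates(cohort, ca125_cutoff, he4_cutoff)
  coefs <- unclass(model)
  X <- cbind(
    `(Intercept)` = 1, age = enc$age, ca125_high = enc$ca125_high,
    he4_high = enc$he4_high, histology_serous = enc$histology_serous
  )
  lp <- drop(X[, names(coefs), drop = FALSE] %*% coefs)
  tibble::tibble(
    patient_id = enc$patient_id,
    linear_predictor = lp,
    probability = plogis(lp)
  )
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk calibration test: patients are grouped by predicted
#' probability quantiles (ties kept together), and the statistic sums
#' `(O - E)^2 / E` over groups and both outcome classes, with E the summed
#' probabilities. Degrees of freedom are `groups - 2`.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param outcomes Outcome labels (1/TRUE/"suboptimal" = event).
#' @param groups Number of risk groups, default 10.
#' @return A tibble with `statistic`, `df`, `p.value`, `groups`.
#' @export
hosmer_lemeshow <- function(probabilities, outcomes, groups = 10) {
  y <- as.numeric(as_positive(outcomes))
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) abort("inputs must have equal length")
  if (length(p) < 2 * groups) {
    abort("too few observations for the requested number of groups")
  }
  breaks <- unique(quantile(p, probs = seq(0, 1, length.out = groups + 1)))
  if (length(breaks) < 3) {
    abort("too few distinct probabilities; use fewer groups")
  }
  g <- cut(p, breaks = breaks, include.lowest = TRUE)
  n_g <- length(levels(g))
  obs1 <- tapply(y, g, sum)
  exp1 <- tapply(p, g, sum)
  n_per <- tapply(y, g, length)
  obs0 <- n_per - obs1
  exp0 <- n_per - exp1
  contrib1 <- ifelse(exp1 > 0, (obs1 - exp1)^2 / exp1, 0)
  contrib0 <- ifelse(exp0 > 0, (obs0 - exp0)^2 / exp0, 0)
  stat <- sum(contrib1 + contrib0)
  df <- n_g - 2
  tibble::tibble(
    statistic = stat, df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE),
    groups = n_g
  )
}

#' Evaluate predicted probabilities on a validation set
#'
#' Discrimination summary of a probability scorer on held-out patients:
#' AUC with Hanley-McNeil standard error and CI, plus sensitivity and
#' specificity at the Youden-optimal probability cutoff.
#'
#' @param probabilities Predicted probabilities of suboptimal cytoreduction.
#' @param truth Outcome labels, both classes present.
#' @param level Confidence level for the AUC interval.
#' @return A one-row tibble: `auc`, `auc_se`, `conf.low`, `conf.high`,
#'   `cutoff`, `sensitivity`, `specificity`.
#' @export
evaluate_validation <- function(probabilities, truth, level = 0.95) {
  roc <- roc_auc(probabilities, truth)
  ci <- auc_se_ci_hanley(roc$auc, roc$n_pos, roc$n_neg, level)
  yj <- youden_cutoff(probabilities, truth)
  tibble::tibble(
    auc = roc$auc, auc_se = ci$se,
    conf.low = ci$conf.low, conf.high = ci$conf.high,
    cutoff = yj$cutoff,
    sensitivity = yj$sensitivity,
    specificity = yj$specificity
  )
}
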