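#' Moment-matched log-normal parameters
#'
#' Given a target mean and SD on the natural scale, returns the log-scale
#' parameters of the log-normal distribution with exactly those moments:
#' `sdlog^2 = log(1 + (sd/mean)^2)` and `meanlog = log(mean) - sdlog^2 / 2`.
#' Used for serum markers, whose SDs are comparable to (or exceed) their
#' means, ruling out a Gaussian model for a positive quantity.
#'
#' @param mean Target arithmetic mean (> 0).
#' @param sd Target arithmetic SD (>= 0).
#' @return A list with `meanlog` and `sdlog`.
#' @export
#' @examples
#' p <- lognormal_params_from_moments(997.44, 1050.33)
#' exp(p$meanlog + p$sdlog^2 / 2) # recovers the mean
lognormal_params_from_moments <- function(mean, sd) {
  assert_scalar_number(mean, "mean")
  assert_scalar_number(sd, "sd", lower = 0)
  if (mean <= 0) abort("`mean` must be > 0 for a log-normal model")
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Default synthetic-cohort configuration
#'
#' Returns the generator configuration calibrated to the characteristics
#' table of the 83-patient advanced epithelial ovarian cancer cohort the
#' package models: 52 optimal / 31 suboptimal cytoreductions, outcome-
#' conditional Gaussian age (truncated to \[18, 90\]), moment-matched
#' log-normal CA125 and HE4, and outcome-conditional categorical frequencies
#' for FIGO stage, grade, histology, ECOG and ASA.
#'
#' @return A list of class `synthetic_config` with elements `n`,
#'   `p_suboptimal`, and per-group distribution parameters.
#' @export
default_cohort_config <- function() {
  cfg <- list(
    n = 83L,
    p_suboptimal = 31 / 83,
    age = list(
      optimal = list(mean = 52.13, sd = 9.81),
      suboptimal = list(mean = 56.45, sd = 11.24),
      lower = 18, upper = 90
    ),
    ca125 = list(
      optimal = list(mean = 1285.57, sd = 1662.24),
      suboptimal = list(mean = 1219.36, sd = 1341.36)
    ),
    he4 = list(
      optimal = list(mean = 419.96, sd = 355.56),
      suboptimal = list(mean = 997.44, sd = 1050.33)
    ),
    categorical = list(
      figo_stage = list(
        levels = c("III", "IV"),
        optimal = c(46, 6) / 52,
        suboptimal = c(28, 3) / 31
      ),
      grade = list(
        levels = c("1", "2", "3"),
        # grades 1-2 are pooled in the source table; split evenly
        optimal = c(9, 9, 34) / 52,
        suboptimal = c(5, 5, 21) / 31
      ),
      histology = list(
        levels = c("serous", "other"),
        optimal = c(45, 7) / 52,
        suboptimal = c(23, 8) / 31
      ),
      ecog = list(
        levels = c("0", "1", "2"),
        optimal = c(45, 6, 1) / 52,
        suboptimal = c(24, 3, 4) / 31
      ),
      asa = list(
        levels = c("1", "2", "3plus"),
        optimal = c(5, 44, 3) / 52,
        suboptimal = c(4, 25, 2) / 31
      )
    )
  )
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(config) {
  if (!is.list(config)) abort("`config` must be a synthetic_config list")
  assert_scalar_number(config$n, "n", lower = 1)
  assert_scalar_number(config$p_suboptimal, "p_suboptimal")
  if (config$p_suboptimal <= 0 || config$p_suboptimal >= 1) {
    abort("`p_suboptimal` must be in (0, 1)")
  }
  for (v in names(config$categorical)) {
    for (g in c("optimal", "suboptimal")) {
      p <- config$categorical[[v]][[g]]
      if (any(p < 0)) abort(sprintf("negative category probability in %s", v))
      if (abs(sum(p) - 1) > 1e-9) {
        abort(sprintf("category probabilities for %s/%s do not sum to 1", v, g))
      }
    }
  }
  invisible(config)
}

# Truncated-normal draw by resampling; at the default age parameters the
# truncation to [18, 90] is essentially inactive (mean shift < 0.1%).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` patients: the outcome is Bernoulli(`p_suboptimal`) (or
#' fixed group counts via `outcome_counts`), and all covariates are drawn
#' independently from the outcome-conditional distributions in `config`.
#' Fully reproducible given `seed`; a single RNG stream is used and records
#' are drawn in order.
#'
#' @param config A `synthetic_config`, e.g. [default_cohort_config()].
#' @param seed Integer RNG seed.
#' @param n Optional override of `config$n`.
#' @param outcome_counts Optional named vector `c(optimal =, suboptimal =)`
#'   fixing the group sizes exactly instead of Bernoulli sampling (useful for
#'   worked examples that condition on observed counts). Must sum to `n`.
#' @return A validated cohort tibble with a `provenance` attribute recording
#'   the seed.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(), seed = 1)
#' dplyr::count(cohort, outcome)
generate_cohort <- function(config = default_cohort_config(), seed = 1L,
                            n = NULL, outcome_counts = NULL) {
  validate_config(config)
  n <- as.integer(n %||% config$n)
  with_seed(seed, {
    if (is.null(outcome_counts)) {
      outcome <- ifelse(runif(n) < config$p_suboptimal, "suboptimal", "optimal")
    } else {
      if (sum(outcome_counts) != n) {
        abort("`outcome_counts` must sum to the cohort size")
      }
      outcome <- sample(rep(
        c("optimal", "suboptimal"),
        c(outcome_counts[["optimal"]], outcome_counts[["suboptimal"]])
      ))
    }
    age <- ca125 <- he4 <- numeric(n)
    cats <- list()
    for (g in c("optimal", "suboptimal")) {
      idx <- which(outcome == g)
      if (length(idx) == 0) next
      a <- config$age[[g]]
      age[idx] <- rnorm_trunc(
        length(idx), a$mean, a$sd,
        config$age$lower %||% 18, config$age$upper %||% 90
      )
      for (m in c("ca125", "he4")) {
        p <- lognormal_params_from_moments(config[[m]][[g]]$mean, config[[m]][[g]]$sd)
        val <- rlnorm(length(idx), p$meanlog, p$sdlog)
        if (m == "ca125") ca125[idx] <- val else he4[idx] <- val
      }
      for (v in names(config$categorical)) {
        spec <- config$categorical[[v]]
        cats[[v]] <- cats[[v]] %||% character(n)
        cats[[v]][idx] <- sample(spec$levels, length(idx),
          replace = TRUE, prob = spec[[g]]
        )
      }
    }
    out <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = age,
      figo_stage = cats$figo_stage,
      grade = as.integer(cats$grade),
      histology = cats$histology,
      ca125 = ca125,
      he4 = he4,
      ecog = as.integer(cats$ecog),
      asa = cats$asa,
      outcome = outcome
    )
    out <- validate_cohort(out)
    attr(out, "provenance") <- sprintf("synthetic seed=%s n=%d", seed, n)
    out
  })
}
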