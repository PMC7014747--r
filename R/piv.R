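#' Default dichotomization rules for PIV parameters
#'
#' Returns the cutoff specification mapping each clinicopathological
#' parameter to a binary risk indicator (1 = points toward suboptimal
#' cytoreduction): age > 68.5 years, FIGO stage IV, non-serous histology,
#' grade 3, CA125 >= 313.60 U/ml, HE4 >= 777.10 pmol/L, ECOG > 0, and
#' ASA class >= 3. Markers and ASA use a closed (>=) boundary; age and ECOG
#' use a strict (>) boundary, matching cutoffs placed between attainable
#' values.
#'
#' @param age_cutoff,ca125_cutoff,he4_cutoff Numeric cutoffs for the
#'   continuous parameters, overriding the defaults (e.g. with cohort-specific
#'   Youden cutoffs from [youden_cutoff()]).
#' @return A named list of predicate functions, one per parameter, in the
#'   canonical parameter order.
#' @export
default_cutoff_spec <- function(age_cutoff = 68.5, ca125_cutoff = 313.60,
                                he4_cutoff = 777.10) {
  list(
    age = function(r) r$age > age_cutoff,
    figo_stage = function(r) r$figo_stage == "IV",
    histology = function(r) r$histology == "other",
    grade = function(r) r$grade == 3,
    ca125 = function(r) r$ca125 >= ca125_cutoff,
    he4 = function(r) r$he4 >= he4_cutoff,
    ecog = function(r) r$ecog > 0,
    asa = function(r) r$asa == "3plus"
  )
}

piv_parameters <- c(
  "age", "figo_stage", "histology", "grade", "ca125", "he4", "ecog", "asa"
)

#' Binarize a cohort into risk indicators
#'
#' Applies a cutoff specification to every patient, producing one 0/1
#' indicator column per parameter.
#'
#' @param cohort A cohort data frame.
#' @param spec A cutoff specification from [default_cutoff_spec()].
#' @return A tibble with `patient_id`, `outcome`, and an integer indicator
#'   column per parameter.
#' @export
binarize_cohort <- function(cohort, spec = default_cutoff_spec()) {
  cohort <- validate_cohort(cohort)
  out <- tibble::tibble(
    patient_id = cohort$patient_id, outcome = cohort$outcome
  )
  for (p in names(spec)) {
    out[[p]] <- as.integer(spec[[p]](cohort))
  }
  out
}

#' Per-parameter diagnostic efficacy table
#'
#' For each dichotomized parameter, computes the full set of diagnostic
#' metrics of its indicator against the surgical outcome, plus the AUC of
#' the underlying score (raw values for continuous markers and age; the 0/1
#' indicator for the categorical parameters).
#'
#' @inheritParams binarize_cohort
#' @return A tibble with one row per parameter: `parameter`, the counts and
#'   metrics from [diagnostic_metrics()], and `auc`.
#' @export
parameter_diagnostics <- function(cohort, spec = default_cutoff_spec()) {
  cohort <- validate_cohort(cohort)
  if (length(unique(cohort$outcome)) < 2) {
    abort("cannot compare groups: cohort contains a single outcome class")
  }
  ind <- binarize_cohort(cohort, spec)
  continuous_score <- list(
    age = cohort$age, ca125 = cohort$ca125, he4 = cohort$he4
  )
  purrr::map_dfr(names(spec), function(p) {
    metrics <- diagnostic_metrics(confusion_table(
      cohort$outcome, ind[[p]] == 1
    ))
    score <- continuous_score[[p]] %||% ind[[p]]
    dplyr::bind_cols(
      tibble::tibble(parameter = p), metrics,
      tibble::tibble(auc = roc_auc(score, cohort$outcome)$auc)
    )
  })
}

#' Published per-parameter diagnostic metrics
#'
#' The printed diagnostic-efficacy table of the original 83-patient cohort
#' (sensitivity, specificity, PPV, NPV, accuracy, AUC and point weight per
#' parameter at the published cutoffs). Because the patient-level data were
#' never deposited, these printed metrics are the reference input for
#' reconstructing the published PIV point weights.
#'
#' @return A tibble with one row per parameter in canonical order.
#' @export
published_parameter_metrics <- function() {
  tibble::tribble(
    ~parameter,    ~cutoff, ~sensitivity, ~specificity, ~ppv, ~npv, ~accuracy, ~auc,  ~point,
    "age",         68.5,    0.16,         0.98,         0.83, 0.66, 0.67,      0.57,  2L,
    "figo_stage",  NA,      0.10,         0.89,         0.33, 0.62, 0.59,      0.49,  1L,
    "histology",   NA,      0.26,         0.87,         0.53, 0.66, 0.64,      0.56,  2L,
    "grade",       NA,      0.68,         0.35,         0.38, 0.64, 0.47,      0.51,  1L,
    "ca125",       313.60,  0.81,         0.42,         0.45, 0.79, 0.57,      0.53,  1L,
    "he4",         777.10,  0.48,         0.89,         0.71, 0.74, 0.73,      0.68,  2L,
    "ecog",        NA,      0.23,         0.87,         0.50, 0.65, 0.63,      0.55,  2L,
    "asa",         NA,      0.07,         0.94,         0.40, 0.63, 0.61,      0.50,  1L
  )
}

#' Build a Predictive Index Value (PIV) model
#'
#' Turns a per-parameter diagnostics table into a points-based score.
#' Two weighting modes are supported:
#' \describe{
#'   \item{`"ppv_weighted"` (default)}{all parameters are included; a
#'     parameter scores 2 points if its PPV >= `ppv_min`, else 1 point. On
#'     the published metrics this reproduces the printed point column
#'     (2,1,2,1,1,2,2,1).}
#'   \item{`"selected_only"`}{only parameters with PPV >= `ppv_min` and
#'     NPV >= `npv_min` (and accuracy >= `accuracy_min`) are included, each
#'     at 2 points — on the published metrics this selects age, histology,
#'     HE4 and ECOG, giving the 0-8 score range.}
#' }
#'
#' @param rows A parameter-diagnostics tibble ([parameter_diagnostics()] or
#'   [published_parameter_metrics()]).
#' @param mode Weighting mode, see above.
#' @param ppv_min,npv_min Predictive-value thresholds, default 0.5.
#' @param accuracy_min Accuracy threshold used in `selected_only` mode,
#'   default 0 (no constraint).
#' @return An object of class `piv_model`: list with a `weights` tibble
#'   (`parameter`, `weight`) and `max_score`.
#' @export
#' @examples
#' build_piv_model(published_parameter_metrics())
build_piv_model <- function(rows, mode = c("ppv_weighted", "selected_only"),
                            ppv_min = 0.5, npv_min = 0.5, accuracy_min = 0) {
  mode <- match.arg(mode)
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) abort("`rows` must contain at least one parameter")
  if (mode == "ppv_weighted") {
    weights <- rows |>
      dplyr::transmute(
        parameter = .data$parameter,
        weight = ifelse(!is.na(.data$ppv) & .data$ppv >= ppv_min, 2L, 1L)
      )
  } else {
    weights <- rows |>
      dplyr::filter(
        !is.na(.data$ppv), .data$ppv >= ppv_min,
        !is.na(.data$npv), .data$npv >= npv_min,
        .data$accuracy >= accuracy_min
      ) |>
      dplyr::transmute(parameter = .data$parameter, weight = 2L)
    if (nrow(weights) == 0) {
      abort("no parameters selected: all fall below the PPV/NPV/accuracy thresholds")
    }
  }
  structure(
    list(
      weights = weights,
      max_score = sum(weights$weight),
      mode = mode
    ),
    class = "piv_model"
  )
}

#' @export
print.piv_model <- function(x, ...) {
  cat(sprintf(
    "PIV model (%s): %d parameters, score range 0-%d\n",
    x$mode, nrow(x$weights), x$max_score
  ))
  print(x$weights)
  invisible(x)
}

#' @method tidy piv_model
#' @export
tidy.piv_model <- function(x, ...) x$weights

#' @method glance piv_model
#' @export
glance.piv_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x$weights), max_score = x$max_score, mode = x$mode
  )
}

#' Score patients with a PIV model
#'
#' Each patient's PIV is the weight-sum of their positive risk indicators
#' over the model's included parameters.
#'
#' @inheritParams binarize_cohort
#' @param model A `piv_model` from [build_piv_model()].
#' @return A tibble with `patient_id`, `outcome`, `piv` (integer score). The
#'   attribute `"histogram"` holds the score-by-outcome frequency table
#'   covering 0..`max_score`.
#' @export
piv_scores <- function(cohort, model, spec = default_cutoff_spec()) {
  ind <- binarize_cohort(cohort, spec)
  missing_par <- setdiff(model$weights$parameter, names(ind))
  if (length(missing_par) > 0) {
    abort(sprintf(
      "cutoff spec lacks parameter(s): %s", paste(missing_par, collapse = ", ")
    ))
  }
  w <- setNames(model$weights$weight, model$weights$parameter)
  score_mat <- as.matrix(ind[names(w)])
  out <- tibble::tibble(
    patient_id = ind$patient_id,
    outcome = ind$outcome,
    piv = as.integer(score_mat %*% w)
  )
  hist <- out |>
    dplyr::count(
      piv = factor(.data$piv, levels = 0:model$max_score),
      .data$outcome, .drop = FALSE
    ) |>
    dplyr::mutate(piv = as.integer(as.character(.data$piv))) |>
    tidyr::pivot_wider(
      names_from = "outcome", values_from = "n", values_fill = 0L
    )
  for (col in c("optimal", "suboptimal")) {
    if (!col %in% names(hist)) hist[[col]] <- 0L
  }
  attr(out, "histogram") <- hist[c("piv", "optimal", "suboptimal")]
  out
}

#' Threshold sweep of a PIV score
#'
#' Evaluates the rule "PIV >= t flags suboptimal" for every threshold
#' t = 1..max_score, returning the full diagnostic-metric row per threshold.
#' By construction sensitivity is non-increasing and specificity
#' non-decreasing in the threshold; this is verified as a post-check.
#'
#' @param scores Integer PIV scores (e.g. `piv_scores()$piv`).
#' @param truth Outcome labels, both classes present.
#' @param max_score Largest threshold to evaluate; defaults to `max(scores)`.
#' @return An object of class `piv_sweep`: a tibble with `threshold` and the
#'   [diagnostic_metrics()] columns.
#' @export
threshold_sweep <- function(scores, truth, max_score = max(scores)) {
  pos <- as_positive(truth)
  if (!any(pos) || all(pos)) {
    abort("both outcome classes must be present for a threshold sweep")
  }
  rows <- purrr::map_dfr(seq_len(max(1, max_score)), function(t) {
    dplyr::bind_cols(
      tibble::tibble(threshold = t),
      diagnostic_metrics(confusion_table(pos, scores >= t))
    )
  })
  sens_ok <- all(diff(rows$sensitivity) <= 1e-12)
  spec_ok <- all(diff(rows$specificity) >= -1e-12)
  if (!sens_ok || !spec_ok) {
    abort("internal error: threshold sweep violated monotonicity")
  }
  structure(rows, class = c("piv_sweep", class(rows)))
}

#' @method autoplot piv_sweep
#' @export
autoplot.piv_sweep <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("threshold", "sensitivity", "specificity", "accuracy") |>
    tidyr::pivot_longer(-"threshold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$threshold)) +
    ggplot2::labs(
      x = "PIV threshold (score >= t flags suboptimal)", y = "Metric value",
      colour = NULL
    )
}

#' Plot the PIV score distribution by surgical outcome
#'
#' @param scores The result of [piv_scores()].
#' @return A ggplot object (stacked frequency bars by outcome).
#' @export
plot_piv_histogram <- function(scores) {
  hist <- attr(scores, "histogram")
  if (is.null(hist)) {
    hist <- scores |>
      dplyr::count(piv = .data$piv, .data$outcome) |>
      tidyr::pivot_wider(
        names_from = "outcome", values_from = "n", values_fill = 0L
      )
  }
  long <- tidyr::pivot_longer(hist, -"piv",
    names_to = "outcome", values_to = "n"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$piv, y = .data$n, fill = .data$outcome
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "PIV score", y = "Patients", fill = "Cytoreduction")
}
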