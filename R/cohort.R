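#' Patient cohort tables
#'
#' A cohort is an ordinary tibble with one row per patient and the columns
#' listed below. The positive class throughout the package is *suboptimal*
#' cytoreduction (residual disease after primary debulking surgery).
#'
#' Required columns:
#' \describe{
#'   \item{patient_id}{unique identifier (character)}
#'   \item{age}{years, in \[18, 100\]}
#'   \item{figo_stage}{`"III"` or `"IV"` (advanced disease only)}
#'   \item{grade}{tumor grade, 1, 2 or 3}
#'   \item{histology}{`"serous"` or `"other"`}
#'   \item{ca125}{preoperative serum CA125, U/ml, > 0}
#'   \item{he4}{preoperative serum HE4, pmol/L, > 0}
#'   \item{ecog}{ECOG performance status, 0, 1 or 2}
#'   \item{asa}{ASA class, `"1"`, `"2"` or `"3plus"` (classes >= 3 collapsed)}
#'   \item{outcome}{`"optimal"` (no residual tumor) or `"suboptimal"`}
#' }
#'
#' @name cohort
NULL

cohort_columns <- c(
  "patient_id", "age", "figo_stage", "grade", "histology",
  "ca125", "he4", "ecog", "asa", "outcome"
)

#' Validate and normalize a cohort table
#'
#' Checks the cohort schema and row-level invariants, normalizing categorical
#' spellings on the way (case-insensitive; numeric ASA classes >= 3 are mapped
#' to `"3plus"`). Analyses in this package expect complete cases: every field,
#' including the surgical outcome, must be present in every row.
#'
#' @param cohort A data frame with the columns described in [cohort].
#' @return The validated cohort as a tibble, with normalized categories and
#'   columns in canonical order.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "cohort is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(cohort)[cohort_columns]
  out$patient_id <- as.character(out$patient_id)
  if (anyDuplicated(out$patient_id)) {
    abort("duplicate patient_id values in cohort")
  }

  norm_cat <- function(x, map, field) {
    x <- tolower(trimws(as.character(x)))
    x <- ifelse(x %in% names(map), unname(map[x]), x)
    bad <- which(!x %in% unique(unname(map)))
    if (length(bad) > 0) {
      abort(sprintf(
        "row %d: invalid value for \"%s\": %s",
        bad[1], field, out[[field]][bad[1]]
      ))
    }
    x
  }

  out$figo_stage <- norm_cat(out$figo_stage,
    c(iii = "III", iv = "IV", "3" = "III", "4" = "IV", "III" = "III", "IV" = "IV"),
    "figo_stage"
  )
  out$histology <- norm_cat(out$histology,
    c(serous = "serous", other = "other", others = "other", "non-serous" = "other"),
    "histology"
  )
  out$outcome <- norm_cat(out$outcome,
    c(optimal = "optimal", suboptimal = "suboptimal"),
    "outcome"
  )
  asa_raw <- tolower(trimws(as.character(out$asa)))
  asa_num <- suppressWarnings(as.numeric(asa_raw))
  out$asa <- ifelse(!is.na(asa_num) & asa_num >= 3, "3plus",
    ifelse(asa_raw %in% c("3plus", ">=3", "3+"), "3plus", asa_raw)
  )
  bad_asa <- which(!out$asa %in% c("1", "2", "3plus"))
  if (length(bad_asa) > 0) {
    abort(sprintf("row %d: invalid value for \"asa\"", bad_asa[1]))
  }

  check_num <- function(field, lower, upper, strict_lower = FALSE) {
    x <- suppressWarnings(as.numeric(out[[field]]))
    bad <- which(is.na(x) | x < lower | x > upper | (strict_lower & x <= lower))
    if (length(bad) > 0) {
      abort(sprintf(
        "row %d: field \"%s\" out of range (value %s)",
        bad[1], field, as.character(out[[field]][bad[1]])
      ))
    }
    x
  }
  out$age <- check_num("age", 18, 100)
  out$ca125 <- check_num("ca125", 0, Inf, strict_lower = TRUE)
  out$he4 <- check_num("he4", 0, Inf, strict_lower = TRUE)
  out$grade <- as.integer(check_num("grade", 1, 3))
  out$ecog <- as.integer(check_num("ecog", 0, 2))
  out
}

#' Read a cohort from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row and the exact
#' column names described in [cohort]. Rows are validated and categorical
#' values normalized via [validate_cohort()]; row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0 && ncol(raw) > 0) {
    missing_cols <- setdiff(cohort_columns, names(raw))
    if (length(missing_cols) > 0) {
      abort(sprintf(
        "cohort is missing required column(s): %s",
        paste(missing_cols, collapse = ", ")
      ))
    }
    empty <- tibble::as_tibble(raw)[cohort_columns]
    empty$age <- numeric(0); empty$ca125 <- numeric(0); empty$he4 <- numeric(0)
    empty$grade <- integer(0); empty$ecog <- integer(0)
    return(empty)
  }
  validate_cohort(raw)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, path))` reproduces
#' `x` field for field.
#'
#' @param cohort A cohort data frame (validated before writing).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) > 0) cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Welch (or pooled) two-sample t-test from group moments
#'
#' Computes the two-sample t statistic, degrees of freedom and two-sided
#' p-value from per-group mean, SD and n — the summary-statistic path used
#' when comparing groups whose raw values are summarized as mean +/- SD.
#'
#' @param mean1,sd1,n1 First group's sample mean, sample SD (n-1 denominator)
#'   and size.
#' @param mean2,sd2,n2 Second group.
#' @param var_equal If `TRUE`, use the pooled-variance (Student) test;
#'   default is Welch's unequal-variance test.
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' # HE4 differs strongly between surgical-outcome groups:
#' t_test_from_moments(419.96, 355.56, 52, 997.44, 1050.33, 31)
t_test_from_moments <- function(mean1, sd1, n1, mean2, sd2, n2,
                                var_equal = FALSE) {
  if (min(n1, n2) < 2) abort("each group needs n >= 2")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  stat <- if (se == 0) 0 else (mean1 - mean2) / se
  tibble::tibble(
    statistic = stat, df = df,
    p.value = if (se == 0) 1 else 2 * pt(-abs(stat), df)
  )
}

#' Summarize a cohort by surgical outcome
#'
#' Produces a clinical characteristics table in the usual layout:
#' continuous variables as mean +/- SD overall and per outcome group with a
#' two-sample t-test p-value (Welch by default), categorical variables as
#' counts and percentages with a Pearson chi-square p-value (no continuity
#' correction; a warning is raised when any expected cell count is below 5).
#'
#' @param cohort A cohort data frame; both outcome groups must be non-empty.
#' @param var_equal Passed to the t-test: `FALSE` (default) for Welch.
#' @return An object of class `cohort_summary`: a list with `continuous` and
#'   `categorical` tibbles, the overall `optimal_rate`, and group sizes.
#'   `tidy()` returns the two tables stacked in long form.
#' @export
summarize_cohort <- function(cohort, var_equal = FALSE) {
  cohort <- validate_cohort(cohort)
  counts <- table(factor(cohort$outcome, c("optimal", "suboptimal")))
  if (any(counts == 0)) {
    abort("cannot compare groups: cohort contains a single outcome class")
  }

  cont_vars <- c("age", "ca125", "he4")
  continuous <- purrr::map_dfr(cont_vars, function(v) {
    x <- cohort[[v]]
    g_opt <- x[cohort$outcome == "optimal"]
    g_sub <- x[cohort$outcome == "suboptimal"]
    tt <- t_test_from_moments(
      mean(g_opt), sd(g_opt), length(g_opt),
      mean(g_sub), sd(g_sub), length(g_sub),
      var_equal = var_equal
    )
    tibble::tibble(
      variable = v,
      mean_all = mean(x), sd_all = sd(x),
      mean_optimal = mean(g_opt), sd_optimal = sd(g_opt),
      mean_suboptimal = mean(g_sub), sd_suboptimal = sd(g_sub),
      p.value = tt$p.value
    )
  })

  cat_vars <- list(
    figo_stage = c("III", "IV"),
    grade = c("1", "2", "3"),
    histology = c("serous", "other"),
    ecog = c("0", "1", "2"),
    asa = c("1", "2", "3plus")
  )
  categorical <- purrr::imap_dfr(cat_vars, function(levels, v) {
    f <- factor(as.character(cohort[[v]]), levels = levels)
    tab <- table(f, factor(cohort$outcome, c("optimal", "suboptimal")))
    # drop empty rows so the chi-square margins stay positive
    keep <- rowSums(tab) > 0
    p <- chi_square_test(t(tab[keep, , drop = FALSE]))$p.value
    tibble::tibble(
      variable = v,
      level = levels,
      n_all = as.integer(rowSums(tab)),
      pct_all = as.numeric(rowSums(tab)) / nrow(cohort) * 100,
      n_optimal = as.integer(tab[, "optimal"]),
      n_suboptimal = as.integer(tab[, "suboptimal"]),
      p.value = p
    )
  })

  structure(
    list(
      continuous = continuous,
      categorical = categorical,
      n = nrow(cohort),
      n_optimal = as.integer(counts[["optimal"]]),
      n_suboptimal = as.integer(counts[["suboptimal"]]),
      optimal_rate = as.numeric(counts[["optimal"]]) / nrow(cohort)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Cohort of %d patients: %d optimal / %d suboptimal (optimal rate %.2f%%)\n\n",
    x$n, x$n_optimal, x$n_suboptimal, 100 * x$optimal_rate
  ))
  cat("Continuous variables (mean +/- SD, t-test):\n")
  print(x$continuous)
  cat("\nCategorical variables (counts, chi-square):\n")
  print(x$categorical)
  invisible(x)
}

#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  cont <- x$continuous |>
    dplyr::transmute(
      variable = .data$variable, level = NA_character_,
      statistic_all = .data$mean_all,
      statistic_optimal = .data$mean_optimal,
      statistic_suboptimal = .data$mean_suboptimal,
      p.value = .data$p.value, type = "continuous"
    )
  cat <- x$categorical |>
    dplyr::transmute(
      variable = .data$variable, level = as.character(.data$level),
      statistic_all = as.numeric(.data$n_all),
      statistic_optimal = as.numeric(.data$n_optimal),
      statistic_suboptimal = as.numeric(.data$n_suboptimal),
      p.value = .data$p.value, type = "categorical"
    )
  dplyr::bind_rows(cont, cat)
}

#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_optimal = x$n_optimal, n_suboptimal = x$n_suboptimal,
    optimal_rate = x$optimal_rate
  )
}
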