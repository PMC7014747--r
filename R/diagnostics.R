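#' Confusion table for suboptimal-cytoreduction prediction
#'
#' Cross-tabulates true outcome against a binary prediction. The positive
#' class is always *suboptimal* cytoreduction: a true positive is a
#' suboptimal patient flagged as suboptimal.
#'
#' @param truth Character or logical vector of true outcomes
#'   (`"optimal"`/`"suboptimal"`, or `TRUE` for suboptimal).
#' @param predicted Predicted outcomes, same encoding and length.
#' @return A list of class `confusion_table` with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_table <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length")
  }
  if (length(truth) == 0) abort("empty input")
  as_pos <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x == 1)
    x <- tolower(as.character(x))
    bad <- !x %in% c("optimal", "suboptimal")
    if (any(bad)) abort("labels must be \"optimal\" or \"suboptimal\"")
    x == "suboptimal"
  }
  t_pos <- as_pos(truth)
  p_pos <- as_pos(predicted)
  structure(
    list(
      tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
      fn = sum(t_pos & !p_pos), tn = sum(!t_pos & !p_pos)
    ),
    class = "confusion_table"
  )
}

#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (positive class =
#'   suboptimal cytoreduction).
#' @return A `confusion_table`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("confusion table total must be positive")
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
    dimnames = list(
      truth = c("suboptimal", "optimal"),
      predicted = c("suboptimal", "optimal")
    )
  )
  print(m)
  invisible(x)
}

#' Diagnostic metrics from a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy, each per its standard definition with suboptimal cytoreduction
#' as the positive class. A metric whose denominator is zero is returned as
#' `NA` rather than coerced to a number.
#'
#' @param table A `confusion_table`, or a data frame with columns
#'   `tp`, `fp`, `fn`, `tn` (one row per table, vectorized).
#' @return A tibble with columns `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
#' @examples
#' # the PIV >= 6 operating point: 7 flagged, all truly suboptimal
#' diagnostic_metrics(confusion_counts(tp = 7, fp = 0, fn = 24, tn = 52))
diagnostic_metrics <- function(table) {
  if (inherits(table, "confusion_table")) {
    table <- tibble::as_tibble(unclass(table))
  }
  table <- tibble::as_tibble(table)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  with(table, tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  ))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, as used for the
#' categorical rows of a clinical characteristics table. Warns when any
#' expected cell count is below 5.
#'
#' @param table A matrix of counts (groups x categories).
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("contingency table has a zero margin")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    warn("some expected cell counts are below 5; chi-square approximation may be poor")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble::tibble(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p.value = res$p.value
  )
}

#' Spearman rank correlation
#'
#' Tie-aware Spearman correlation: the Pearson correlation of midranks.
#' Returns `NA` if either vector is constant.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y))
}
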