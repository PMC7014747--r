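#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC curve over thresholds at all distinct scores
#' (rule: score >= threshold flags suboptimal) and computes the AUC as the
#' midrank Mann-Whitney statistic, so ties contribute 1/2. Higher scores must
#' indicate a higher chance of suboptimal cytoreduction.
#'
#' @param scores Numeric marker or model scores.
#' @param truth Outcome labels (see [confusion_table()] for accepted
#'   encodings); both classes must be present.
#' @return An object of class `roc_result`: list with `points` (a tibble of
#'   operating points `fpr`, `tpr`, `threshold`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth) {
  pos <- as_positive(truth)
  if (length(scores) != length(pos)) {
    abort("`scores` and `truth` must have equal length")
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("both outcome classes must be present for ROC analysis")
  }
  # midrank Mann-Whitney AUC
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thresholds, function(t) {
    flag <- scores >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(flag & !pos) / n_neg,
      tpr = sum(flag & pos) / n_pos
    )
  })
  structure(
    list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

as_positive <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) return(truth == 1)
  x <- tolower(as.character(truth))
  bad <- !x %in% c("optimal", "suboptimal")
  if (any(bad)) abort("labels must be \"optimal\" or \"suboptimal\"")
  x == "suboptimal"
}

# Trapezoidal area under the ROC polygon; used as the internal cross-check
# of the midrank AUC (the two must agree to numerical precision).
trapezoid_auc <- function(points) {
  pts <- points[order(points$fpr, points$tpr), ]
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC over %d positives (suboptimal) / %d negatives: AUC = %.4f\n",
    x$n_pos, x$n_neg, x$auc
  ))
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  ci <- auc_se_ci_hanley(x$auc, x$n_pos, x$n_neg)
  tibble::tibble(
    auc = x$auc, se = ci$se, conf.low = ci$conf.low, conf.high = ci$conf.high,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f", object$auc)
    )
}

#' Hanley-McNeil standard error and confidence interval for an AUC
#'
#' Closed-form approximation to the sampling variance of an empirical AUC:
#' `[A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)] / (n_pos n_neg)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. The CI is symmetric normal, clipped
#' to \[0, 1\].
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pos,n_neg Group sizes (>= 2).
#' @param level Confidence level, default 0.95.
#' @return A tibble with `auc`, `se`, `conf.low`, `conf.high`.
#' @export
auc_se_ci_hanley <- function(auc, n_pos, n_neg, level = 0.95) {
  assert_scalar_number(auc, "auc", 0, 1)
  if (n_pos < 2 || n_neg < 2) abort("need n_pos >= 2 and n_neg >= 2")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auc = auc, se = se,
    conf.low = max(0, auc - z * se),
    conf.high = min(1, auc + z * se)
  )
}

#' Power to distinguish an AUC from 0.5 (Hanley-McNeil)
#'
#' Power of the two-sided level-`alpha` test of AUC = 0.5 against the
#' alternative `auc_alt`, using the Hanley-McNeil standard error under the
#' null (`SE0`, at AUC 0.5) and under the alternative (`SE1`):
#' `power = Phi((auc_alt - 0.5 - z * SE0) / SE1)`.
#'
#' @param auc_alt Alternative AUC in (0.5, 1].
#' @param n_pos,n_neg Group sizes.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power as a single number in \[0, 1\].
#' @export
#' @examples
#' # 31 suboptimal vs 52 optimal patients, target AUC 0.73:
#' auc_power_hanley(0.73, n_pos = 31, n_neg = 52) # ~0.955, i.e. 96%
auc_power_hanley <- function(auc_alt, n_pos, n_neg, alpha = 0.05) {
  assert_scalar_number(auc_alt, "auc_alt", lower = 0, upper = 1)
  if (auc_alt <= 0.5) abort("`auc_alt` must exceed the null value 0.5")
  assert_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  se0 <- auc_se_ci_hanley(0.5, n_pos, n_neg)$se
  se1 <- auc_se_ci_hanley(auc_alt, n_pos, n_neg)$se
  z <- qnorm(1 - alpha / 2)
  pnorm((auc_alt - 0.5 - z * se0) / se1)
}

#' Youden-optimal cutoff for a continuous marker
#'
#' Scans candidate cutoffs (midpoints between consecutive distinct sorted
#' scores, plus -Inf/+Inf sentinels) under the rule score >= cutoff flags
#' suboptimal, and returns the cutoff maximizing Youden's J =
#' sensitivity + specificity - 1. Ties are broken toward the lowest cutoff.
#'
#' @inheritParams roc_auc
#' @return A tibble with `cutoff`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, truth) {
  pos <- as_positive(truth)
  if (length(scores) != length(pos)) {
    abort("`scores` and `truth` must have equal length")
  }
  if (!any(pos) || all(pos)) {
    abort("both outcome classes must be present for cutoff selection")
  }
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- NULL
  for (cut in candidates) {
    flag <- scores >= cut
    sens <- sum(flag & pos) / sum(pos)
    spec <- sum(!flag & !pos) / sum(!pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- tibble::tibble(
        cutoff = cut, youden_j = j, sensitivity = sens, specificity = spec
      )
    }
  }
  best
}
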