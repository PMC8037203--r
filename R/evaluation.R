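#' Confusion table with cancer as the positive class
#'
#' @param predictions logical predictions (`TRUE` = cancer call).
#' @param labels logical truth (`TRUE` = cancer).
#' @return a list of class `ConfusionTable`: `TP`, `FP`, `TN`, `FN`.
#' @export
confusionTable <- function(predictions, labels) {
  predictions <- as.logical(predictions); labels <- as.logical(labels)
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  structure(list(TP = sum(predictions & labels),
                 FP = sum(predictions & !labels),
                 TN = sum(!predictions & !labels),
                 FN = sum(!predictions & labels)),
            class = "ConfusionTable")
}

#' @export
print.ConfusionTable <- function(x, ...) {
  cat(sprintf("ConfusionTable: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

# round half away from zero, the report-parity convention
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Continuity-corrected Wilson score confidence interval
#'
#' The score-based binomial interval with a half-count continuity
#' correction (the convention of the classic clinical-test
#' calculators), clipped to `[0, 1]`; the lower bound is exactly 0
#' when `successes = 0` and the upper exactly 1 when
#' `successes = n`.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n >= 1`.
#' @param confidence coverage level. Default 0.95.
#' @return numeric(2): lower and upper bound, as proportions.
#' @examples
#' round(100 * wilsonCcInterval(8, 10), 1)  # 44.2 96.5
#' @export
wilsonCcInterval <- function(successes, n, confidence = 0.95) {
  if (length(successes) != 1L || length(n) != 1L || n < 1 ||
      successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("require integer counts with 0 <= successes <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / n; q <- 1 - p
  lower <- if (successes == 0) 0 else
    (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * q + 1))) /
      (2 * (n + z^2))
  upper <- if (successes == n) 1 else
    (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * q - 1))) /
      (2 * (n + z^2))
  c(lower = max(0, lower), upper = min(1, upper))
}

#' Diagnostic performance metrics with confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value
#' and accuracy from a confusion table, each with its
#' continuity-corrected Wilson 95% CI. A metric with a zero
#' denominator is reported as `NA` (undefined), never as 0.
#'
#' @param table a [confusionTable()] result.
#' @param confidence CI coverage. Default 0.95.
#' @return a [S4Vectors::DataFrame] with one row per metric: `metric`,
#'   `successes`, `n`, `estimate` (proportion), `lower`, `upper`, and
#'   `percent`/`percentLower`/`percentUpper` rounded half-up to one
#'   decimal for report parity.
#' @examples
#' diagnosticMetrics(confusionTable(c(rep(TRUE, 8), rep(FALSE, 16)),
#'                                  c(rep(TRUE, 9), rep(FALSE, 15))))
#' @export
diagnosticMetrics <- function(table, confidence = 0.95) {
  stopifnot(inherits(table, "ConfusionTable"))
  defs <- list(
    sensitivity = c(table$TP, table$TP + table$FN),
    specificity = c(table$TN, table$TN + table$FP),
    ppv = c(table$TP, table$TP + table$FP),
    npv = c(table$TN, table$TN + table$FN),
    accuracy = c(table$TP + table$TN,
                 table$TP + table$FP + table$TN + table$FN))
  rows <- lapply(names(defs), function(metric) {
    s <- defs[[metric]][1]; n <- defs[[metric]][2]
    if (n == 0)
      return(DataFrame(metric = metric, successes = s, n = n,
                       estimate = NA_real_, lower = NA_real_,
                       upper = NA_real_, percent = NA_real_,
                       percentLower = NA_real_, percentUpper = NA_real_))
    ci <- wilsonCcInterval(s, n, confidence)
    DataFrame(metric = metric, successes = s, n = n, estimate = s / n,
              lower = unname(ci[1]), upper = unname(ci[2]),
              percent = roundHalfUp(100 * s / n),
              percentLower = roundHalfUp(100 * ci[1]),
              percentUpper = roundHalfUp(100 * ci[2]))
  })
  do.call(rbind, rows)
}

#' ROC curve and AUC with Hanley-McNeil confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random cancer score
#' exceeds a random non-cancer score, ties counted 1/2 (computed from
#' midranks; identical to the trapezoidal area under the empirical ROC
#' curve). The CI uses the Hanley-McNeil standard error.
#'
#' @param scores numeric scores (higher = more cancer-like).
#' @param labels logical truth (`TRUE` = cancer).
#' @param confidence CI coverage. Default 0.95.
#' @return a list: `auc`, `ci` (length 2, clipped to `[0, 1]`), `se`,
#'   and `roc`, a [S4Vectors::DataFrame] of (`threshold`, `fpr`,
#'   `tpr`) points for the strict rule `score > threshold`.
#' @export
rocAuc <- function(scores, labels, confidence = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE)[-1], -Inf)
  pts <- vapply(thresholds, function(t) {
    pred <- scores > t
    c(fpr = sum(pred & !labels) / nNeg, tpr = sum(pred & labels) / nPos)
  }, numeric(2))

  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
                (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(auc = auc,
       ci = c(lower = max(0, auc - z * se), upper = min(1, auc + z * se)),
       se = se,
       roc = DataFrame(threshold = thresholds, fpr = pts["fpr", ],
                       tpr = pts["tpr", ]))
}

#' Cohort sample size for estimating a mean in a finite population
#'
#' Evaluates `n = (N * s^2 * t^2) / ((N - 1) * e^2 + s^2 * t^2)`: the
#' finite-population sample size needed to estimate a mean with
#' absolute sampling error `e` at the confidence multiplier `t`
#' (a t-distribution critical value), given population size `N` and
#' standard deviation `s`.
#'
#' @param N population size.
#' @param s standard deviation of the quantity (e.g. mean Cq).
#' @param tCrit critical value of the t distribution.
#' @param e absolute sampling error.
#' @param mean optional mean of the quantity; when given, `e` must be
#'   smaller than it (it is an absolute error on that scale).
#' @return a list: `n` (raw value) and `nCeiling`.
#' @note With a population of 200 patients/year, mean Cq
#'   17.78 +/- 1.92, t = 2.306 and e = 5% of the mean, the formula
#'   evaluates to ~21.9 (ceiling 22).
#' @export
sampleSizeEstimate <- function(N, s, tCrit, e, mean = NULL) {
  vals <- c(N = N, s = s, tCrit = tCrit, e = e)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("N, s, tCrit and e must all be positive")
  if (!is.null(mean) && e >= mean)
    stop("sampling error e must be smaller than the mean")
  n <- (N * s^2 * tCrit^2) / ((N - 1) * e^2 + s^2 * tCrit^2)
  list(n = n, nCeiling = ceiling(n))
}
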