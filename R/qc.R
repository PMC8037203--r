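#' Hemolysis screen from the miR-23a / miR-451 delta Cq
#'
#' Plasma hemolysis releases erythrocyte-borne miR-451a, which lowers
#' its Cq relative to the erythrocyte-poor miR-23a-3p. The screen
#' computes, per sample, `delta = Cq(miR-23a) - Cq(miR-451)` and flags
#' the sample as hemolysed iff `delta > cutoff` (strictly; default
#' cutoff 7 cycles). Samples where either indicator is undetected get
#' an undefined delta and flag `"indeterminate"`. The delta is
#' invariant to per-sample additive Cq shifts (loading differences).
#'
#' @param cqset a [CqSet-class].
#' @param assay23a,assay451 indicator assay row names.
#' @param cutoff strict positivity cut-off in cycles. Default 7.
#' @return a [S4Vectors::DataFrame] with columns `sample_id`, `delta`,
#'   `flag` (`"pass"`, `"hemolysed"`, `"indeterminate"`).
#' @examples
#' cq <- matrix(c(18, 10, 18, 18), 2,
#'              dimnames = list(c("hsa-miR-23a-3p", "hsa-miR-451a"),
#'                              c("bad", "ok")))
#' sheet <- data.frame(sample_id = c("bad", "ok"), group = "healthy",
#'                     cohort = "screening")
#' hemolysisScreen(CqSet(cq, sheet))
#' @export
hemolysisScreen <- function(cqset, assay23a = "hsa-miR-23a-3p",
                            assay451 = "hsa-miR-451a", cutoff = 7) {
  stopifnot(is(cqset, "CqSet"))
  cq <- cqValues(cqset)
  for (a in c(assay23a, assay451))
    if (!a %in% rownames(cq)) stop("assay not present in matrix: ", a)
  delta <- cq[assay23a, ] - cq[assay451, ]
  flag <- ifelse(is.na(delta), "indeterminate",
                 ifelse(delta > cutoff, "hemolysed", "pass"))
  DataFrame(sample_id = colnames(cq), delta = unname(delta),
            flag = unname(flag))
}

#' Detection-rate filter over the cancer / non-cancer super-groups
#'
#' An assay is retained iff it is detected (defined Cq) in at least
#' `minRate` of the samples of the cancer super-group OR of the
#' non-cancer super-group; assays undetected in more than
#' `1 - minRate` of the samples of both super-groups are excluded.
#'
#' @param cqset a [CqSet-class] whose `colData` carries the cancer flag.
#' @param minRate minimum detection rate in (0, 1]. Default 0.95.
#' @return a list of class `QcReport`: `retained` and `excluded` assay
#'   name vectors, and `detectionRates`, a [S4Vectors::DataFrame] with
#'   per-assay rates in each super-group.
#' @export
detectionFilter <- function(cqset, minRate = 0.95) {
  stopifnot(is(cqset, "CqSet"))
  if (length(minRate) != 1L || !is.finite(minRate) ||
      minRate <= 0 || minRate > 1)
    stop("minRate must lie in (0, 1]")
  cq <- cqValues(cqset)
  cancer <- isCancer(cqset)
  if (!any(cancer) || !any(!cancer))
    stop("both cancer and non-cancer samples are required")
  rateCancer <- rowMeans(!is.na(cq[, cancer, drop = FALSE]))
  rateNonCancer <- rowMeans(!is.na(cq[, !cancer, drop = FALSE]))
  keep <- rateCancer >= minRate | rateNonCancer >= minRate
  structure(list(
    retained = rownames(cq)[keep],
    excluded = rownames(cq)[!keep],
    detectionRates = DataFrame(assay = rownames(cq),
                               cancer = unname(rateCancer),
                               non_cancer = unname(rateNonCancer),
                               retained = unname(keep)),
    minRate = minRate), class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QcReport: %d assays retained, %d excluded (min rate %g)\n",
              length(x$retained), length(x$excluded), x$minRate))
  invisible(x)
}
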