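#' Livak 2^-ddCt normalization with a global geometric-mean reference
#'
#' Array-card (TLDA) normalization: for each sample the reference
#' quantification is the geometric mean over all retained assays of
#' the linear quantities 2^-Cq, which on the cycle scale is the
#' arithmetic mean Cq. Then `dCt(a, s) = Cq(a, s) - reference(s)`, the
#' calibrator of each assay is the arithmetic mean of its dCt over the
#' control samples, and the reported value is
#' `-(dCt - calibrator) = log2(2^-ddCt)`, i.e. positive values mean
#' over-expression relative to controls. Undetected reactions among
#' retained assays are imputed at the censoring limit (maximal Cq =
#' minimal abundance) with a warning giving the imputed-cell count.
#'
#' @param cqset a [CqSet-class].
#' @param retainedAssays assays entering normalization (e.g. the
#'   `retained` element of [detectionFilter()]); default all assays.
#' @param controlSamples sample ids defining the calibrator; default
#'   the healthy group.
#' @return a [RelExprSet-class] over the retained assays,
#'   `scale = "tlda"`.
#' @seealso [livakNormalizeEndogenous()] for single-assay panels.
#' @export
livakNormalizeGlobal <- function(cqset, retainedAssays = rownames(cqset),
                                 controlSamples = NULL) {
  stopifnot(is(cqset, "CqSet"))
  if (is.null(controlSamples))
    controlSamples <-
      colnames(cqset)[sampleInfo(cqset)$group == "healthy"]
  if (length(controlSamples) == 0L)
    stop("controlSamples must be non-empty")
  missing <- setdiff(retainedAssays, rownames(cqset))
  if (length(missing))
    stop("retainedAssays not in matrix: ", paste(missing, collapse = ", "))
  unknown <- setdiff(controlSamples, colnames(cqset))
  if (length(unknown))
    stop("unknown control samples: ", paste(unknown, collapse = ", "))

  cq <- cqValues(cqset)[retainedAssays, , drop = FALSE]
  undetectedInControls <-
    rowSums(!is.na(cq[, controlSamples, drop = FALSE])) == 0L
  if (any(undetectedInControls))
    stop("assay undetected in every control sample: ",
         paste(retainedAssays[undetectedInControls], collapse = ", "))
  nImputed <- sum(is.na(cq))
  if (nImputed > 0) {
    warning(sprintf("imputing %d undetected cells at Cq = %g",
                    nImputed, censoringLimit(cqset)))
    cq[is.na(cq)] <- censoringLimit(cqset)
  }

  reference <- colMeans(cq)
  dct <- sweep(cq, 2, reference)
  calibrator <- rowMeans(dct[, controlSamples, drop = FALSE])
  logrq <- -sweep(dct, 1, calibrator)
  RelExprSet(logrq, sampleInfo(cqset), scale = "tlda")
}

#' Livak 2^-ddCt normalization against endogenous reference miRNAs
#'
#' Single-assay normalization: the per-sample reference quantification
#' is the arithmetic mean Cq of the endogenous control assays
#' (defaults miR-423-5p and miR-361-5p, a stable plasma pair). The
#' remainder follows [livakNormalizeGlobal()]: dCt against the
#' reference, calibrator from the control samples' dCt, output
#' `log2(2^-ddCt)`.
#'
#' @param cqset a [CqSet-class].
#' @param targets target assay names to quantify.
#' @param references endogenous reference assay names; must be
#'   detected in every sample.
#' @param controlSamples calibrator samples; default the healthy group.
#' @return a [RelExprSet-class] over the targets,
#'   `scale = "single_assay"`.
#' @export
livakNormalizeEndogenous <- function(cqset, targets,
                                     references = c("hsa-miR-423-5p",
                                                    "hsa-miR-361-5p"),
                                     controlSamples = NULL) {
  stopifnot(is(cqset, "CqSet"), length(targets) >= 1)
  if (is.null(controlSamples))
    controlSamples <-
      colnames(cqset)[sampleInfo(cqset)$group == "healthy"]
  if (length(controlSamples) == 0L)
    stop("controlSamples must be non-empty")
  missing <- setdiff(c(targets, references), rownames(cqset))
  if (length(missing))
    stop("assays not in matrix: ", paste(missing, collapse = ", "))
  cq <- cqValues(cqset)
  refCq <- cq[references, , drop = FALSE]
  if (anyNA(refCq)) {
    bad <- colnames(cq)[colSums(is.na(refCq)) > 0]
    stop("reference assay undetected in samples: ",
         paste(bad, collapse = ", "))
  }
  tgt <- cq[targets, , drop = FALSE]
  nImputed <- sum(is.na(tgt))
  if (nImputed > 0) {
    warning(sprintf("imputing %d undetected cells at Cq = %g",
                    nImputed, censoringLimit(cqset)))
    tgt[is.na(tgt)] <- censoringLimit(cqset)
  }
  reference <- colMeans(refCq)
  dct <- sweep(tgt, 2, reference)
  calibrator <- rowMeans(dct[, controlSamples, drop = FALSE])
  logrq <- -sweep(dct, 1, calibrator)
  RelExprSet(logrq, sampleInfo(cqset), scale = "single_assay")
}

#' Quantile normalization of a log2 expression matrix
#'
#' Forces every sample (column) onto the common distribution whose
#' sorted values are the across-sample means of sorted columns,
#' preserving within-sample ranks; ties share the mean of their rank
#' quantiles. Idempotent. Delegates to
#' [limma::normalizeQuantiles()] (`ties = TRUE`).
#'
#' @param x a [RelExprSet-class] or a complete numeric matrix with at
#'   least two columns.
#' @return the same container type, quantile-normalized; for a
#'   `RelExprSet` the `quantileNormalized` metadata flag is set.
#' @export
quantileNormalize <- function(x) {
  m <- exprValues(x)
  if (ncol(m) < 2L) stop("at least two samples are required")
  if (anyNA(m)) stop("missing values present; normalize/impute first")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (is(x, "RelExprSet")) {
    SummarizedExperiment::assay(x, "logrq") <- qn
    metadata(x)$quantileNormalized <- TRUE
    return(x)
  }
  qn
}
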