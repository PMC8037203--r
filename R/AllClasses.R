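#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

CANCER_GROUPS <- c("crc", "metastatic_crc")
HISTOLOGY_GROUPS <- c("healthy", "hyperplastic_polyp", "adenoma",
                      "crc", "metastatic_crc")
COHORTS <- c("screening", "discovery", "validation")

#' Container for raw qPCR quantification cycles
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' (`"cq"`) of quantification cycles with rows = qPCR assays (miRNAs)
#' and columns = samples. Undetected reactions (no amplification within
#' the censoring limit, conventionally cycle 40) are stored as `NA`.
#' Column metadata carries the sample sheet: `group` (histology stratum),
#' `cohort`, and the derived binary `cancer` flag (`group` is `crc` or
#' `metastatic_crc`).
#'
#' @slot censoringLimit numeric(1), the Cq censoring cycle (default 40).
#' @export
setClass("CqSet",
  contains = "SummarizedExperiment",
  representation(censoringLimit = "numeric"),
  prototype(censoringLimit = 40))

setValidity("CqSet", function(object) {
  msg <- character()
  if (length(object@censoringLimit) != 1L || !is.finite(object@censoringLimit) ||
      object@censoringLimit <= 0)
    msg <- c(msg, "censoringLimit must be a single positive number")
  if (!"cq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'cq' is required")
  else {
    v <- SummarizedExperiment::assay(object, "cq")
    if (any(!is.na(v) & (v <= 0 | v > object@censoringLimit)))
      msg <- c(msg, sprintf(
        "defined Cq values must lie in (0, %g]; undetected reactions are NA",
        object@censoringLimit))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate assay names")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("group", "cohort", "cancer"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("group" %in% colnames(cd) && !all(cd$group %in% HISTOLOGY_GROUPS))
    msg <- c(msg, paste("group must be one of:",
                        paste(HISTOLOGY_GROUPS, collapse = ", ")))
  if (all(c("group", "cancer") %in% colnames(cd)) &&
      !identical(as.logical(cd$cancer),
                 as.character(cd$group) %in% CANCER_GROUPS))
    msg <- c(msg, "cancer flag must equal group %in% {crc, metastatic_crc}")
  if (length(msg)) msg else TRUE
})

#' Container for log2 relative quantification
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' (`"logrq"`) of finite log2 relative quantities, i.e.
#' `log2(2^-ddCt) = -ddCt` after Livak normalization. `metadata()`
#' records the quantification `scale` (`"tlda"` for global-mean
#' reference, `"single_assay"` for endogenous-control reference) and
#' whether quantile normalization has been applied.
#'
#' @export
setClass("RelExprSet", contains = "SummarizedExperiment")

setValidity("RelExprSet", function(object) {
  msg <- character()
  if (!"logrq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logrq' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "logrq"))))
    msg <- c(msg, "logrq values must all be finite")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate assay names")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' A fixed marker-combination diagnostic model
#'
#' A linear score over named miRNA markers with a strict decision
#' threshold: a sample is called cancer iff
#' `sum(weights * expr[markers]) > threshold`. The `scale` tag records
#' which quantification scale the threshold was calibrated on:
#' `"tlda"` (array-card, global-mean Livak), `"single_assay"`
#' (endogenous-control Livak), or `"external_equal_weight"`
#' (equal weights for externally normalized matrices).
#'
#' @slot markers character, ordered marker names.
#' @slot weights numeric, one finite weight per marker.
#' @slot threshold numeric(1), strict decision cut-off.
#' @slot scale character(1), quantification scale tag.
#' @slot provenance character(1), free-text origin note.
#' @export
setClass("SignatureModel",
  representation(markers = "character", weights = "numeric",
                 threshold = "numeric", scale = "character",
                 provenance = "character"))

setValidity("SignatureModel", function(object) {
  msg <- character()
  if (length(object@markers) == 0L || anyDuplicated(object@markers))
    msg <- c(msg, "markers must be non-empty and unique")
  if (length(object@weights) != length(object@markers))
    msg <- c(msg, "one weight per marker required")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (length(object@scale) != 1L ||
      !object@scale %in% c("tlda", "single_assay", "external_equal_weight"))
    msg <- c(msg, "scale must be tlda, single_assay or external_equal_weight")
  if (length(msg)) msg else TRUE
})

#' geNorm stability ranking of reference-gene candidates
#'
#' Records the serial-exclusion trajectory of the geNorm algorithm:
#' per-round stability values M, the order in which unstable candidates
#' were excluded, the final retained pair with its average M, and the
#' pairwise-variation series V(n/n+1) used to judge how many reference
#' genes a normalization factor needs.
#'
#' @slot candidates character, all candidate assay names.
#' @slot mByRound list of named numeric vectors, M per remaining
#'   candidate at each exclusion round (round 1 = all candidates).
#' @slot exclusionOrder character, candidates in order of removal.
#' @slot finalPair character(2), the two most stable candidates.
#' @slot finalPairM numeric(1), average M of the final pair.
#' @slot vSeries named numeric, V(n/n+1) for n = 2..(candidates-1).
#' @export
setClass("StabilityRanking",
  representation(candidates = "character", mByRound = "list",
                 exclusionOrder = "character", finalPair = "character",
                 finalPairM = "numeric", vSeries = "numeric"))

setValidity("StabilityRanking", function(object) {
  msg <- character()
  if (length(object@finalPair) != 2L)
    msg <- c(msg, "finalPair must contain exactly two candidates")
  if (any(unlist(object@mByRound) < 0) || any(object@vSeries < 0))
    msg <- c(msg, "M and V values must be non-negative")
  if (!setequal(c(object@exclusionOrder, object@finalPair),
                object@candidates))
    msg <- c(msg, "exclusionOrder plus finalPair must partition candidates")
  if (length(msg)) msg else TRUE
})

#' @describeIn CqSet-class compact display
#' @param object a `CqSet`
#' @export
setMethod("show", "CqSet", function(object) {
  v <- SummarizedExperiment::assay(object, "cq")
  cat(sprintf("CqSet: %d assays x %d samples (censoring at Cq %g)\n",
              nrow(object), ncol(object), object@censoringLimit))
  cat(sprintf("  undetected cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  grp <- table(SummarizedExperiment::colData(object)$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = " "),
      "\n")
})

#' @describeIn RelExprSet-class compact display
#' @param object a `RelExprSet`
#' @export
setMethod("show", "RelExprSet", function(object) {
  md <- metadata(object)
  cat(sprintf("RelExprSet: %d assays x %d samples, scale=%s%s\n",
              nrow(object), ncol(object),
              if (is.null(md$scale)) "?" else md$scale,
              if (isTRUE(md$quantileNormalized)) " (quantile-normalized)"
              else ""))
})

#' @describeIn SignatureModel-class compact display
#' @param object a `SignatureModel`
#' @export
setMethod("show", "SignatureModel", function(object) {
  cat(sprintf("SignatureModel (%s): cancer iff score > %g\n",
              object@scale, object@threshold))
  for (i in seq_along(object@markers))
    cat(sprintf("  %-18s x %g\n", object@markers[i], object@weights[i]))
  if (nzchar(object@provenance)) cat("  ", object@provenance, "\n", sep = "")
})

#' @describeIn StabilityRanking-class compact display
#' @param object a `StabilityRanking`
#' @export
setMethod("show", "StabilityRanking", function(object) {
  cat(sprintf(
    "StabilityRanking: %d candidates; final pair %s + %s (mean M = %.3f)\n",
    length(object@candidates), object@finalPair[1], object@finalPair[2],
    object@finalPairM))
  if (length(object@vSeries))
    cat("  V(n/n+1):", paste(sprintf("%s=%.3f", names(object@vSeries),
                                     object@vSeries), collapse = " "), "\n")
})
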