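#' Construct a CqSet from a Cq matrix and a sample sheet
#'
#' @param cq numeric matrix of quantification cycles, rows = assays,
#'   columns = samples; `NA` marks undetected reactions.
#' @param sampleData data.frame or [S4Vectors::DataFrame] with one row
#'   per sample, columns `sample_id` (or rownames), `group` (one of
#'   `healthy`, `hyperplastic_polyp`, `adenoma`, `crc`,
#'   `metastatic_crc`) and `cohort` (`screening`, `discovery`,
#'   `validation`). A logical `cancer` column is derived from `group`.
#' @param censoringLimit Cq censoring cycle; values above it are
#'   invalid (undetected reactions must already be `NA`). Default 40.
#' @return a [CqSet-class] object.
#' @examples
#' cq <- matrix(c(20, 25, 21, 26), 2,
#'              dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     group = c("healthy", "crc"),
#'                     cohort = "screening")
#' CqSet(cq, sheet)
#' @export
CqSet <- function(cq, sampleData, censoringLimit = 40) {
  cq <- as.matrix(cq)
  if (is.null(rownames(cq)) || is.null(colnames(cq)))
    stop("cq matrix must have assay rownames and sample colnames")
  cd <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(cd)) rownames(cd) <- cd$sample_id
  if (!all(colnames(cq) %in% rownames(cd)))
    stop("sampleData is missing samples: ",
         paste(setdiff(colnames(cq), rownames(cd)), collapse = ", "))
  cd <- cd[colnames(cq), , drop = FALSE]
  cd$group <- as.character(cd$group)
  cd$cancer <- cd$group %in% CANCER_GROUPS
  new("CqSet",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(cq = cq), colData = DataFrame(cd)),
      censoringLimit = censoringLimit)
}

#' Construct a RelExprSet from a log2 relative-quantification matrix
#'
#' @param logrq numeric matrix of finite log2 relative quantities.
#' @param sampleData optional per-sample metadata (as in [CqSet()]).
#' @param scale quantification scale tag: `"tlda"`, `"single_assay"` or
#'   `"external_equal_weight"`.
#' @param quantileNormalized logical flag recorded in `metadata()`.
#' @return a [RelExprSet-class] object.
#' @export
RelExprSet <- function(logrq, sampleData = NULL, scale = "tlda",
                       quantileNormalized = FALSE) {
  logrq <- as.matrix(logrq)
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(logrq))
  } else {
    cd <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(cd)) rownames(cd) <- cd$sample_id
    DataFrame(cd[colnames(logrq), , drop = FALSE])
  }
  out <- new("RelExprSet",
             SummarizedExperiment::SummarizedExperiment(
               assays = list(logrq = logrq), colData = cd))
  metadata(out)$scale <- scale
  metadata(out)$quantileNormalized <- quantileNormalized
  out
}

#' Accessors for Cq and expression containers
#'
#' `cqValues()` returns the raw Cq matrix (`NA` = undetected);
#' `exprValues()` the log2 relative-quantification matrix;
#' `sampleInfo()` the sample sheet; `isCancer()` the binary cancer flag
#' (`TRUE` for `crc` / `metastatic_crc`).
#'
#' @param x a [CqSet-class] or [RelExprSet-class]
#' @return see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
cqValues <- function(x) {
  stopifnot(is(x, "CqSet"))
  SummarizedExperiment::assay(x, "cq")
}

#' @rdname accessors
#' @export
exprValues <- function(x) {
  if (is(x, "RelExprSet")) return(SummarizedExperiment::assay(x, "logrq"))
  as.matrix(x)
}

#' @rdname accessors
#' @export
sampleInfo <- function(x) SummarizedExperiment::colData(x)

#' @rdname accessors
#' @export
isCancer <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cancer" %in% colnames(cd)) return(as.logical(cd$cancer))
  as.character(cd$group) %in% CANCER_GROUPS
}

#' @rdname accessors
#' @export
censoringLimit <- function(x) {
  stopifnot(is(x, "CqSet"))
  x@censoringLimit
}

#' Accessors for SignatureModel objects
#'
#' @param model a [SignatureModel-class]
#' @return `markerNames()`: character vector; `markerWeights()`: named
#'   numeric vector; `decisionThreshold()`: numeric(1);
#'   `modelScale()`: character(1).
#' @name signature-accessors
NULL

#' @rdname signature-accessors
#' @export
markerNames <- function(model) model@markers

#' @rdname signature-accessors
#' @export
markerWeights <- function(model) stats::setNames(model@weights, model@markers)

#' @rdname signature-accessors
#' @export
decisionThreshold <- function(model) model@threshold

#' @rdname signature-accessors
#' @export
modelScale <- function(model) model@scale
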