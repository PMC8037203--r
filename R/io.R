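#' Read and write Cq matrices, sample sheets and expression matrices
#'
#' The plain-text interchange formats are: Cq matrix as TSV with assay
#' names in the first column, samples in the remaining columns and
#' `NA` marking undetected reactions; sample sheet as CSV with columns
#' `sample_id`, `group`, `cohort`; expression matrices as generic TSV
#' with an assay-name first column (the layout of GEO series-matrix
#' tables after header stripping).
#'
#' @param file path to read or write.
#' @param cqFile,sheetFile paths to the Cq TSV and the sample-sheet
#'   CSV.
#' @param cqset a [CqSet-class] to write.
#' @param censoringLimit Cq censoring cycle. Default 40.
#' @return `readCqSet()` a [CqSet-class]; `readExpressionMatrix()` a
#'   numeric matrix with assay rownames; the writers return their
#'   input invisibly.
#' @name qpcr-io
NULL

readMatrixTsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname qpcr-io
#' @export
readCqSet <- function(cqFile, sheetFile, censoringLimit = 40) {
  cq <- readMatrixTsv(cqFile)
  sheet <- utils::read.csv(sheetFile, stringsAsFactors = FALSE)
  CqSet(cq, sheet, censoringLimit = censoringLimit)
}

#' @rdname qpcr-io
#' @export
writeCqSet <- function(cqset, cqFile, sheetFile) {
  stopifnot(is(cqset, "CqSet"))
  cq <- cqValues(cqset)
  df <- data.frame(assay = rownames(cq), cq, check.names = FALSE)
  utils::write.table(df, cqFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(as.data.frame(sampleInfo(cqset))[
    , c("sample_id", "group", "cohort")], sheetFile, row.names = FALSE,
    quote = FALSE)
  invisible(cqset)
}

#' @rdname qpcr-io
#' @export
readExpressionMatrix <- function(file) readMatrixTsv(file)

#' Serialize and restore signature models as JSON
#'
#' @param model a [SignatureModel-class].
#' @param file path of the JSON file.
#' @return `readSignatureModel()` a [SignatureModel-class];
#'   `writeSignatureModel()` its input, invisibly.
#' @export
writeSignatureModel <- function(model, file) {
  stopifnot(is(model, "SignatureModel"))
  jsonlite::write_json(
    list(markers = model@markers, weights = model@weights,
         threshold = model@threshold, scale = model@scale,
         provenance = model@provenance),
    file, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname writeSignatureModel
#' @export
readSignatureModel <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("SignatureModel", markers = x$markers, weights = x$weights,
      threshold = x$threshold, scale = x$scale,
      provenance = if (is.null(x$provenance)) "" else x$provenance)
}
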