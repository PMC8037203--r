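PUBLISHED_MARKERS <- c("hsa-let-7e-5p", "hsa-miR-106a-5p",
                       "hsa-miR-28-3p", "hsa-miR-542-5p")
PUBLISHED_WEIGHTS <- c(1.037, 0.9, 0.247, 0.903)

#' The published four-miRNA colorectal cancer score
#'
#' The fixed plasma signature
#' `score = let-7e-5p x 1.037 + miR-106a-5p x 0.9 + miR-28-3p x 0.247
#' + miR-542-5p x 0.903` over log2 relative quantities, with a strict
#' cancer-prediction threshold that depends on the quantification
#' scale: 1.024 on array-card (TLDA, global-mean Livak) data, 2.442 on
#' single-assay (endogenous-control Livak) data, and 19.14 with equal
#' weights (all 1) on externally normalized matrices such as RNA-seq
#' quantifications. These published models are constants, not training
#' targets.
#'
#' @param scale `"tlda"`, `"single_assay"` or
#'   `"external_equal_weight"`.
#' @return a [SignatureModel-class].
#' @examples
#' publishedSignature("tlda")
#' @export
publishedSignature <- function(scale = c("tlda", "single_assay",
                                         "external_equal_weight")) {
  scale <- match.arg(scale)
  switch(scale,
    tlda = new("SignatureModel", markers = PUBLISHED_MARKERS,
               weights = PUBLISHED_WEIGHTS, threshold = 1.024,
               scale = "tlda",
               provenance = "published four-miRNA plasma score (TLDA)"),
    single_assay = new("SignatureModel", markers = PUBLISHED_MARKERS,
                       weights = PUBLISHED_WEIGHTS, threshold = 2.442,
                       scale = "single_assay",
                       provenance = "published score, single-assay recalibration"),
    external_equal_weight = new("SignatureModel",
                                markers = PUBLISHED_MARKERS,
                                weights = rep(1, 4), threshold = 19.14,
                                scale = "external_equal_weight",
                                provenance = "equal-weight score for external matrices"))
}

normalizeMarkerName <- function(x) sub("^hsa-", "", tolower(x))

matchMarkers <- function(markers, assayNames) {
  idx <- match(normalizeMarkerName(markers), normalizeMarkerName(assayNames))
  if (anyNA(idx))
    stop("markers not found in expression matrix: ",
         paste(markers[is.na(idx)], collapse = ", "))
  idx
}

#' Score samples with a signature model
#'
#' `score(s) = sum_i weight_i * expr(marker_i, s)`, no intercept.
#' Marker names are matched case-insensitively with an optional
#' `hsa-` prefix; a missing marker is an error (never silently
#' imputed).
#'
#' @param expr a [RelExprSet-class] or log2 expression matrix.
#' @param model a [SignatureModel-class].
#' @return named numeric vector of per-sample scores.
#' @examples
#' m <- matrix(1, 4, 2, dimnames = list(
#'   c("let-7e-5p", "miR-106a-5p", "miR-28-3p", "miR-542-5p"),
#'   c("s1", "s2")))
#' scoreSamples(m, publishedSignature("tlda"))  # 3.087 each
#' @export
scoreSamples <- function(expr, model) {
  stopifnot(is(model, "SignatureModel"))
  m <- exprValues(expr)
  idx <- matchMarkers(model@markers, rownames(m))
  drop(model@weights %*% m[idx, , drop = FALSE])
}

#' Classify samples from scores
#'
#' Predicts cancer iff `score > threshold`, strictly: a score exactly
#' at the threshold is called non-cancer.
#'
#' @param scores numeric scores (finite).
#' @param model a [SignatureModel-class], or a single numeric
#'   threshold.
#' @return logical vector, `TRUE` = predicted cancer.
#' @export
classifySamples <- function(scores, model) {
  threshold <- if (is(model, "SignatureModel")) model@threshold
               else as.numeric(model)
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  if (length(scores) == 0L) return(logical(0))
  stopifnot(all(is.finite(scores)))
  scores > threshold
}

svmWeights <- function(x, y) {
  fit <- e1071::svm(x, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE)
  drop(crossprod(fit$coefs, fit$SV))
}

standardizeBy <- function(x, center, scl) {
  scl[scl == 0] <- 1
  sweep(sweep(x, 2, center), 2, scl, "/")
}

# Recursive elimination path: feature names ordered from first-removed
# to last-surviving, computed on (already standardized) training data.
rfePath <- function(x, y) {
  feats <- colnames(x)
  path <- character(0)
  while (length(feats) > 1L) {
    w <- svmWeights(x[, feats, drop = FALSE], y)
    worst <- feats[which.min(w^2)]
    path <- c(path, worst)
    feats <- setdiff(feats, worst)
  }
  c(path, feats)
}

svmAccuracy <- function(xTrain, yTrain, xTest, yTest) {
  fit <- e1071::svm(xTrain, factor(yTrain), kernel = "linear", cost = 1,
                    scale = FALSE)
  mean(as.logical(as.character(stats::predict(fit, xTest))) == yTest)
}

#' Linear SVM with recursive feature elimination and LOOCV
#'
#' Trains a linear soft-margin SVM (C = 1) on candidate markers,
#' eliminating one feature at a time by smallest squared weight, and
#' reports for each requested model size the selected markers, the
#' apparent (resubstitution) accuracy, and the leave-one-out
#' cross-validated accuracy. To avoid selection bias, the elimination
#' path is recomputed inside every LOOCV fold; features are
#' standardized using training-fold statistics only.
#'
#' @param expr a [RelExprSet-class] or log2 expression matrix.
#' @param cancer logical class labels per sample; defaults to the
#'   container's cancer flag.
#' @param candidateMarkers assay names to start from (e.g. the
#'   up-regulated significant markers of [selectMarkers()]).
#' @param sizes model sizes to report. Default `1:6` capped at the
#'   number of candidates.
#' @return a [S4Vectors::DataFrame] with one row per size: `size`,
#'   `markers` (comma-separated, in elimination-survival order),
#'   `apparentAccuracy`, `loocvAccuracy`; the full marker sets are in
#'   `metadata(x)$markerSets`.
#' @export
trainSvmRfe <- function(expr, cancer = NULL, candidateMarkers,
                        sizes = 1:6) {
  m <- exprValues(expr)
  if (is.null(cancer)) cancer <- isCancer(expr)
  cancer <- as.logical(cancer)
  stopifnot(length(cancer) == ncol(m))
  if (length(unique(cancer)) < 2L)
    stop("both classes must be present")
  idx <- matchMarkers(candidateMarkers, rownames(m))
  x <- t(m[idx, , drop = FALSE])
  colnames(x) <- candidateMarkers
  sizes <- sort(unique(pmin(sizes, length(candidateMarkers))))

  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  xs <- standardizeBy(x, ctr, scl)
  fullPath <- rfePath(xs, cancer)
  topK <- function(path, k) path[(length(path) - k + 1L):length(path)]

  n <- nrow(x)
  loocvPred <- matrix(NA, n, length(sizes),
                      dimnames = list(rownames(x), NULL))
  for (i in seq_len(n)) {
    ctrI <- colMeans(x[-i, , drop = FALSE])
    sclI <- apply(x[-i, , drop = FALSE], 2, stats::sd)
    xTr <- standardizeBy(x[-i, , drop = FALSE], ctrI, sclI)
    xTe <- standardizeBy(x[i, , drop = FALSE], ctrI, sclI)
    pathI <- rfePath(xTr, cancer[-i])
    for (j in seq_along(sizes)) {
      f <- topK(pathI, sizes[j])
      fit <- e1071::svm(xTr[, f, drop = FALSE], factor(cancer[-i]),
                        kernel = "linear", cost = 1, scale = FALSE)
      loocvPred[i, j] <- as.logical(as.character(
        stats::predict(fit, xTe[, f, drop = FALSE])))
    }
  }

  apparent <- vapply(sizes, function(k) {
    f <- topK(fullPath, k)
    svmAccuracy(xs[, f, drop = FALSE], cancer, xs[, f, drop = FALSE], cancer)
  }, numeric(1))
  loocv <- colMeans(loocvPred == cancer)
  markerSets <- lapply(sizes, topK, path = fullPath)

  out <- DataFrame(size = sizes,
                   markers = vapply(markerSets, paste, "", collapse = ","),
                   apparentAccuracy = apparent, loocvAccuracy = loocv)
  metadata(out)$markerSets <- stats::setNames(markerSets,
                                              paste0("size", sizes))
  out
}

#' Calibrate a decision threshold for best overall accuracy
#'
#' Exhaustively evaluates candidate cut-points (midpoints between
#' adjacent sorted unique scores, plus one point below the minimum and
#' one above the maximum) under the strict rule `cancer iff
#' score > threshold`, and returns the threshold maximizing overall
#' accuracy; ties are broken by highest specificity, then by lowest
#' threshold.
#'
#' @param scores numeric scores.
#' @param cancer logical true labels.
#' @return a list: `threshold`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
calibrateThreshold <- function(scores, cancer) {
  cancer <- as.logical(cancer)
  stopifnot(length(scores) == length(cancer))
  if (length(unique(cancer)) < 2L) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (t in cand) {
    pred <- scores > t
    acc <- mean(pred == cancer)
    spec <- mean(!pred[!cancer])
    if (is.null(best) || acc > best$accuracy + 1e-12 ||
        (abs(acc - best$accuracy) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && t < best$threshold)))) {
      best <- list(threshold = t, accuracy = acc,
                   sensitivity = mean(pred[cancer]), specificity = spec)
    }
  }
  best
}
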