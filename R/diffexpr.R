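#' Fit random-variance-model hyperparameters
#'
#' The random variance model shares variance information across assays
#' through an inverse-gamma prior on the per-assay residual variance:
#' equivalently, the observed pooled variances satisfy
#' `s^2 * a * b ~ F(df, 2a)`. The hyperparameters `(a, b)` are fitted
#' by maximum likelihood over the observed variances (Nelder-Mead on
#' the log scale, method-of-moments start).
#'
#' @param variances per-assay pooled residual variances (length >= 10).
#' @param df residual degrees of freedom, a single value or one per
#'   assay (all >= 1).
#' @return a list of class `RvmHyper`: `a`, `b`, `logLik`, `converged`.
#' @references Wright GW, Simon RM (2003) A random variance model for
#'   detection of differential gene expression in small microarray
#'   experiments. Bioinformatics 19:2448-2455.
#' @export
fitRvmHyperparams <- function(variances, df) {
  s2 <- as.numeric(variances)
  if (length(s2) < 10L) stop("at least 10 assay variances are required")
  df <- rep_len(as.numeric(df), length(s2))
  if (any(df < 1)) stop("df must be >= 1 for every assay")
  if (any(!is.finite(s2)) || any(s2 < 0)) stop("variances must be finite, >= 0")
  if (all(s2 == 0)) stop("degenerate input: all variances are zero")
  pos <- s2 > 0   # zero variances carry no likelihood mass under the model
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(log(a * b) + stats::df(s2[pos] * a * b, df[pos], 2 * a, log = TRUE))
  }
  start <- c(log(2), log(1 / mean(s2[pos])))
  fit <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(a = exp(fit$par[1]), b = exp(fit$par[2]),
                 logLik = -fit$value, converged = fit$convergence == 0L),
            class = "RvmHyper")
}

#' @export
print.RvmHyper <- function(x, ...) {
  cat(sprintf("RvmHyper: a = %.4g, b = %.4g (logLik %.2f%s)\n", x$a, x$b,
              x$logLik, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Random-variance moderated t-test for cancer vs non-cancer
#'
#' Per assay, the pooled two-sample variance `s^2` is shrunk toward the
#' prior: `s~^2 = (df * s^2 + 2/b) / (df + 2a)` with
#' `df = n1 + n0 - 2`, the t statistic uses `s~^2`, and the p-value is
#' two-sided from a t distribution with `df + 2a` degrees of freedom.
#' With `hyper = NULL` no shrinkage is applied and the ordinary pooled
#' two-sample t-test is returned. Fold changes use the signed
#' convention `FC = sign(2^|delta|)` where
#' `delta = mean(cancer) - mean(non-cancer)` on the log2 scale, so
#' `|FC| >= 1` always.
#'
#' @param expr a [RelExprSet-class] or log2 expression matrix.
#' @param cancer logical cancer flag per sample; defaults to the
#'   container's flag.
#' @param hyper an `RvmHyper` from [fitRvmHyperparams()], the string
#'   `"fit"` to fit it from these data, or `NULL` for the classical
#'   pooled t-test.
#' @param pMax,fcMin significance filter: flagged iff `p < pMax` and
#'   `|FC| >= fcMin`. Defaults 0.05 and 1.5.
#' @return a [S4Vectors::DataFrame] (one row per assay) with columns
#'   `assay`, `meanCancer`, `meanNonCancer`, `log2FC`, `fc`, `t`, `df`,
#'   `p`, `q` (Benjamini-Hochberg, informational), `direction`,
#'   `significant`.
#' @export
rvmTTest <- function(expr, cancer = NULL, hyper = "fit",
                     pMax = 0.05, fcMin = 1.5) {
  m <- exprValues(expr)
  if (is.null(cancer)) cancer <- isCancer(expr)
  cancer <- as.logical(cancer)
  stopifnot(length(cancer) == ncol(m))
  n1 <- sum(cancer); n0 <- sum(!cancer)
  if (n1 < 2L || n0 < 2L)
    stop("each group needs at least 2 samples")

  m1 <- rowMeans(m[, cancer, drop = FALSE])
  m0 <- rowMeans(m[, !cancer, drop = FALSE])
  ss1 <- rowSums((m[, cancer, drop = FALSE] - m1)^2)
  ss0 <- rowSums((m[, !cancer, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- (ss1 + ss0) / df

  if (identical(hyper, "fit")) hyper <- fitRvmHyperparams(s2, df)
  if (is.null(hyper)) {
    sTilde2 <- s2
    dfT <- df
  } else {
    stopifnot(inherits(hyper, "RvmHyper"))
    sTilde2 <- (df * s2 + 2 / hyper$b) / (df + 2 * hyper$a)
    dfT <- df + 2 * hyper$a
  }
  delta <- m1 - m0
  tstat <- delta / sqrt(sTilde2 * (1 / n1 + 1 / n0))
  p <- 2 * stats::pt(-abs(tstat), dfT)
  fc <- ifelse(delta >= 0, 2^delta, -(2^(-delta)))
  direction <- ifelse(delta >= 0, "up", "down")
  DataFrame(assay = rownames(m), meanCancer = unname(m1),
            meanNonCancer = unname(m0), log2FC = unname(delta),
            fc = unname(fc), t = unname(tstat), df = unname(rep_len(dfT, nrow(m))),
            p = unname(p), q = unname(stats::p.adjust(p, "BH")),
            direction = unname(direction),
            significant = unname(p < pMax & abs(fc) >= fcMin))
}

#' Signed fold change between super-groups
#'
#' @inheritParams rvmTTest
#' @return named numeric vector of signed fold changes (`2^delta` for
#'   up, `-2^-delta` for down; magnitude always >= 1).
#' @export
foldChange <- function(expr, cancer = NULL) {
  m <- exprValues(expr)
  if (is.null(cancer)) cancer <- isCancer(expr)
  delta <- rowMeans(m[, cancer, drop = FALSE]) -
    rowMeans(m[, !cancer, drop = FALSE])
  ifelse(delta >= 0, 2^delta, -(2^(-delta)))
}

#' Select candidate markers from a differential-expression table
#'
#' @param deTable output of [rvmTTest()].
#' @param pMax strict p-value cut-off. Default 0.05.
#' @param fcMin minimum fold-change magnitude. Default 1.5.
#' @param direction `"up"` (over-expressed in cancer, the default for
#'   classifier candidates), `"down"`, or `"both"`.
#' @return character vector of marker (assay) names.
#' @export
selectMarkers <- function(deTable, pMax = 0.05, fcMin = 1.5,
                          direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  keep <- deTable$p < pMax & abs(deTable$fc) >= fcMin
  if (direction == "up") keep <- keep & deTable$fc > 0
  if (direction == "down") keep <- keep & deTable$fc < 0
  deTable$assay[keep]
}

#' Hierarchical clustering with 1 - Pearson correlation distance
#'
#' Agglomerates items (samples or assays) under complete linkage with
#' distance `1 - cor(x, y)`, the convention used for expression
#' heatmaps.
#'
#' @param expr a [RelExprSet-class] or matrix.
#' @param items `"samples"` (cluster columns, the default) or
#'   `"assays"` (cluster rows).
#' @return a list: `hclust` (a [stats::hclust] tree) and `order`
#'   (item labels in dendrogram order).
#' @export
hierarchicalCluster <- function(expr, items = c("samples", "assays")) {
  items <- match.arg(items)
  m <- exprValues(expr)
  x <- if (items == "samples") m else t(m)   # items in columns
  if (ncol(x) < 2L) stop("at least 2 items are required")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance item(s), correlation undefined: ",
         paste(colnames(x)[vars == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "complete")
  list(hclust = hc, order = hc$labels[hc$order])
}
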