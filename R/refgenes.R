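#' Pre-filter endogenous-control candidates by abundance
#'
#' Candidate reference miRNAs must be abundant and always detected:
#' assays with arithmetic mean Cq strictly below `meanCqMax` over all
#' samples and no undetected value qualify.
#'
#' @param cqset a [CqSet-class].
#' @param meanCqMax strict upper bound on the mean Cq. Default 20.
#' @return character vector of candidate assay names (may be empty).
#' @export
prefilterCandidates <- function(cqset, meanCqMax = 20) {
  stopifnot(is(cqset, "CqSet"), nrow(cqset) > 0)
  cq <- cqValues(cqset)
  complete <- rowSums(is.na(cq)) == 0L
  abundant <- rowMeans(cq) < meanCqMax   # NA mean fails the test anyway
  rownames(cq)[complete & !is.na(abundant) & abundant]
}

#' geNorm stability measure M
#'
#' For candidate reference genes with strictly positive linear-scale
#' relative quantities, the pairwise variation `V_jk` is the standard
#' deviation across samples of `log2(q_j / q_k)`, and the stability
#' measure `M_j` is the mean of `V_jk` over all partners `k != j`.
#' Lower M = more stable. M is invariant to multiplicative rescaling
#' of any candidate and to sample permutation.
#'
#' @param quantities numeric matrix, candidates x samples, strictly
#'   positive linear-scale relative quantities (e.g. `2^logrq`).
#' @return named numeric vector of M values.
#' @export
genormM <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 3L) stop("at least 3 candidates are required")
  if (ncol(q) < 2L) stop("at least 2 samples are required")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("quantities must be strictly positive and finite")
  lq <- log2(q)
  k <- nrow(lq)
  # sd of (lq_j - lq_k) across samples for every ordered pair
  V <- matrix(0, k, k, dimnames = list(rownames(lq), rownames(lq)))
  for (j in seq_len(k - 1L))
    for (l in (j + 1L):k) {
      V[j, l] <- V[l, j] <- stats::sd(lq[j, ] - lq[l, ])
    }
  rowSums(V) / (k - 1L)
}

#' geNorm serial-exclusion ranking and pairwise variation
#'
#' Iteratively removes the candidate with the highest stability value
#' M (ties broken by removing the lexicographically last assay name),
#' recomputing M among the survivors, until two candidates remain:
#' the proposed endogenous reference pair, reported with its average M
#' ("average expression stability"). The pairwise variation series
#' `V(n/n+1)` is the standard deviation across samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_n` is the per-sample geometric
#' mean of the n most stable candidates; geNorm's conventional cut-off
#' V < 0.15 suggests n references suffice, but no rule is enforced
#' here.
#'
#' @param quantities as in [genormM()], at least 3 candidates.
#' @return a [StabilityRanking-class].
#' @examples
#' set.seed(7)
#' base <- matrix(2^rnorm(5 * 8, 0, 1), 5, 8,
#'                dimnames = list(paste0("miR-", letters[1:5]), NULL))
#' base[1:2, ] <- 2^matrix(rnorm(2 * 8, 0, 0.02), 2, 8)  # a stable pair
#' genormRank(base)
#' @export
genormRank <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 3L) stop("at least 3 candidates are required")
  candidates <- rownames(q)
  if (is.null(candidates)) stop("quantities must have candidate rownames")

  remaining <- q
  mByRound <- list()
  excluded <- character()
  while (nrow(remaining) > 2L) {
    M <- genormM(remaining)
    mByRound[[length(mByRound) + 1L]] <- M
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[length(worst)]       # deterministic tie-break
    excluded <- c(excluded, worst)
    remaining <- remaining[setdiff(rownames(remaining), worst), ,
                           drop = FALSE]
  }
  # M of the final pair: sd of their log-ratio (each partner's only V)
  finalM <- stats::sd(log2(remaining[1, ] / remaining[2, ]))
  mByRound[[length(mByRound) + 1L]] <-
    stats::setNames(rep(finalM, 2L), rownames(remaining))

  # stability order, most stable first (final pair, then reverse exclusion)
  stabilityOrder <- c(sort(rownames(remaining)), rev(excluded))
  lq <- log2(q)
  nf <- function(n) colMeans(lq[stabilityOrder[seq_len(n)], , drop = FALSE])
  vSeries <- numeric(0)
  if (length(stabilityOrder) >= 3L) {
    ns <- 2:(length(stabilityOrder) - 1L)
    vSeries <- vapply(ns, function(n) stats::sd(nf(n) - nf(n + 1L)),
                      numeric(1))
    names(vSeries) <- sprintf("V%d/%d", ns, ns + 1L)
  }
  new("StabilityRanking", candidates = candidates, mByRound = mByRound,
      exclusionOrder = excluded, finalPair = sort(rownames(remaining)),
      finalPairM = finalM, vSeries = vSeries)
}
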