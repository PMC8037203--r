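# Independent brute-force oracles and small fixtures, used to check
# the vectorized implementations on toy inputs.

# toy CqSet: explicit values, assays x samples
makeCqSet <- function(cq, groups, cohort = "screening") {
  samples <- colnames(cq)
  if (is.null(samples)) {
    samples <- sprintf("s%02d", seq_len(ncol(cq)))
    colnames(cq) <- samples
  }
  if (is.null(rownames(cq)))
    rownames(cq) <- sprintf("miR-%02d", seq_len(nrow(cq)))
  CqSet(cq, data.frame(sample_id = samples, group = groups,
                       cohort = cohort))
}

# Livak global-mean normalization by explicit per-cell loops
oracleLivakGlobal <- function(cq, controlSamples) {
  out <- cq * NA
  ref <- numeric(ncol(cq))
  for (s in seq_len(ncol(cq))) ref[s] <- mean(cq[, s])
  dct <- cq
  for (a in seq_len(nrow(cq)))
    for (s in seq_len(ncol(cq)))
      dct[a, s] <- cq[a, s] - ref[s]
  for (a in seq_len(nrow(cq))) {
    calib <- mean(dct[a, controlSamples])
    for (s in seq_len(ncol(cq)))
      out[a, s] <- -(dct[a, s] - calib)
  }
  out
}

# geNorm M by explicit double loop over candidate pairs
oracleGenormM <- function(q) {
  k <- nrow(q)
  M <- numeric(k)
  for (j in seq_len(k)) {
    vs <- numeric(0)
    for (l in seq_len(k)) {
      if (l == j) next
      vs <- c(vs, stats::sd(log2(q[j, ] / q[l, ])))
    }
    M[j] <- mean(vs)
  }
  names(M) <- rownames(q)
  M
}

# full geNorm serial exclusion recomputed exhaustively at every round
oracleGenormRank <- function(q) {
  excluded <- character(0)
  while (nrow(q) > 2L) {
    M <- oracleGenormM(q)
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[length(worst)]
    excluded <- c(excluded, worst)
    q <- q[setdiff(rownames(q), worst), , drop = FALSE]
  }
  list(excluded = excluded, finalPair = sort(rownames(q)),
       finalPairM = stats::sd(log2(q[1, ] / q[2, ])))
}

# AUC by counting over all (positive, negative) pairs, ties 1/2
oracleAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# complete-linkage agglomeration on a distance matrix, merge heights only
oracleCompleteLinkageHeights <- function(d) {
  d <- as.matrix(d)
  heights <- numeric(0)
  groups <- as.list(seq_len(nrow(d)))
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups))
      for (j in seq_along(groups))
        if (i < j) {
          h <- max(d[groups[[i]], groups[[j]]])
          if (h < best[1]) best <- c(h, i, j)
        }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  sort(heights)
}

# run the full marker-screening chain on a simulated dataset and
# return the selected up-regulated markers
screenMarkers <- function(sim) {
  qc <- detectionFilter(sim$cqset)
  expr <- suppressWarnings(livakNormalizeGlobal(sim$cqset, qc$retained))
  de <- rvmTTest(quantileNormalize(expr))
  selectMarkers(de)
}
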