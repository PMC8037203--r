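test_that("the published four-miRNA models carry the printed constants", {
  tlda <- publishedSignature("tlda")
  expect_identical(markerNames(tlda),
                   c("hsa-let-7e-5p", "hsa-miR-106a-5p", "hsa-miR-28-3p",
                     "hsa-miR-542-5p"))
  expect_equal(unname(markerWeights(tlda)), c(1.037, 0.9, 0.247, 0.903))
  expect_equal(decisionThreshold(tlda), 1.024)
  expect_equal(decisionThreshold(publishedSignature("single_assay")), 2.442)
  ext <- publishedSignature("external_equal_weight")
  expect_equal(unname(markerWeights(ext)), rep(1, 4))
  expect_equal(decisionThreshold(ext), 19.14)
  expect_error(publishedSignature("bogus"))
})

fourMarkerMatrix <- function(values) {
  m <- matrix(values, 4, length(values) / 4)
  rownames(m) <- c("let-7e-5p", "miR-106a-5p", "miR-28-3p", "miR-542-5p")
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("scoring is the weighted sum, with flexible marker matching", {
  tlda <- publishedSignature("tlda")
  expect_equal(unname(scoreSamples(fourMarkerMatrix(rep(0, 4)), tlda)), 0)
  expect_equal(unname(scoreSamples(fourMarkerMatrix(rep(1, 4)), tlda)),
               3.087)
  # first marker alone at 1 scores its weight, over the tlda threshold
  s <- scoreSamples(fourMarkerMatrix(c(1, 0, 0, 0)), tlda)
  expect_equal(unname(s), 1.037)
  expect_true(classifySamples(s, tlda))
  # names match case-insensitively with optional hsa- prefix
  m <- fourMarkerMatrix(rep(1, 4))
  rownames(m) <- c("HSA-LET-7E-5P", "hsa-mir-106a-5p", "MIR-28-3P",
                   "miR-542-5p")
  expect_equal(unname(scoreSamples(m, tlda)), 3.087)
  # a missing marker is an error naming it
  expect_error(scoreSamples(m[1:3, , drop = FALSE], tlda), "542")
})

test_that("scoring is linear in the expression values", {
  set.seed(60)
  tlda <- publishedSignature("tlda")
  x <- fourMarkerMatrix(rnorm(20))
  y <- fourMarkerMatrix(rnorm(20))
  expect_equal(scoreSamples(3 * x, tlda), 3 * scoreSamples(x, tlda))
  expect_equal(scoreSamples(x + y, tlda),
               scoreSamples(x, tlda) + scoreSamples(y, tlda))
})

test_that("classification is strict at every published threshold", {
  for (scale in c("tlda", "single_assay", "external_equal_weight")) {
    model <- publishedSignature(scale)
    t <- decisionThreshold(model)
    expect_false(classifySamples(t, model))
    expect_true(classifySamples(t + 1e-9, model))
    expect_false(classifySamples(t - 1e-9, model))
  }
  expect_identical(classifySamples(numeric(0), 1), logical(0))
})

test_that("threshold calibration maximizes accuracy exhaustively", {
  res <- calibrateThreshold(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$threshold, 2.5)
  expect_equal(res$accuracy, 1)

  # on random inputs the result beats every candidate cut-point
  set.seed(61)
  for (rep in 1:5) {
    sc <- round(rnorm(30), 1)
    lab <- runif(30) > 0.4
    res <- calibrateThreshold(sc, lab)
    accs <- vapply(c(sc - 1e-6, sc + 1e-6),
                   function(t) mean((sc > t) == lab), numeric(1))
    expect_gte(res$accuracy + 1e-12, max(accs))
  }

  # fully interleaved scores cannot beat the majority rate
  sc <- 1:10
  lab <- rep(c(TRUE, FALSE), 5)
  expect_equal(calibrateThreshold(sc, lab)$accuracy, 0.5)

  # all-equal scores: threshold sits above the common value
  res0 <- calibrateThreshold(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_gt(res0$threshold, 2)
  expect_false(any(classifySamples(rep(2, 6), res0$threshold)))
})

test_that("SVM-RFE keeps planted informative features and ranks them first", {
  set.seed(62)
  n <- 40
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:n)))
  x[1, lab] <- x[1, lab] + 4   # two strongly informative features
  x[2, lab] <- x[2, lab] + 4
  rfe <- trainSvmRfe(x, lab, rownames(x))
  sets <- S4Vectors::metadata(rfe)$markerSets
  for (k in 2:6)
    expect_true(all(c("f1", "f2") %in% sets[[paste0("size", k)]]))
  expect_true(all(rfe$loocvAccuracy[rfe$size >= 2] >= 0.95))

  # a single perfectly separating feature gives LOOCV accuracy 1 at size 1
  x2 <- matrix(rnorm(3 * n), 3, n,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:n)))
  x2[1, ] <- ifelse(lab, 10, -10) + rnorm(n, sd = 0.1)
  rfe2 <- trainSvmRfe(x2, lab, rownames(x2), sizes = 1)
  expect_identical(S4Vectors::metadata(rfe2)$markerSets$size1, "g1")
  expect_equal(rfe2$loocvAccuracy, 1)

  expect_error(trainSvmRfe(x, rep(TRUE, n), rownames(x)), "class")
})

test_that("a trained size-4 model beats a random 4-marker model on plants", {
  wins <- vapply(1:10, function(s) {
    sim <- simulateCqDataset(synthConfig(nPerGroup = 6, nAssays = 60,
                                         seed = 700 + s))
    qc <- detectionFilter(sim$cqset)
    expr <- quantileNormalize(suppressWarnings(
      livakNormalizeGlobal(sim$cqset, qc$retained)))
    cancer <- isCancer(expr)
    rfe <- trainSvmRfe(expr, cancer, sim$truth$plantedUpAssays, sizes = 4)
    set.seed(s)
    rand <- sample(setdiff(rownames(expr), sim$truth$plantedUpAssays), 4)
    rfeRand <- trainSvmRfe(expr, cancer, rand, sizes = 4)
    rfe$loocvAccuracy - rfeRand$loocvAccuracy
  }, numeric(1))
  expect_gt(mean(wins), 0)
})
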