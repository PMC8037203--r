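test_that("global-mean Livak normalization handles hand-worked cases", {
  # one assay, all Cq equal: everything is its own reference -> 0
  cq1 <- matrix(20, 1, 4, dimnames = list("a", paste0("s", 1:4)))
  x1 <- makeCqSet(cq1, c("healthy", "healthy", "crc", "crc"))
  out1 <- livakNormalizeGlobal(x1, controlSamples = c("s1", "s2"))
  expect_equal(unname(exprValues(out1)), matrix(0, 1, 4))

  # an assay one cycle below its calibrator, reference held fixed by a
  # compensating second assay -> log2 RQ = +1
  cq2 <- rbind(a = c(20, 19), b = c(20, 21))
  colnames(cq2) <- c("ctrl", "case")
  x2 <- makeCqSet(cq2, c("healthy", "crc"))
  out2 <- livakNormalizeGlobal(x2, controlSamples = "ctrl")
  expect_equal(exprValues(out2)["a", "case"], 1)
  expect_equal(exprValues(out2)["b", "case"], -1)
})

test_that("global-mean Livak matches a brute-force oracle exactly", {
  set.seed(10)
  cq <- matrix(runif(25, 18, 32), 5, 5,
               dimnames = list(paste0("m", 1:5), paste0("s", 1:5)))
  x <- makeCqSet(cq, c("healthy", "healthy", "adenoma", "crc", "crc"))
  out <- livakNormalizeGlobal(x, controlSamples = c("s1", "s2"))
  expect_equal(exprValues(out), oracleLivakGlobal(cq, c("s1", "s2")),
               tolerance = 1e-10)
})

test_that("global-mean normalization cancels per-sample loading shifts", {
  set.seed(11)
  cq <- matrix(runif(30, 18, 30), 6, 5,
               dimnames = list(paste0("m", 1:6), paste0("s", 1:5)))
  groups <- c("healthy", "healthy", "adenoma", "crc", "crc")
  base <- livakNormalizeGlobal(makeCqSet(cq, groups),
                               controlSamples = c("s1", "s2"))
  cqShift <- cq; cqShift[, "s4"] <- cqShift[, "s4"] + 2.7
  shifted <- livakNormalizeGlobal(makeCqSet(cqShift, groups),
                                  controlSamples = c("s1", "s2"))
  expect_equal(exprValues(shifted)[, "s4"], exprValues(base)[, "s4"])
})

test_that("undetected cells are imputed at the censoring limit with warning", {
  cq <- rbind(a = c(20, NA, 20), b = c(22, 22, 22))
  colnames(cq) <- paste0("s", 1:3)
  x <- makeCqSet(cq, c("healthy", "crc", "crc"))
  expect_warning(out <- livakNormalizeGlobal(x, controlSamples = "s1"),
                 "imputing 1")
  cqImp <- cq; cqImp["a", "s2"] <- 40
  expect_equal(exprValues(out), oracleLivakGlobal(cqImp, "s1"),
               tolerance = 1e-10)
  # assay undetected in all control samples is an error
  cq2 <- rbind(a = c(NA, 20, 20), b = c(22, 22, 22))
  colnames(cq2) <- paste0("s", 1:3)
  x2 <- makeCqSet(cq2, c("healthy", "crc", "crc"))
  expect_error(livakNormalizeGlobal(x2, controlSamples = "s1"), "control")
})

test_that("endogenous-reference Livak reproduces worked examples", {
  # target equal to the reference mean everywhere -> 0
  cq <- rbind(t = c(20, 20), r1 = c(19, 19), r2 = c(21, 21))
  colnames(cq) <- c("ctrl", "case")
  x <- makeCqSet(cq, c("healthy", "crc"))
  out <- livakNormalizeEndogenous(x, "t", references = c("r1", "r2"),
                                  controlSamples = "ctrl")
  expect_equal(unname(exprValues(out)), matrix(0, 1, 2))

  # target 2 cycles below the reference mean in the case only -> +2
  cq2 <- cq; cq2["t", "case"] <- 18
  out2 <- livakNormalizeEndogenous(makeCqSet(cq2, c("healthy", "crc")),
                                   "t", references = c("r1", "r2"),
                                   controlSamples = "ctrl")
  expect_equal(exprValues(out2)["t", "case"], 2)

  # undetected reference is an error naming the sample
  cq3 <- cq; cq3["r1", "case"] <- NA
  expect_error(livakNormalizeEndogenous(makeCqSet(cq3, c("healthy", "crc")),
                                        "t", references = c("r1", "r2"),
                                        controlSamples = "ctrl"),
               "case")
})

test_that("endogenous normalization is equivariant under sample permutation", {
  set.seed(12)
  cq <- matrix(runif(24, 15, 30), 4, 6,
               dimnames = list(c("t1", "t2", "r1", "r2"), paste0("s", 1:6)))
  groups <- c("healthy", "healthy", "adenoma", "adenoma", "crc", "crc")
  out <- livakNormalizeEndogenous(makeCqSet(cq, groups), c("t1", "t2"),
                                  references = c("r1", "r2"),
                                  controlSamples = c("s1", "s2"))
  perm <- c(4, 2, 6, 1, 3, 5)
  outP <- livakNormalizeEndogenous(makeCqSet(cq[, perm], groups[perm]),
                                   c("t1", "t2"),
                                   references = c("r1", "r2"),
                                   controlSamples = c("s1", "s2"))
  expect_equal(exprValues(outP), exprValues(out)[, perm])
})

test_that("quantile normalization matches its defining property", {
  # hand-computed 2x2 case
  m <- matrix(c(0, 2, 1, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn), matrix(c(0.5, 2.5, 0.5, 2.5), 2))

  set.seed(13)
  m2 <- matrix(rnorm(60), 12, 5,
               dimnames = list(paste0("a", 1:12), paste0("s", 1:5)))
  qn2 <- quantileNormalize(m2)
  sorted <- apply(qn2, 2, sort)
  # identical column distributions, to machine precision
  expect_lt(max(abs(sorted - rowMeans(sorted))), 1e-12)
  # within-sample ranks preserved
  for (j in 1:5) expect_equal(rank(qn2[, j]), rank(m2[, j]))
  # idempotence and fixed point on identical columns
  expect_equal(quantileNormalize(qn2), qn2)
  same <- matrix(rep(rnorm(10), 3), 10, 3,
                 dimnames = list(paste0("a", 1:10), paste0("s", 1:3)))
  expect_equal(quantileNormalize(same), same)

  expect_error(quantileNormalize(matrix(c(1, NA, 2, 3), 2)), "[Mm]issing")
})
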