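#' Configuration for the synthetic qPCR cohort generator
#'
#' Bundles the parameters of [simulateCqDataset()] with validation.
#' Defaults emulate a TaqMan low-density-array screening cohort: a
#' 381-assay panel, five histology strata, a handful of markers
#' up-regulated in cancer, two high-abundance low-variance
#' endogenous-like assays, and censoring of undetected reactions at
#' cycle 40.
#'
#' @param nPerGroup samples per histology group (5 groups). Default 20.
#' @param nAssays panel size. Default 381.
#' @param nPlantedUp number of assays up-regulated in cancer samples.
#'   Default 6.
#' @param effectLog2 mean log2 shift of planted assays in cancer
#'   (1 log2 unit = 1 Cq cycle). Default 1.5.
#' @param baselineCqMean,baselineCqSd normal distribution of per-assay
#'   baseline Cq. Defaults 32 and 6, so that a realistic minority of
#'   low-abundance assays falls foul of the detection filter.
#' @param dropoutCqLimit censoring cycle; draws above it become
#'   undetected (`NA`). Default 40.
#' @param nStable number of endogenous-like stable assays (baseline
#'   ~N(18, 1), technical sd 0.1 cycles). Default 2.
#' @param hemolysisFraction fraction of samples contaminated by
#'   hemolysis. Default 0.
#' @param noiseSd per-sample technical noise sd in cycles. Default 0.5.
#' @param seed RNG seed.
#' @return a named list of validated parameters (class `synthConfig`).
#' @export
synthConfig <- function(nPerGroup = 20, nAssays = 381, nPlantedUp = 6,
                        effectLog2 = 1.5, baselineCqMean = 32,
                        baselineCqSd = 6, dropoutCqLimit = 40,
                        nStable = 2, hemolysisFraction = 0,
                        noiseSd = 0.5, seed = 1L) {
  cfg <- list(nPerGroup = nPerGroup, nAssays = nAssays,
              nPlantedUp = nPlantedUp, effectLog2 = effectLog2,
              baselineCqMean = baselineCqMean, baselineCqSd = baselineCqSd,
              dropoutCqLimit = dropoutCqLimit, nStable = nStable,
              hemolysisFraction = hemolysisFraction, noiseSd = noiseSd,
              seed = seed)
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid synthConfig field '%s': %s", field, why),
                  call. = FALSE)
  for (f in c("nPerGroup", "nAssays", "nPlantedUp", "nStable"))
    chk(length(cfg[[f]]) == 1L && cfg[[f]] >= 0 && cfg[[f]] == round(cfg[[f]]),
        f, "must be a non-negative integer")
  chk(cfg$nPerGroup >= 1, "nPerGroup", "must be at least 1")
  # 2 slots are reserved for the hemolysis indicator assays
  chk(cfg$nPlantedUp + cfg$nStable + 2 <= cfg$nAssays, "nAssays",
      "panel too small for planted + stable + hemolysis-indicator assays")
  chk(is.finite(cfg$effectLog2), "effectLog2", "must be finite")
  chk(cfg$hemolysisFraction >= 0 && cfg$hemolysisFraction <= 1,
      "hemolysisFraction", "must lie in [0, 1]")
  chk(cfg$baselineCqSd >= 0, "baselineCqSd", "must be non-negative")
  chk(cfg$noiseSd >= 0, "noiseSd", "must be non-negative")
  chk(cfg$dropoutCqLimit > 0, "dropoutCqLimit", "must be positive")
  structure(cfg, class = "synthConfig")
}

#' Simulate a Cq-level qPCR cohort with known ground truth
#'
#' Generates a censored Cq matrix over the five histology strata
#' (healthy, hyperplastic polyp, adenoma, CRC, metastatic CRC) with a
#' planted set of cancer-up-regulated assays, stable endogenous-like
#' assays, the two hemolysis-indicator assays (`hsa-miR-23a-3p`,
#' `hsa-miR-451a`), and optional hemolysis contamination. Per-assay
#' baselines are drawn once from N(baselineCqMean, baselineCqSd); each
#' reaction adds technical noise (sd `noiseSd` cycles; 0.1 for stable
#' assays); up-regulation in cancer lowers Cq by `effectLog2` cycles
#' (one cycle = one log2 unit under the 2^-ddCt model); draws above
#' `dropoutCqLimit` are recorded as undetected.
#'
#' @param config a [synthConfig()] object.
#' @return a list with elements `cqset` (a [CqSet-class]),
#'   `truth` (list: `plantedUpAssays`, `stableAssays`,
#'   `hemolysedSamples`, `cancerSamples`).
#' @examples
#' sim <- simulateCqDataset(synthConfig(nPerGroup = 4, nAssays = 40))
#' sim$cqset
#' sim$truth$plantedUpAssays
#' @export
simulateCqDataset <- function(config = synthConfig()) {
  if (!inherits(config, "synthConfig")) config <- do.call(synthConfig, config)
  set.seed(config$seed)
  nS <- 5L * config$nPerGroup
  groups <- rep(HISTOLOGY_GROUPS, each = config$nPerGroup)
  samples <- sprintf("S%03d", seq_len(nS))
  sheet <- data.frame(sample_id = samples, group = groups,
                      cohort = "screening", stringsAsFactors = FALSE)
  cancer <- groups %in% CANCER_GROUPS

  nOther <- config$nAssays - config$nPlantedUp - config$nStable - 2L
  planted <- if (config$nPlantedUp)
    sprintf("planted-miR-%02d", seq_len(config$nPlantedUp)) else character()
  stable <- if (config$nStable)
    sprintf("stable-miR-%02d", seq_len(config$nStable)) else character()
  hemo <- c("hsa-miR-23a-3p", "hsa-miR-451a")
  other <- if (nOther) sprintf("synth-miR-%04d", seq_len(nOther)) else character()
  assays <- c(planted, stable, hemo, other)

  # per-assay baselines: planted markers are detectable by construction
  # (the study's markers were among the assays passing the 95% filter)
  baseline <- c(
    stats::rnorm(length(planted), 26, 2),
    stats::rnorm(length(stable), 18, 1),
    c(19, 17),  # miR-23a-3p, miR-451a: non-hemolysed delta ~ +2
    stats::rnorm(length(other), config$baselineCqMean, config$baselineCqSd))
  noiseSd <- ifelse(assays %in% stable, 0.1, config$noiseSd)

  cq <- baseline +
    matrix(stats::rnorm(config$nAssays * nS), config$nAssays, nS) * noiseSd
  dimnames(cq) <- list(assays, samples)
  cq[planted, cancer] <- cq[planted, cancer] - config$effectLog2
  cq <- pmax(cq, 0.5)

  hemolysed <- character()
  if (config$hemolysisFraction > 0) {
    nH <- round(config$hemolysisFraction * nS)
    hemolysed <- sort(sample(samples, nH))
  }

  cq[cq > config$dropoutCqLimit] <- NA_real_
  cqset <- CqSet(cq, sheet, censoringLimit = config$dropoutCqLimit)
  if (length(hemolysed))
    cqset <- injectHemolysis(cqset, hemolysed)

  list(cqset = cqset,
       truth = list(plantedUpAssays = planted, stableAssays = stable,
                    hemolysedSamples = hemolysed,
                    cancerSamples = samples[cancer]))
}

#' Inject hemolysis contamination into selected samples
#'
#' Hemolysis releases erythrocyte miR-451a into plasma, lowering its
#' Cq; the hemolysis delta Cq(miR-23a) - Cq(miR-451) then exceeds the
#' screening cut-off of 7 cycles. For each affected sample the
#' miR-451a Cq is decreased (never increased) so that the delta is
#' strictly greater than `7 + margin`. All other assays are untouched.
#'
#' @param cqset a [CqSet-class] containing both indicator assays.
#' @param sampleIds samples to contaminate (may be empty).
#' @param margin cycles by which the delta exceeds 7. Default 0.5.
#' @param assay23a,assay451 indicator assay names.
#' @return the modified [CqSet-class].
#' @export
injectHemolysis <- function(cqset, sampleIds, margin = 0.5,
                            assay23a = "hsa-miR-23a-3p",
                            assay451 = "hsa-miR-451a") {
  stopifnot(is(cqset, "CqSet"), margin > 0)
  if (length(sampleIds) == 0L) return(cqset)
  unknown <- setdiff(sampleIds, colnames(cqset))
  if (length(unknown))
    stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  cq <- cqValues(cqset)
  for (a in c(assay23a, assay451))
    if (!a %in% rownames(cq)) stop("assay not present: ", a)
  v23 <- cq[assay23a, sampleIds]
  if (anyNA(v23) || anyNA(cq[assay451, sampleIds]))
    stop("indicator assays undetected in: ",
         paste(sampleIds[is.na(v23) | is.na(cq[assay451, sampleIds])],
               collapse = ", "))
  cq[assay451, sampleIds] <- pmin(cq[assay451, sampleIds],
                                  v23 - 7 - margin)
  cq[assay451, ] <- pmax(cq[assay451, ], 0.01)
  SummarizedExperiment::assay(cqset, "cq") <- cq
  validObject(cqset)
  cqset
}
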