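# plasmiR

Circulating (plasma) microRNAs are promising minimally invasive markers
for colorectal cancer: a blood draw instead of a colonoscopy for the
first screening step. Deriving a usable test from a qPCR panel, however,
chains together many small statistical decisions — hemolysis screening,
detection filtering, relative quantification, variance-moderated marker
screening, feature elimination with honest cross-validation, and
clinical performance reporting with appropriate intervals. **plasmiR**
implements that chain end to end for TaqMan low-density array (TLDA)
and single-assay qPCR data, ships the published four-miRNA plasma score
as a ready-to-apply model, and includes a synthetic cohort generator so
every stage is testable without any external data.

The package is written in Bioconductor style: Cq matrices and log2
relative-expression matrices live in `SummarizedExperiment`-derived
containers (`CqSet`, `RelExprSet`) with validity checks, and trained or
published classifiers are immutable `SignatureModel` objects.

## The model

Raw quantification cycles Cq are converted to log2 relative quantities
under the Livak model. For array cards, with per-sample global reference
ref(s) = mean over retained assays of Cq(a, s):

    ΔCt(a, s)   = Cq(a, s) − ref(s)
    ΔΔCt(a, s)  = ΔCt(a, s) − mean over control samples of ΔCt(a, ·)
    logRQ(a, s) = −ΔΔCt(a, s)          (= log2 of 2^−ΔΔCt)

Markers are screened with the random-variance moderated t-test: observed
per-assay pooled variances are modeled as s² · a·b ~ F(df, 2a), the
hyperparameters (a, b) are fit by maximum likelihood, and each test uses
the shrunken variance s̃² = (df·s² + 2/b) / (df + 2a) with df + 2a
degrees of freedom. Candidates (p < 0.05, fold change ≥ 1.5, up in
cancer) feed linear SVM recursive feature elimination with the
elimination path recomputed inside every leave-one-out fold.

The published diagnostic score is the fixed linear functional

    score = 1.037·let-7e-5p + 0.9·miR-106a-5p + 0.247·miR-28-3p + 0.903·miR-542-5p

over log2 relative quantities, calling cancer iff score strictly exceeds
a scale-specific threshold: 1.024 (TLDA), 2.442 (single TaqMan assays),
or 19.14 with equal weights for externally normalized matrices.
Performance is reported as sensitivity/specificity/PPV/NPV/accuracy with
continuity-corrected Wilson 95% intervals and Mann–Whitney AUC with a
Hanley–McNeil CI.

## Worked example

A fully synthetic study at the default conditions — 381 assays, five
histology groups of 20 samples (healthy, hyperplastic polyp, adenoma,
CRC, metastatic CRC), six planted cancer markers at +1.5 log2 units:

```r
library(plasmiR)

sim  <- simulateCqDataset(synthConfig(seed = 1))
qc   <- detectionFilter(sim$cqset)           # retains 343 of 381 assays
expr <- quantileNormalize(livakNormalizeGlobal(sim$cqset, qc$retained))

de <- rvmTTest(expr)
selectMarkers(de)
#> "planted-miR-01" ... "planted-miR-06"     # all 6 planted markers, 0 false
head(de[order(de$p), c("assay", "log2FC", "fc", "t", "p")], 3)
#>            assay    log2FC        fc         t           p
#> 1 planted-miR-05   1.30749   2.47511   13.0657 5.99609e-30
#> 2 planted-miR-04   1.17675   2.26067   12.3945 1.05524e-27
#> 3 planted-miR-02   1.21598   2.32298   12.1707 5.83862e-27

trainSvmRfe(expr, isCancer(expr), selectMarkers(de), sizes = 1:4)
#>   size                                                       markers apparentAccuracy loocvAccuracy
#> 1    1                                                planted-miR-04             0.96          0.94
#> 2    2                                 planted-miR-02,planted-miR-04             0.98          0.97
#> 3    3                  planted-miR-05,planted-miR-02,planted-miR-04             1.00          0.99
#> 4    4   planted-miR-01,planted-miR-05,planted-miR-02,planted-miR-04             1.00          1.00

genormRank(2^exprValues(expr)[prefilterCandidates(sim$cqset), ])
#> StabilityRanking: 12 candidates; final pair stable-miR-01 + stable-miR-02 (mean M = 0.156)
```

Applying the published score — e.g. to a sample with unit log2
expression of every marker:

```r
m <- matrix(1, 4, 1, dimnames = list(c("hsa-let-7e-5p", "hsa-miR-106a-5p",
                                       "hsa-miR-28-3p", "hsa-miR-542-5p"), "unit"))
scoreSamples(m, publishedSignature("tlda"))
#>  unit
#> 3.087                                    # > 1.024, classified cancer
```

Diagnostic metrics from a confusion table (here 19/32 cancers and 46/53
non-cancers called correctly):

```r
diagnosticMetrics(confusionTable(predicted, truth))
#>        metric successes   n estimate    lower    upper percent
#> 1 sensitivity        19  32 0.593750 0.407854 0.757809    59.4
#> 2 specificity        46  53 0.867925 0.740470 0.940863    86.8
#> 3         ppv        19  26 0.730769 0.519494 0.876476    73.1
#> 4         npv        46  59 0.779661 0.649435 0.873077    78.0
#> 5    accuracy        65  85 0.764706 0.657974 0.847097    76.5
```

See `vignettes/plasmiR-methods.Rmd` for the full methods description,
parameter rationale, and limitations of the synthetic generator.

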