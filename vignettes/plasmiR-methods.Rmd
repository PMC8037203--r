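---
title: "Methods: building circulating miRNA diagnostic classifiers from qPCR panels"
author: "plasmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building circulating miRNA diagnostic classifiers from qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmiR)
```

## Scope and model

plasmiR implements the analysis chain used to derive and apply plasma
miRNA diagnostic signatures for colorectal cancer from qPCR panels:
quantification cycles (Cq) from a ~381-assay TaqMan low-density array
(TLDA) or from individual TaqMan assays are quality-controlled,
converted to log2 relative quantities under the Livak
$2^{-\Delta\Delta C_t}$ model, screened for differentially expressed
markers with a random-variance moderated t-test, combined into a
linear support-vector-machine classifier by recursive feature
elimination, and evaluated with clinical diagnostic metrics. The
package also ships the published four-miRNA plasma score
(let-7e-5p, miR-106a-5p, miR-28-3p, miR-542-5p) as an immutable
`SignatureModel` with its three scale-specific decision thresholds.

Samples are stratified into five histology groups — healthy,
hyperplastic polyp, adenoma, CRC, metastatic CRC — with the binary
cancer status defined as membership of the last two. All containers
are `SummarizedExperiment` derivatives (`CqSet` for raw cycles,
`RelExprSet` for log2 relative quantities), so the usual subsetting
and metadata idioms apply.

## Quality control

**Hemolysis.** Erythrocyte lysis floods plasma with miR-451a, so the
delta `Cq(miR-23a-3p) - Cq(miR-451a)` rises in hemolysed samples.
`hemolysisScreen()` flags a sample as hemolysed iff the delta strictly
exceeds 7 cycles. Two conventions here are deliberate choices, since
the screening rule is usually quoted only as the marker pair plus
"positive if > 7": the delta is oriented so that hemolysis *increases*
it (miR-451a release lowers its Cq), and "positive" is read as
positive *for hemolysis*, i.e. the flagged sample should be excluded.
Both the pair and the cut-off are arguments. Samples where either
indicator failed to amplify are flagged `indeterminate` rather than
passed.

**Detection filter.** `detectionFilter()` retains an assay iff it is
detected in at least 95% (configurable) of the samples of the cancer
super-group *or* of the non-cancer super-group. The filter operates on
the two super-groups rather than the five strata because constantly
deficient assays are defined by failing in both arms of the eventual
comparison; an assay robustly detected in cancers only is still
informative. Undetected values are never imputed at this stage —
imputation is a normalization policy.

## Normalization

**Global-mean Livak (TLDA mode).** For array cards no single reference
gene is needed: the reference quantification of a sample is the
geometric mean of the linear quantities $2^{-C_q}$ over all retained
assays, which on the cycle scale is simply the arithmetic mean Cq —
the only reading of a "geometric mean normalization factor" that
yields one factor per sample. Then
$\Delta C_t(a,s) = C_q(a,s) - \mathrm{ref}(s)$, the calibrator of
assay $a$ is the arithmetic mean of its $\Delta C_t$ over the control
samples, and the reported value is
$-\Delta\Delta C_t = \log_2 2^{-\Delta\Delta C_t}$. Control samples
default to the healthy group (configurable, e.g. to all non-cancer
samples). The construction makes the output invariant to per-sample
additive Cq shifts, i.e. to loading/input-quantity differences, which
is the point of the global factor.

**Undetected values.** After the detection filter, at most 5% of
cells per assay in one super-group can be undetected. Those cells are
imputed at the censoring limit (Cq 40 = minimal measurable abundance)
with a warning reporting the count. Imputing at the limit is
conservative: it never manufactures expression, only bounds it from
below.

**Endogenous-control Livak (single-assay mode).** When only a few
targets are re-measured by individual assays, the per-sample reference
is the mean Cq of two endogenous reference miRNAs (defaults
miR-423-5p and miR-361-5p). References must amplify in every sample;
failures are an error naming the samples, not a silent imputation.

**Quantile normalization.** Applied after the Livak step and log2
transform (the pipeline order is Livak → log2 → quantile → testing;
the `RelExprSet` metadata records both the scale and whether the
quantile step ran). Delegated to `limma::normalizeQuantiles(ties =
TRUE)`: every column is forced onto the across-sample mean of sorted
columns, ties share the mean of their rank quantiles, and the map is
idempotent.

## Reference-gene selection (geNorm)

`prefilterCandidates()` keeps assays with mean Cq strictly below 20
and complete detection — reference candidates must be abundant
everywhere. `genormM()` and `genormRank()` implement the geNorm
stability measure on linear relative quantities ($2^{\mathrm{logrq}}$,
per geNorm's published definition — the scale is a choice, since the
upstream report applies "Genorm" without stating one): the pairwise
variation $V_{jk}$ is the standard deviation across samples of
$\log_2(q_j/q_k)$, the stability $M_j$ is the mean of $V_{jk}$ over
partners, and the least stable candidate is excluded each round until
a pair remains (ties broken by removing the lexicographically last
name, for determinism). The pairwise-variation series $V(n/n+1)$
compares normalization factors built from the $n$ versus $n+1$ most
stable candidates; geNorm's conventional $V < 0.15$ rule is reported
but not enforced, since the number of references is ultimately a
study design decision. The published study's own values for its final
pair (average stability 0.23, pairwise variation 0.065) derive from
raw plasma data that are not public; they are context, not
reproduction targets.

## Marker screening: the random variance model

With ~20 samples per arm and hundreds of assays, per-assay variance
estimates are noisy; the random variance model stabilizes them by
treating the true residual variances as draws from an inverse-gamma
prior. Equivalently the observed pooled variances satisfy
$s^2 \cdot a b \sim F(\mathrm{df}, 2a)$, which is the form used for
the maximum-likelihood fit of $(a, b)$ (`fitRvmHyperparams()`;
Nelder–Mead on log-parameters, method-of-moments start, convergence
status reported). The moderated test
(`rvmTTest()`) replaces $s^2$ by
$\tilde s^2 = (\mathrm{df}\, s^2 + 2/b)/(\mathrm{df} + 2a)$ and
refers $t$ to $\mathrm{df} + 2a$ degrees of freedom, i.e. the prior
contributes $2a$ pseudo-observations of variance scale $1/(ab)$. In
the homogeneous limit (all variances equal) the fit drives
$a \to \infty$ with $1/(ab)$ pinned at the common value, so the
moderated variances collapse to it; with `hyper = NULL` the classical
pooled t-test is recovered exactly. P-values are two-sided (markers
can be over- or under-represented). Selection uses raw `p < 0.05`
combined with a signed fold change $|\mathrm{FC}| \ge 1.5$
(`FC = 2^\Delta` for up, `-2^{-\Delta}` for down, so
$|\mathrm{FC}| \ge 1$ always); a Benjamini–Hochberg column is emitted
for information but deliberately not used for selection, matching the
screening design the package reproduces. Classifier candidates are
the *up-regulated* significant markers only: a blood test should key
on analytes the tumor adds to plasma.

## Classifier training and the published score

`trainSvmRfe()` trains a linear soft-margin SVM (C = 1, features
standardized with training-fold statistics) and eliminates one
feature at a time by smallest squared weight, reporting apparent and
leave-one-out accuracies for each requested model size. The C = 1 /
linear-kernel configuration is the common default for this kind of
low-dimensional marker panel and is exposed through the function
arguments rather than hard-coded policy. Crucially, the elimination
path is recomputed inside every LOOCV fold: selecting features on the
full data and then cross-validating only the final fit would leak the
left-out sample into feature selection and bias accuracy upward.

Two properties of the LOOCV estimate are worth knowing when reading
test output. First, with balanced classes each training fold is
imbalanced by exactly one sample *against* the left-out class, so
under a permutation null the LOOCV accuracy sits slightly **below**
the majority rate (we measure ≈ 0.47–0.49 instead of 0.5 at n = 40);
this pessimism is a property of leave-one-out itself, not of the
elimination procedure, and the package's null check therefore asserts
the absence of *optimistic* bias (one-sided) plus a gross lower
bound. Second, apparent accuracy at small n is always optimistic;
both numbers are reported side by side for that reason.

The published four-miRNA score is a fixed linear functional,
`score = 1.037·let-7e-5p + 0.9·miR-106a-5p + 0.247·miR-28-3p +
0.903·miR-542-5p` over log2 relative quantities, with no intercept,
and strict thresholds 1.024 (TLDA scale), 2.442 (single-assay scale)
and 19.14 (equal weights, externally normalized matrices such as
RNA-seq). The elimination path that produced these weights is not
recoverable from public data, so `publishedSignature()` treats them
as constants; `calibrateThreshold()` reproduces the *procedure* used
to rescale the threshold on a new quantification scale — an
exhaustive search over midpoints between adjacent sorted unique
scores (plus one point beyond each extreme) maximizing overall
accuracy, ties broken by higher specificity then lower threshold
(determinism; specificity is preferred because the score screens a
mostly non-cancer population). Marker names are matched
case-insensitively with an optional `hsa-` prefix, since external
matrices vary in naming; arm suffixes (`-5p`/`-3p`) must match.

## Diagnostic performance reporting

`diagnosticMetrics()` reports sensitivity, specificity, PPV, NPV and
accuracy with continuity-corrected Wilson 95% intervals. The corrected
Wilson interval is fixed as the CI method because it reproduces the
conventions of the classic clinical-test calculators to the printed
decimal (e.g. 8/10 → 44.2–96.5%), where the uncorrected interval does
not; a metric with an empty denominator is reported as undefined
(`NA`), never as zero. Percentages are rounded half-up to one decimal
for report parity; raw proportions are always retained. `rocAuc()`
computes the Mann–Whitney AUC (ties counted ½, equal to the
trapezoidal area under the empirical ROC) with a Hanley–McNeil
standard-error CI. `sampleSizeEstimate()` evaluates the
finite-population mean-estimation formula
$n = N s^2 t^2 / ((N-1)e^2 + s^2 t^2)$; note that with a population
of 200, Cq 17.78 ± 1.92, $t = 2.306$ and $e$ = 5% of the mean it
evaluates to ≈ 21.9, so published per-group sizes around 16 should be
read as a design target rather than a value this formula reproduces.

## The synthetic cohort generator

`simulateCqDataset()` exists so that every stage is testable without
any external download. Its defaults are the study conditions the
pipeline assumes: a 381-assay panel over five histology strata
(default 20 samples each, the size at which the screening chain has
comfortable power and close to the real per-group range of 17–27);
six planted assays up-regulated in cancer by 1.5 log2 units
(implemented as a 1.5-cycle Cq decrease — one cycle is one doubling);
two stable endogenous-like assays (baseline ~N(18, 1), technical sd
0.1 cycles, mirroring the abundance of the real reference pair); the
two hemolysis indicator assays at baselines 19 and 17 so the clean
delta is ≈ 2; per-assay baselines ~N(32, 6) with censoring at cycle
40, which makes a realistic minority (~10%) of low-abundance assays
fail the 95% detection filter; and per-reaction technical noise of
0.5 cycles, typical qPCR replicate variability. Planted markers draw
their baselines from N(26, 2) — detectable by construction, as real
markers must be to survive screening. Hemolysis contamination is off
by default (the real pipeline excludes such samples before analysis)
and `injectHemolysis()` plants it deterministically by lowering the
miR-451a Cq until the delta strictly exceeds 7.

What the generator does **not** emulate: correlated co-regulated
miRNA modules, between-batch effects, assay-specific amplification
efficiencies (the Livak model assumes perfect doubling), heavy-tailed
or sample-quality-driven dropout, or unequal group sizes. Passing
tests on this generator therefore demonstrate that the chain recovers
planted truth under its own statistical assumptions — idealized but
honest power/calibration checks — not that the published biological
signature is re-derivable, which would require the original plasma
measurements.

## Numerical and design notes

* Problem sizes in the shipped checks (chosen to keep the default
  suite quick while leaving no power doubts): oracle comparisons on
  5×5–6×6 toy matrices at 1e-10; RVM recovery at 2000 assays
  (within 15% of truth); type-I error at 1000 null assays; marker
  recovery over 100 generator seeds; permutation null over 50
  permutations at n = 40.
* All iterative pieces are deterministic: geNorm ties break
  lexicographically, threshold calibration ties break by specificity
  then value, RFE ties resolve by `which.min` order.
* Degenerate inputs are errors, not guesses: single-class labels,
  zero-variance items under correlation distance, all-zero variances
  in the RVM fit, missing markers at scoring time.
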