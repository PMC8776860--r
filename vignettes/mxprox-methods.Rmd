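---
title: "Methods: spatial proximity and survival modelling in mxprox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial proximity and survival modelling in mxprox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxprox)
```

## Scope and data model

`mxprox` starts where image analysis ends: at a per-slide table of cell
centroids (µm, origin top-left, y downward) with binary marker calls from a
declared panel and a nucleated flag. Everything upstream — registration,
pixel classification, segmentation, intensity thresholding — is out of
scope; marker calls are binary at ingest. If the analyzed tissue area is not
supplied, it is approximated by the axis-aligned bounding box of the
nucleated cells (logged); densities therefore assume the slide was cropped
to tissue. Whether "nucleated" means hematoxylin-positive nuclei or all
segmented objects is a segmentation-pipeline decision; the flag is simply
passed through and the caller decides what it carries.

## Slide-level quantification

Three per-slide metrics feed the paired analysis:

* **Density**: marker-positive cells / area (cells/mm²). By construction
  `density × area` reconstructs the integer count exactly.
* **Frequency**: 100 × (nucleated marker⁺ cells) / (nucleated cells).
* **Pair statistic**: the number of *distinct* target (SOX10⁺) cells having
  at least one reference (CD8⁺) cell within Euclidean centroid distance
  r, divided by the reference count. The default r = 45 µm reflects the
  spatial scale over which paracrine signalling between cells is effective;
  an any-distance variant (every target pairs iff any reference exists) is
  reported alongside.

Pairing semantics were genuinely open: "number of paired cells" could count
cells or (target, reference) edges. We count distinct cells — the quantity
is then bounded by the target count and reads as "how many tumor cells sit
near a T cell" — and provide the all-edges reading behind
`mode = "edges"`. The boundary is inclusive (distance ≤ r pairs), distances
are centroid-to-centroid with no membrane correction, and comparisons use
squared distances so a tie at exactly d = r never depends on sqrt rounding.

The fixed-radius search buckets reference cells on a uniform grid of cell
size r and scans the 3×3 neighborhood of each target's bucket; it is exact,
and the test suite holds it to equality with an exhaustive O(n²) oracle on
100 random instances including engineered boundary ties.

Per patient, each metric is reduced to `log2(post/pre)`. A zero in either
slide leaves the fold-change *undefined*: it propagates as a flagged missing
value, is excluded pairwise from correlations (with the exclusion logged),
and no pseudocount is applied unless explicitly requested
(`pseudocount = ε`, logged). Paired pre-vs-post comparisons use the Wilcoxon
matched-pairs signed-rank test and PFS associations use Spearman rank
correlation; a quadratic least-squares fit with a pointwise 95% t-band
(n − 3 df) is provided as the visualization layer.

## Statistical conventions

* **Wilcoxon signed-rank.** Zero differences are discarded (classic
  convention, logged). For n ≤ 25 the two-sided p is exact: the null
  distribution of the signed-rank sum over all 2ⁿ sign assignments is built
  by convolution over doubled average ranks (so ties are exact too), and p
  is the probability of a statistic at least as far from the symmetric
  center as observed. Beyond n = 25 the normal approximation with
  tie-corrected variance is used, without continuity correction; the method
  is recorded in the result.
* **Spearman.** Average ranks for ties; rho is the Pearson correlation of
  ranks, hence invariant to strictly monotone transforms. The p-value uses
  the t approximation `t = rho·sqrt((n−2)/(1−rho²))` even at the n ≈ 11 of a
  paired-biopsy cohort, with the method recorded; an exact permutation p
  (all n! orderings) is available for n ≤ 10. At these sample sizes the
  asymptotic p is approximate — the recorded method keeps that visible.
* **Two-sided tests throughout**; no multiple-testing correction across the
  slide-level metric family.

## Synthetic slides: what they emulate and what they do not

`simulate_slide` draws reference cells from a homogeneous Poisson process,
target cells as a mixture of uniform placements and Gaussian displacements
(sd `attract_sigma_um`, default 15 µm) from uniformly chosen reference
cells, and an unlabeled nucleated background. Defaults (1×1 mm window,
λ_ref = λ_target = 2×10⁻⁴/µm² = 200 cells/mm², λ_other = 10⁻³/µm²) give
slide compositions in the range of immune-infiltrated tumor sections at a
size where closed-form checks are sharp yet fast; the attraction construct
emulates biologically coupled proximity at the sub-45-µm scale.

Boundary handling matters for validation. Under `boundary = "torus"`
displacements wrap, and with `attract_frac = 0` the paired fraction has the
exact Poisson void-probability form `1 − exp(−λ_ref·π·r²)` — *provided the
distance itself is the torus metric*. Planar Euclidean counting on a
bounded window truncates discs near the border and undershoots the closed
form by ≈0.02 at the default geometry, which is why `count_paired_cells`
accepts `torus_dims_um` (references are expanded by their eight periodic
images; exact for r < min(dims)/2). Real slides are always analyzed with
the planar metric; `boundary = "bounded"` (displacements clamped) exists
for realism.

The simulator does not emulate: anisotropic tissue architecture, holes and
necrotic regions (so the bounding-box area fallback is unbiased here but
not on real slides), segmentation errors or marker-call noise, and
non-Poisson clustering beyond the declared attraction. Passing tests
therefore certify the *computations*, not robustness to those artifacts.

`simulate_paired_cohort` programs the expansion–PFS link as
`log2 FC = slope · standardize(−PFS) + N(0, noise_sd)` with PFS uniform on
2–30 months, so slope > 0 always encodes "faster progression ↔ greater
tumor-cell expansion"; the programmed fold-changes are returned as ground
truth. Cohort defaults (slope 1.5, noise 0.3) put the realized Spearman
correlation in the strong-negative regime observed for tumor-cellularity
expansion while leaving visible noise. One master seed drives a named
substream per patient/slide, so regenerating a subset reproduces it.

## Cohort survival stage

Exclusion filters drop OS < 0, missing OS or OS status, and stage group
`excluded` (stage 0 and "I/II NOS"; any unparseable stage string maps to
`excluded` with a warning, making the stage mapping total). The filter logs
per-criterion counts and is idempotent. Complete cases are required;
multiple imputation and penalized variable selection are out of scope.

Modelling conventions, chosen where the field leaves room and recorded in
output rather than inferred:

* Cox partial likelihood with **Efron** tie handling (the modern default).
* Continuous predictors are reported **per IQR**: `HR = exp(β·IQR)` with CI
  endpoints transformed identically; the IQR uses linear-interpolation
  (type 7) quantiles computed on the analysis sample. Per-IQR reporting is
  invariant to affine rescaling of the covariate.
* Disease stage enters as **stratified baseline hazards**, not a covariate,
  accommodating non-proportional stage effects; the interaction analysis
  compares the main-effects model (immune score + marker) against the model
  adding score×marker by likelihood ratio (`2Δll`, df = added terms).
* **Median split** dichotomizes at the sample median with ties to `low`
  (logged), used for KM visualization groups and the four marker×CD8
  subgroups, whose six pairwise Wilcoxon rank-sum p-values are multiplied
  by 6 and capped at 1; a fully tied comparison is reported as p = 1 and a
  subgroup smaller than 2 flags its comparisons rather than computing them.
* **c-index**: Harrell's concordance (risk-score ties count 0.5), with
  bootstrap optimism correction — B = 200 by default under a single
  documented seed; optimism is the mean of (c on the bootstrap sample −
  that model's c on the original data), subtracted from the apparent c.

`simulate_survival_cohort` generates exponential event times with hazard
`baseline_hazard · exp(Σβx)` and independent exponential censoring, plus
declared covariate distributions, optional product-term coefficients, and
downstream expression columns programmed on log2 scale — enough structure to
exercise every estimator against its programmed truth.

## Numerical choices and degenerate inputs

Undefined quantities are values, not crashes: zero reference cells flag the
pair statistic `NA`; an all-zero difference vector or a constant covariate
is an error named for its cause; a degenerate Wilcoxon or skipped Spearman
inside the pipeline is reported with its reason and the run completes. The
LR statistic is clamped at 0 within a 10⁻⁶ tolerance and a larger reduced
log-likelihood raises a nesting/convergence error.

## Problem sizes used in validation

The suite validates on sizes where the checks are sharp and quick: 100
random 200×200-point slides for oracle equivalence, 50–60 torus slides for
the closed form (3 Monte-Carlo-SE band), all n ≤ 12 for exact-p
enumeration, n = 2000 for HR recovery with 500 replicates of n = 150 for CI
coverage, 1000 replicates for null-calibration KS checks, and 40 seeds ×
B = 60 for the optimism property. These are the package's validation
scales; the estimators themselves have no size limits beyond memory.

## Known limitations

Densities depend on the area denominator, and the bounding-box fallback is
only a proxy for a tissue mask. The pair statistic is a first-order count,
deliberately short of K-function or permutation-based neighborhood
enrichment (out of scope). Spearman p-values at n ≈ 11 rely on an
asymptotic approximation unless the exact option is used. The survival
simulator's exponential baseline cannot probe departures from proportional
hazards other than the stage stratification it was built to exercise.
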