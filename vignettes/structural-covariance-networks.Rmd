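---
title: "Structural covariance networks: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scovnet)
```

## The model

A structural covariance network treats atlas regions as nodes and the
Pearson correlation of a morphometric measure — here regional gray-matter
volume (GMV, mL) — across the subjects of one group as edge weights. The
pipeline is:

1. **Residualization.** For each region independently, ordinary least
   squares of volume on an intercept plus age (years), sex (0/1) and total
   intracranial volume (mL). Residuals are exactly mean-centered and
   orthogonal to the retained covariates; constant or collinear covariates
   are dropped with a warning rather than failing. Because OLS residuals are
   invariant to affine recoding of a regressor, the 0/1 sex coding is a
   convention, not an assumption (asserted in the tests).
2. **Correlation.** Pairwise Pearson correlation of the residuals over
   subjects gives a symmetric N × N matrix; the diagonal is fixed to zero
   (no self-connections). At least 3 subjects are required; zero-variance
   regions yield zero correlations with a warning.
3. **Thresholding.** At target sparsity *s* the top
   `round(s · N(N−1)/2)` edges are kept and set to 1. The grid is 0.19 to
   0.49 in steps of 0.02 (16 densities), built from integer step indices so
   the endpoints are floating-point exact.
4. **Metrics, hubs, degree fits, robustness, permutation inference** on the
   binary graphs, as described below.

All group-level containers are S4 classes with validity checks; the cohort
itself extends `SummarizedExperiment` (regions × subjects assay, covariates
in `colData`), so standard Bioconductor subsetting applies.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| sparsity grid | 0.19–0.49, step 0.02 | edge density | the standard range over which group SCNs stay connected but non-trivial; all curve metrics and AUCs use it |
| `nPerm` | 1000 | permutations | resolves p to 1/1001 with the +1 correction; fewer than 100 triggers a granularity warning |
| `nNull` | 100 | rewired graphs | small-world normalization; the across-seed spread of σ at 100 nulls is below 5% on default synthetic graphs |
| `nSim` | 1000 | removal orders | random-failure averaging; Monte-Carlo error of the LCC curve scales as 1/√nSim |
| hub rule | mean + 1.5 SD | degrees | sample SD (n−1); membership is strictly above the threshold, so all-equal degrees give no hubs |
| PSQI cutoff | 5 | score | total score strictly above 5 labels a subject as sleep-disordered when groups are derived from PSQI |

## The synthetic-data generator

The generator exists so that every downstream stage has a stated,
reproducible world to be tested in. Regional volumes for subject *i*, region
*j* in block *b(j)* are

> v_ij = mu_j + beta_age,j age_i + beta_sex,j sex_i + beta_tiv,j tiv_i +
> noiseSd · z_ij,
> z_ij = sqrt(rhoOut) g_i + sqrt(rhoIn − rhoOut) f_i,b(j) + sqrt(1 − rhoIn) e_ij,

with one shared standard-normal factor *g*, one factor *f* per block and
idiosyncratic noise *e*. This latent-factor construction makes the implied
block-constant correlation matrix positive semi-definite *by construction*,
so the constructor only needs to enforce 0 ≤ rhoOut ≤ rhoIn < 1; anything
else is rejected.

Defaults state a realistic young-adult MRI cohort once and are not meant to
be tuned: 30 subjects/group, 90 regions in six 15-region blocks (a coarse
module structure of the scale seen in lobar covariance), rhoIn = 0.5,
rhoOut = 0.1, mean regional volume 8 mL with residual SD 0.8 mL (≈10%
coefficient of variation of AAL regional GMV), age ~ N(25, 8) years (the
cohorts this emulates are young adults), sex ~ Bernoulli(0.5), TIV ~
N(1450, 120) mL, and small covariate slopes (−0.02 mL/yr, 0.3 mL, 0.004
mL/mL). All randomness derives from one user seed through a documented
substream rule (`seed · 48271 + 1009 · groupIndex mod 2³¹−1`), so the order
in which groups are generated cannot change any group's draw.

What the generator does **not** emulate: measurement noise correlated with
covariates, non-Gaussian volume distributions, spatially graded (distance-
dependent) covariance, site/scanner effects, or any region-specific mean
profile. A green test therefore establishes that the machinery is correct
and calibrated under exchangeable multivariate-normal data — not that any
particular clinical contrast is detectable.

Degree samples for distribution-fit testing are drawn from the truncated
power-law PMF ∝ d^(1/k) e^(−d/dc) on the finite support 1..dMax
(default 50, covering realistic SCN degree histograms) by inverse-CDF
lookup — exact and rejection-free. `dc = Inf` is the documented flag for
dropping the exponential cutoff.

## Numerical choices

- **Edge ranking.** Thresholding ranks *signed* correlations
  (most-positive first), the convention of the graph-analysis toolbox
  lineage this pipeline follows; absolute-value ranking is available via
  `ranking = "absolute"`. The choice is documented rather than guessed as
  anyone's intent.
- **Tie-breaking.** At the threshold boundary, ties are broken by
  (weight descending, then region-pair index). This makes thresholding
  deterministic and the edge sets *nested* along the grid, which the tests
  assert.
- **Edge count rounding.** `round` half away from zero of s·N(N−1)/2
  (base R's banker's rounding is deliberately not used); at N = 90 and
  s = 0.19 this gives exactly 761 edges.
- **Disconnected graphs.** Lp is the mean distance over *reachable* ordered
  pairs, with the unreachable fraction reported alongside; this keeps Lp
  finite and comparable across permutations. Eglob uses inverse distances
  with 1/∞ = 0 and needs no special-casing. The empty graph gets Lp = NA
  with reachable fraction 0.
- **Small-world nulls.** 100 degree-preserving double-edge-swap graphs with
  10·|E| rewiring trials each (igraph's `keeping_degseq`); degree
  preservation avoids attributing degree-sequence effects to clustering or
  path length. Complete graphs admit no rewiring and return γ = λ = σ = 1
  with a warning.
- **Betweenness normalization** divides by (N−1)(N−2) ordered pairs, so a
  path middle-node and a star center both score exactly 1.
- **AUC** is always the trapezoid rule on the actual grid values.
- **Truncated power-law fitting** is least squares of s·d^(1/k)·e^(−d/dc)
  against the empirical relative-frequency table (PMF scale by default,
  matching degree histograms; a CCDF-scale option exists). The scale s is
  profiled out analytically; (log k, log dc) are optimized by L-BFGS-B from
  a 30-point multistart grid with bounded parameters, and non-convergence is
  a flagged result, never an exception. r² = 1 − SSres/SStot on the fitted
  scale. The printed form of the model reads as exponent 1/k; because that
  typesetting is ambiguous in parts of the literature, the alternative
  d^(k−1) reading is exposed via `exponentForm = "k-1"` without being the
  default.
- **Attack protocol.** Targeted attack recomputes degrees after every
  removal (adaptive — the stricter standard percolation protocol; a static
  ordering is available via `adaptive = FALSE`), breaking ties by node
  order. LCC sizes for a fixed removal order are computed by the reverse
  addition-order union-find trick, O(N + E) per order. LCC is normalized by
  the original N so curves from different steps are comparable.
- **Permutation test.** Residualization happens once on the pooled fit
  before permuting — re-residualizing within permuted labels would be
  ill-posed, and the permuted quantities are meant to be covariate-corrected
  volumes. The two-tailed p uses the +1 correction, guaranteeing p ≥
  1/(nPerm+1) and validity; exhaustive enumeration (all distinct splits,
  identity included) is exact for small cohorts and is tested against an
  independent brute-force oracle. Nodal summaries produce one AUC test per
  region; `fdrCorrect()` applies Benjamini–Hochberg, the field default,
  since no particular correction is canonical here.
- **Three groups** are compared as the three pairwise contrasts; no omnibus
  permutation ANOVA is attempted.
- **Hub degree basis.** Hubs are declared on the per-region degree averaged
  across the 16-density grid — declaring them at one density would be
  arbitrary; a single-density option is exposed (`hubAnalysis(graphs,
  density = "0.19")`).

## Design choices where the design was open

- The cohort container is a `SummarizedExperiment` subclass rather than a
  pair of data frames: it keeps values and covariates aligned under
  subsetting and is the idiom downstream Bioconductor users expect.
- Metric evaluation inside the permutation engine exploits nestedness:
  edges are ranked once per permutation and added cumulatively across the
  grid, and clustering/transitivity are computed by matrix algebra; this is
  what makes 200-replicate calibration studies and 1000-permutation runs
  affordable in pure R.
- Random-failure curves use the union-find percolation trick instead of
  repeated component searches — identical results, ~N-fold faster.
- The robustness group comparison runs through the same permutation
  framework as every other summary (`statistic = "robustness.random"` or
  `"robustness.targeted"`), with the per-density robustness AUC as the
  curve value.

## Known limitations

- Cp, T and Eloc are *not* mathematically monotone in density along the
  nested threshold sequence (adding a pendant edge to a triangle lowers
  Cp); on modular correlation networks they are monotone only up to small
  dips, and the test suite asserts exactly that (Eglob, which is provably
  monotone, is asserted strictly).
- Group-level SCNs yield one network per group, so no subject-level
  network covariates or brain-behavior correlations are possible;
  subject-level (cube- or distance-based) construction is out of scope.
- Weighted-graph metric variants are not implemented; the analysis is
  binary-graph only.
- The log-rank comparison treats degrees as uncensored event times; with 90
  tied-heavy integer observations per group its null calibration is checked
  by simulation in the tests (type-I error within [0.03, 0.07]).
- `igraph`'s rewiring counts *trials*, not accepted swaps; with 10·|E|
  trials the acceptance rate is high enough that the null ensemble is
  indistinguishable for these graph sizes (σ seed-stability < 5%).
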