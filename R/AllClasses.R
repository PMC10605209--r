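#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd quantile pchisq p.adjust optim setNames
#'   rnorm rbinom runif
#' @importFrom utils head tail combn write.csv read.csv packageVersion
NULL

#' GMVCohort: a subjects-by-regions morphometry cohort
#'
#' An S4 container for a cohort of regional gray-matter volumes. It extends
#' \linkS4class{SummarizedExperiment}: the `"gmv"` assay holds regions in rows
#' and subjects in columns, and `colData` carries the per-subject covariates
#' (`age` in years, `sex` coded 0/1, `tiv` total intracranial volume in mL)
#' plus the `group` label. After \code{\link{residualize}} a `"resid"` assay
#' with covariate-adjusted volumes is added.
#'
#' @seealso \code{\link{gmvCohort}}, \code{\link{generateCohort}},
#'   \code{\link{residualize}}
#' @export
setClass("GMVCohort", contains = "SummarizedExperiment")

setValidity("GMVCohort", function(object) {
  msg <- character()
  if (!"gmv" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'gmv' is required")
  else {
    v <- SummarizedExperiment::assay(object, "gmv")
    if (anyNA(v) || !all(is.finite(v)))
      msg <- c(msg, "gmv values must be finite and non-missing")
  }
  cd <- SummarizedExperiment::colData(object)
  for (f in c("age", "sex", "tiv", "group"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData column '%s' is required", f))
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids (colnames) must be present and unique")
  if (is.null(rownames(object)))
    msg <- c(msg, "region labels (rownames) must be present")
  if ("sex" %in% colnames(cd) && !all(cd$sex %in% c(0, 1)))
    msg <- c(msg, "sex must be coded 0/1")
  if (length(msg)) msg else TRUE
})

#' CovarianceNetwork: a group-level correlation network
#'
#' Symmetric matrix of pairwise Pearson correlations between regional
#' (covariate-adjusted) volumes across the subjects of one group, with the
#' diagonal fixed to zero (no self-connections).
#'
#' @slot weights numeric N x N symmetric matrix of Pearson r with zero diagonal.
#' @slot groupLabel character(1) group the network belongs to.
#' @slot nSubjects integer(1) number of subjects the correlations are based on.
#' @seealso \code{\link{correlationNetwork}}, \code{\link{thresholdBySparsity}}
#' @export
setClass("CovarianceNetwork",
         representation(weights = "matrix", groupLabel = "character",
                        nSubjects = "integer"))

setValidity("CovarianceNetwork", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (is.null(rownames(w)) || !identical(rownames(w), colnames(w)))
    msg <- c(msg, "weights must carry identical row/column region labels")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
    msg <- c(msg, "weights must be symmetric")
  if (any(abs(diag(w)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(!is.finite(w)) || any(abs(w) > 1 + 1e-10))
    msg <- c(msg, "weights must be finite correlations in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' BinaryGraph: an undirected 0/1 adjacency at a target sparsity
#'
#' @slot adjacency numeric N x N 0/1 symmetric matrix with zero diagonal.
#' @slot sparsity numeric(1) target edge density in (0, 1].
#' @slot edgeCount integer(1) number of undirected edges.
#' @seealso \code{\link{thresholdBySparsity}}, \code{\link{binaryGraph}}
#' @export
setClass("BinaryGraph",
         representation(adjacency = "matrix", sparsity = "numeric",
                        edgeCount = "integer"))

setValidity("BinaryGraph", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be 0/1")
  if (!identical(unname(a), unname(t(a)))) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  n <- nrow(a)
  npairs <- n * (n - 1) / 2
  if (sum(a) != 2L * object@edgeCount)
    msg <- c(msg, "edgeCount must equal half the number of 1 entries")
  if (object@sparsity <= 0 || object@sparsity > 1)
    msg <- c(msg, "sparsity must lie in (0, 1]")
  if (npairs > 0 && abs(object@edgeCount / npairs - object@sparsity) > 1 / npairs + 1e-12)
    msg <- c(msg, "realized density must be within 1/(N(N-1)/2) of the target sparsity")
  if (length(msg)) msg else TRUE
})

#' MetricCurve: a global metric across the sparsity grid
#'
#' @slot grid numeric vector of densities (the sparsity grid).
#' @slot values numeric vector, metric value at each density.
#' @slot metric character(1) registered metric name.
#' @slot auc numeric(1) trapezoidal area under the curve over the grid.
#' @seealso \code{\link{metricCurve}}, \code{\link{sparsityGrid}}
#' @export
setClass("MetricCurve",
         representation(grid = "numeric", values = "numeric",
                        metric = "character", auc = "numeric"))

setValidity("MetricCurve", function(object) {
  if (length(object@values) != length(object@grid))
    return("values and grid must have the same length")
  TRUE
})

#' HubSet: degree-based network hubs
#'
#' Regions whose degree summary exceeds the across-region mean by more than
#' 1.5 sample standard deviations.
#'
#' @slot hubRegions character vector of hub labels, degree-descending.
#' @slot degreeBasis named numeric vector, the per-region degree summary used.
#' @slot threshold numeric(1) the mean + 1.5 SD cutoff.
#' @seealso \code{\link{identifyHubs}}
#' @export
setClass("HubSet",
         representation(hubRegions = "character", degreeBasis = "numeric",
                        threshold = "numeric"))

setValidity("HubSet", function(object) {
  b <- object@degreeBasis
  if (length(object@hubRegions) > length(b)) return("more hubs than regions")
  if (length(object@hubRegions) &&
      any(b[object@hubRegions] <= object@threshold))
    return("every hub must strictly exceed the threshold")
  TRUE
})

#' DegreeDistributionFit: truncated power-law fit of a degree distribution
#'
#' Least-squares fit of \eqn{P(d) = s \, d^{1/k} \exp(-d/d_c)} to an empirical
#' degree distribution.
#'
#' @slot k numeric(1) power exponent (NA on failure).
#' @slot dc numeric(1) cutoff degree (NA on failure).
#' @slot scale numeric(1) fitted normalization constant.
#' @slot r2 numeric(1) goodness of fit, 1 - SS_res/SS_tot on the fitted scale.
#' @slot converged logical(1) whether the fit succeeded.
#' @slot support integer vector, degree range used for fitting.
#' @seealso \code{\link{fitTruncatedPowerlaw}}
#' @export
setClass("DegreeDistributionFit",
         representation(k = "numeric", dc = "numeric", scale = "numeric",
                        r2 = "numeric", converged = "logical",
                        support = "integer"))

#' RobustnessCurve: largest-component decay under node removal
#'
#' @slot fractionsRemoved numeric vector 0, 1/N, ..., (N-1)/N.
#' @slot lccRelativeSize numeric vector, largest-connected-component size / N
#'   after each removal count (averaged over simulations in random mode).
#' @slot attackType character(1), "random" or "targeted".
#' @slot nSim integer(1) number of simulated removal orders (1 for targeted).
#' @slot auc numeric(1) trapezoidal area of the curve.
#' @seealso \code{\link{randomFailure}}, \code{\link{targetedAttack}}
#' @export
setClass("RobustnessCurve",
         representation(fractionsRemoved = "numeric", lccRelativeSize = "numeric",
                        attackType = "character", nSim = "integer",
                        auc = "numeric"))

setValidity("RobustnessCurve", function(object) {
  msg <- character()
  if (length(object@fractionsRemoved) != length(object@lccRelativeSize))
    msg <- c(msg, "fractions and sizes must align")
  if (any(diff(object@lccRelativeSize) > 1e-12))
    msg <- c(msg, "LCC relative size must be non-increasing")
  if (!object@attackType %in% c("random", "targeted"))
    msg <- c(msg, "attackType must be 'random' or 'targeted'")
  if (length(msg)) msg else TRUE
})

#' PermResult: AUC-summarized permutation test result
#'
#' @slot statistic character(1) name of the network summary compared.
#' @slot grid numeric vector of densities the summary was evaluated on.
#' @slot observedAUC numeric vector (length 1 for global summaries, one per
#'   region for nodal ones): group A minus group B AUC difference.
#' @slot observedCurve numeric matrix (densities x components) of per-density
#'   differences.
#' @slot nullAUC numeric matrix (permutations x components) of null AUC
#'   differences.
#' @slot p numeric vector of two-tailed p-values.
#' @slot nPerm integer(1) number of permutations (distinct splits when
#'   exhaustive).
#' @slot ci95 numeric matrix (2 x densities) of per-density 2.5/97.5 null
#'   percentiles (empty for nodal summaries).
#' @slot exhaustive logical(1) whether all distinct splits were enumerated.
#' @seealso \code{\link{permutationTest}}
#' @export
setClass("PermResult",
         representation(statistic = "character", grid = "numeric",
                        observedAUC = "numeric", observedCurve = "matrix",
                        nullAUC = "matrix", p = "numeric", nPerm = "integer",
                        ci95 = "matrix", exhaustive = "logical"))

setValidity("PermResult", function(object) {
  msg <- character()
  if (nrow(object@nullAUC) != object@nPerm)
    msg <- c(msg, "null distribution must have nPerm rows")
  if (any(object@p <= 0) || any(object@p > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: generating law for a synthetic GMV cohort
#'
#' Describes a multivariate-normal cohort with block-modular inter-regional
#' correlation and additive linear covariate effects. The implied
#' block-constant correlation matrix is positive semi-definite by the latent
#' factor construction (one global factor with loading sqrt(rhoOut), one
#' factor per block with loading sqrt(rhoIn - rhoOut), idiosyncratic noise),
#' so the constructor only needs to enforce 0 <= rhoOut <= rhoIn < 1.
#'
#' @slot nSubjectsPerGroup integer(1).
#' @slot nRegions integer(1).
#' @slot moduleSizes integer vector partitioning the regions into blocks.
#' @slot rhoIn numeric(1) within-block correlation.
#' @slot rhoOut numeric(1) between-block correlation.
#' @slot mu numeric vector of per-region mean volumes (mL).
#' @slot covariateBetas numeric nRegions x 3 matrix of age/sex/tiv slopes.
#' @slot covariateDistributions list with ageMean, ageSd, pMale, tivMean, tivSd.
#' @slot groupEffects named list of per-group rhoIn/rhoOut overrides.
#' @slot noiseSd numeric(1) per-region residual standard deviation (mL).
#' @slot groups character vector of group labels.
#' @slot regionLabels character vector of region labels.
#' @seealso \code{\link{syntheticSpec}}, \code{\link{generateCohort}}
#' @export
setClass("SyntheticSpec",
         representation(nSubjectsPerGroup = "integer", nRegions = "integer",
                        moduleSizes = "integer", rhoIn = "numeric",
                        rhoOut = "numeric", mu = "numeric",
                        covariateBetas = "matrix",
                        covariateDistributions = "list",
                        groupEffects = "list", noiseSd = "numeric",
                        groups = "character", regionLabels = "character"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nSubjectsPerGroup < 3L)
    msg <- c(msg, "need at least 3 subjects per group (correlation undefined below)")
  if (sum(object@moduleSizes) != object@nRegions)
    msg <- c(msg, "moduleSizes must partition the regions")
  if (any(object@moduleSizes < 1L)) msg <- c(msg, "module sizes must be positive")
  rhos <- c(list(c(object@rhoIn, object@rhoOut)),
            lapply(object@groupEffects, function(e)
              c(if (!is.null(e$rhoIn)) e$rhoIn else object@rhoIn,
                if (!is.null(e$rhoOut)) e$rhoOut else object@rhoOut)))
  for (r in rhos) {
    if (r[2] < 0 || r[2] > r[1] || r[1] >= 1)
      msg <- c(msg, sprintf(
        "correlation spec (rhoIn=%g, rhoOut=%g) is not positive semi-definite under the block model (need 0 <= rhoOut <= rhoIn < 1)",
        r[1], r[2]))
  }
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (length(object@mu) != object@nRegions)
    msg <- c(msg, "mu must have one entry per region")
  if (nrow(object@covariateBetas) != object@nRegions ||
      ncol(object@covariateBetas) != 3L)
    msg <- c(msg, "covariateBetas must be nRegions x 3 (age, sex, tiv)")
  if (length(object@regionLabels) != object@nRegions)
    msg <- c(msg, "regionLabels must have one entry per region")
  if (length(msg)) msg else TRUE
})
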