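#' Construct a GMVCohort from subject-level tables
#'
#' @param gmv numeric subjects x regions matrix of gray-matter volumes (mL),
#'   with subject ids as rownames and region labels as colnames.
#' @param covariates data.frame with one row per subject (same order or
#'   rownames matching the gmv rownames) and columns `age`, `sex` (0/1),
#'   `tiv`, and `group`.
#' @return A \linkS4class{GMVCohort}.
#' @examples
#' gmv <- matrix(rnorm(5 * 4, 8), 5, 4,
#'               dimnames = list(paste0("s", 1:5), paste0("r", 1:4)))
#' cov <- data.frame(age = 20:24, sex = c(0, 1, 0, 1, 0), tiv = rep(1450, 5),
#'                   group = "HC", row.names = rownames(gmv))
#' gmvCohort(gmv, cov)
#' @export
gmvCohort <- function(gmv, covariates) {
  gmv <- as.matrix(gmv)
  if (is.null(rownames(gmv))) rownames(gmv) <- paste0("sub", seq_len(nrow(gmv)))
  if (is.null(colnames(gmv))) stop("gmv must carry region labels as colnames")
  if (!is.null(rownames(covariates)) &&
      !all(rownames(covariates) == as.character(seq_len(nrow(covariates))))) {
    if (!setequal(rownames(covariates), rownames(gmv)))
      stop("covariate subject ids do not match the GMV table")
    covariates <- covariates[rownames(gmv), , drop = FALSE]
  } else if (nrow(covariates) != nrow(gmv)) {
    stop("covariates must have one row per subject")
  }
  if (anyNA(covariates[, c("age", "sex", "tiv")]))
    stop("covariates must not contain missing values")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gmv = t(gmv)),
    colData = S4Vectors::DataFrame(covariates, row.names = rownames(gmv)))
  new("GMVCohort", se)
}

#' @describeIn gmvCohort subjects x regions matrix of raw volumes.
#' @param x a GMVCohort.
#' @export
gmvValues <- function(x) t(SummarizedExperiment::assay(x, "gmv"))

#' @describeIn gmvCohort subjects x regions matrix of covariate-adjusted
#'   residual volumes (requires \code{\link{residualize}} first).
#' @export
residValues <- function(x) {
  if (!"resid" %in% SummarizedExperiment::assayNames(x))
    stop("no 'resid' assay: run residualize() first")
  t(SummarizedExperiment::assay(x, "resid"))
}

#' @describeIn gmvCohort region labels.
#' @export
regionLabels <- function(x) {
  if (is(x, "GMVCohort")) return(rownames(x))
  if (is(x, "CovarianceNetwork")) return(rownames(x@weights))
  if (is(x, "BinaryGraph")) return(rownames(x@adjacency))
  stop("no region labels for this object")
}

#' @describeIn gmvCohort subject ids.
#' @export
subjectIds <- function(x) colnames(x)

#' @describeIn gmvCohort per-subject group labels.
#' @export
groupLabels <- function(x) as.character(SummarizedExperiment::colData(x)$group)

#' Construct a BinaryGraph from a 0/1 adjacency matrix
#'
#' Mostly useful for tests and for feeding hand-built graphs to the metric and
#' attack functions; \code{\link{thresholdBySparsity}} is the pipeline route.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity target density; defaults to the realized density.
#' @return A \linkS4class{BinaryGraph}.
#' @export
binaryGraph <- function(adjacency, sparsity = NULL) {
  adjacency <- as.matrix(adjacency)
  mode(adjacency) <- "numeric"
  n <- nrow(adjacency)
  if (is.null(rownames(adjacency))) {
    labs <- sprintf("n%02d", seq_len(n))
    dimnames(adjacency) <- list(labs, labs)
  }
  ec <- as.integer(sum(adjacency) / 2)
  if (is.null(sparsity)) sparsity <- if (n > 1) ec / (n * (n - 1) / 2) else 1
  new("BinaryGraph", adjacency = adjacency, sparsity = sparsity, edgeCount = ec)
}

#' @describeIn binaryGraph the 0/1 adjacency matrix.
#' @param g a BinaryGraph (or plain adjacency matrix, returned as is).
#' @export
adjacency <- function(g) if (is(g, "BinaryGraph")) g@adjacency else as.matrix(g)

#' @describeIn binaryGraph number of undirected edges.
#' @export
edgeCount <- function(g) if (is(g, "BinaryGraph")) g@edgeCount else sum(as.matrix(g)) / 2

#' @describeIn correlationNetwork the symmetric correlation weight matrix.
#' @param net a CovarianceNetwork.
#' @export
networkWeights <- function(net) net@weights

#' @describeIn identifyHubs hub region labels, degree-descending.
#' @param x a HubSet.
#' @export
hubRegions <- function(x) x@hubRegions

#' @describeIn metricCurve the AUC stored on a MetricCurve, RobustnessCurve or
#'   the observed AUC difference of a PermResult.
#' @param x an object with an AUC summary.
#' @export
curveAUC <- function(x) {
  if (is(x, "MetricCurve") || is(x, "RobustnessCurve")) return(x@auc)
  if (is(x, "PermResult")) return(x@observedAUC)
  stop("no AUC for this object")
}

#' @describeIn metricCurve the per-density metric values.
#' @export
curveValues <- function(x) x@values

#' @describeIn permutationTest two-tailed permutation p-value(s).
#' @param x a PermResult.
#' @export
pValue <- function(x) x@p

#' @describeIn permutationTest permutation null distribution of AUC
#'   differences.
#' @export
nullDistribution <- function(x) x@nullAUC

setMethod("show", "CovarianceNetwork", function(object) {
  cat(sprintf("CovarianceNetwork: %d regions, group '%s', %d subjects\n",
              nrow(object@weights), object@groupLabel, object@nSubjects))
  w <- object@weights[upper.tri(object@weights)]
  cat(sprintf("  r range [%.3f, %.3f], mean %.3f\n", min(w), max(w), mean(w)))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d nodes, %d edges (sparsity %.3f)\n",
              nrow(object@adjacency), object@edgeCount, object@sparsity))
})

setMethod("show", "MetricCurve", function(object) {
  cat(sprintf("MetricCurve '%s' over %d densities [%.2f, %.2f]: AUC = %.4f\n",
              object@metric, length(object@grid), min(object@grid),
              max(object@grid), object@auc))
})

setMethod("show", "HubSet", function(object) {
  cat(sprintf("HubSet: %d hubs (threshold %.3f)\n",
              length(object@hubRegions), object@threshold))
  if (length(object@hubRegions))
    cat(" ", paste(object@hubRegions, collapse = ", "), "\n")
})

setMethod("show", "DegreeDistributionFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "Truncated power-law fit: k = %.4f, dc = %.4f, r2 = %.4f (support 1..%d)\n",
      object@k, object@dc, object@r2, max(object@support)))
  else cat("Truncated power-law fit: did not converge\n")
})

setMethod("show", "RobustnessCurve", function(object) {
  cat(sprintf("RobustnessCurve (%s attack%s): AUC = %.4f\n", object@attackType,
              if (object@attackType == "random")
                sprintf(", %d simulations", object@nSim) else "",
              object@auc))
})

setMethod("show", "PermResult", function(object) {
  cat(sprintf("PermResult '%s': %s permutations%s\n", object@statistic,
              object@nPerm, if (object@exhaustive) " (exhaustive)" else ""))
  if (length(object@observedAUC) == 1L)
    cat(sprintf("  observed AUC difference %.5f, two-tailed p = %.4f\n",
                object@observedAUC, object@p))
  else
    cat(sprintf("  nodal summary over %d regions; min p = %.4f\n",
                length(object@p), min(object@p)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d subjects/group x %d regions, %d blocks, rhoIn %.2f, rhoOut %.2f\n",
    object@nSubjectsPerGroup, object@nRegions, length(object@moduleSizes),
    object@rhoIn, object@rhoOut))
  cat(sprintf("  groups: %s\n", paste(object@groups, collapse = ", ")))
})
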