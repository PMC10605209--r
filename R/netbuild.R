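#' The sparsity grid for network thresholding
#'
#' The density grid over which binary networks are analyzed: 0.19 to 0.49 in
#' steps of 0.02 by default (16 values). Constructed from integer indices so
#' the endpoints are exact.
#'
#' @param from,to,by grid bounds and step, in density units.
#' @return numeric vector of densities.
#' @examples
#' sparsityGrid()          # 0.19, 0.21, ..., 0.49
#' @export
sparsityGrid <- function(from = 0.19, to = 0.49, by = 0.02) {
  steps <- .roundHalfUp((to - from) / by)
  from + by * (0:steps)
}

#' Remove covariate effects from regional volumes
#'
#' For each region independently, fits ordinary least squares of volume on an
#' intercept plus the covariates (by default age, sex and total intracranial
#' volume) and keeps the residuals. Covariates that are constant across
#' subjects (rank-deficient design) are dropped with a warning. Residual
#' columns sum to zero; OLS orthogonality makes every region uncorrelated
#' with every retained covariate.
#'
#' @param cohort a \linkS4class{GMVCohort}.
#' @param covariates character vector of colData columns to regress out.
#' @return The cohort with a `"resid"` assay added (see
#'   \code{\link{residValues}}).
#' @export
residualize <- function(cohort, covariates = c("age", "sex", "tiv")) {
  Y <- gmvValues(cohort)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  X <- as.matrix(cd[, covariates, drop = FALSE])
  res <- .residualizeMatrix(Y, X)
  SummarizedExperiment::assay(cohort, "resid") <- t(res)
  cohort
}

# residuals of Y on [1 X], dropping constant columns of X with a warning
.residualizeMatrix <- function(Y, X) {
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep))
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  design <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])
  if (nrow(Y) <= ncol(design))
    stop("need more subjects than regressors to residualize")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[seq.int(qrd$rank + 1L, ncol(design))]
    warning("dropping collinear covariate(s): ",
            paste(colnames(design)[drop_idx], collapse = ", "))
    qrd <- qr(design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE])
  }
  res <- qr.resid(qrd, Y)
  dimnames(res) <- dimnames(Y)
  res
}

#' Build a group's structural covariance network
#'
#' Pairwise Pearson correlation of (residualized) regional volumes across the
#' subjects of one group, returned as a symmetric N x N
#' \linkS4class{CovarianceNetwork} with a zero diagonal. Zero-variance regions
#' get zero correlations with a warning.
#'
#' @param x a \linkS4class{GMVCohort} (with a `"resid"` assay; falls back to
#'   raw volumes with a message) or a plain subjects x regions matrix.
#' @param group group label to subset on (ignored for matrix input).
#' @return A \linkS4class{CovarianceNetwork}.
#' @export
correlationNetwork <- function(x, group = NULL) {
  if (is(x, "GMVCohort")) {
    keep <- if (is.null(group)) rep(TRUE, ncol(x)) else groupLabels(x) == group
    if (!any(keep)) stop("no subjects in group '", group, "'")
    mat <- if ("resid" %in% SummarizedExperiment::assayNames(x)) {
      residValues(x)[keep, , drop = FALSE]
    } else {
      message("no 'resid' assay; correlating raw volumes")
      gmvValues(x)[keep, , drop = FALSE]
    }
    label <- if (is.null(group)) "all" else group
  } else {
    mat <- as.matrix(x)
    label <- if (is.null(group)) "all" else group
  }
  if (nrow(mat) < 3L) stop("need at least 3 subjects to correlate")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance region(s) set to zero correlation: ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
  w <- suppressWarnings(stats::cor(mat))
  w[!is.finite(w)] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (is.null(rownames(w))) {
    labs <- .defaultRegionLabels(ncol(mat))
    dimnames(w) <- list(labs, labs)
  }
  new("CovarianceNetwork", weights = w, groupLabel = label,
      nSubjects = nrow(mat))
}

# edge ranking shared by thresholdBySparsity and the permutation fast path:
# order of upper-triangle indices, best edge first, ties broken by (i, j)
.edgeOrder <- function(w, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  n <- nrow(w)
  ut <- which(upper.tri(w))
  i <- row(w)[ut]
  j <- col(w)[ut]
  key <- if (ranking == "signed") w[ut] else abs(w[ut])
  ut[order(-key, i, j)]
}

.edgeCountAt <- function(n, sparsity) as.integer(.roundHalfUp(sparsity * n * (n - 1) / 2))

#' Threshold a covariance network into a binary graph
#'
#' Retains exactly `round(sparsity * N(N-1)/2)` undirected edges with the
#' largest weights (round half away from zero) and sets them to 1. Ranking is
#' by signed correlation by default (most positive first), with an
#' absolute-value option; ties at the boundary are broken by region-pair
#' index, which makes the edge sets nested across increasing sparsity.
#'
#' @param net a \linkS4class{CovarianceNetwork}.
#' @param sparsity target density in (0, 1].
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return A \linkS4class{BinaryGraph}.
#' @examples
#' ## at sparsity 0.19 a 90-region network keeps round(0.19 * 4005) = 761 edges
#' @export
thresholdBySparsity <- function(net, sparsity, ranking = c("signed", "absolute")) {
  .assertScalarNumber(sparsity, "sparsity", lower = 0, upper = 1,
                      strict_lower = TRUE)
  w <- net@weights
  n <- nrow(w)
  k <- .edgeCountAt(n, sparsity)
  ord <- .edgeOrder(w, match.arg(ranking))
  a <- matrix(0, n, n, dimnames = dimnames(w))
  if (k > 0) {
    keep <- ord[seq_len(k)]
    a[keep] <- 1
  }
  a <- a + t(a)
  new("BinaryGraph", adjacency = a, sparsity = sparsity, edgeCount = k)
}

#' Threshold across the whole sparsity grid
#'
#' @param net a \linkS4class{CovarianceNetwork}.
#' @param grid densities (default \code{\link{sparsityGrid}()}).
#' @param ranking passed to \code{\link{thresholdBySparsity}}.
#' @return named list of \linkS4class{BinaryGraph}, one per density.
#' @export
thresholdGrid <- function(net, grid = sparsityGrid(), ranking = "signed") {
  out <- lapply(grid, function(s) thresholdBySparsity(net, s, ranking))
  names(out) <- sprintf("%.2f", grid)
  out
}

#' Write an adjacency matrix as TSV (with labels) or BrainNet .edge format
#'
#' @param x a \linkS4class{CovarianceNetwork} or \linkS4class{BinaryGraph}.
#' @param file output path.
#' @param format `"tsv"` writes region labels as header row/column;
#'   `"edge"` writes the bare whitespace-separated N x N matrix BrainNet
#'   Viewer expects.
#' @return invisibly, `file`.
#' @export
writeAdjacency <- function(x, file, format = c("tsv", "edge")) {
  format <- match.arg(format)
  m <- if (is(x, "CovarianceNetwork")) x@weights else adjacency(x)
  if (format == "tsv") {
    utils::write.table(m, file, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    utils::write.table(m, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}
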