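# Nonparametric permutation machinery for between-group differences of
# network summaries, AUC-aggregated across the sparsity grid.

# per-density evaluator: residual matrix -> values (vector over densities for
# scalar stats, densities x N matrix for nodal stats). Thresholding exploits
# nestedness: edges are ranked once, then added cumulatively density by
# density.
.curveEvaluator <- function(statistic, grid, ranking, options) {
  greg <- .globalStatRegistry()
  nreg <- .nodalStatRegistry()
  nodal <- statistic %in% names(nreg)
  if (!nodal && !statistic %in% names(greg))
    stop("unknown statistic '", statistic, "'; see registeredStatistics()")
  fun <- if (nodal) nreg[[statistic]] else greg[[statistic]]
  fast <- !nodal && statistic %in% c("clustering", "transitivity")
  function(mat) {
    w <- suppressWarnings(stats::cor(mat))
    w[!is.finite(w)] <- 0
    diag(w) <- 0
    n <- ncol(w)
    ord <- .edgeOrder(w, ranking)
    counts <- vapply(grid, function(s) .edgeCountAt(n, s), integer(1))
    A <- matrix(0, n, n, dimnames = dimnames(w))
    prev <- 0L
    out <- vector("list", length(grid))
    for (gi in seq_along(grid)) {
      k <- counts[gi]
      if (k > prev) {
        idx <- ord[seq.int(prev + 1L, k)]
        A[idx] <- 1
        A[cbind(col(w)[idx], row(w)[idx])] <- 1
        prev <- k
      }
      out[[gi]] <- fun(A, options)
    }
    if (nodal) do.call(rbind, out) else unlist(out)
  }
}

#' Randomly relabel subjects into two groups of the original sizes
#'
#' @param resA,resB subjects x regions residual matrices.
#' @param seed integer seed (NULL = current RNG stream).
#' @return list with `a` and `b`, a random split of the pooled subjects into
#'   groups of sizes nrow(resA) and nrow(resB).
#' @export
permuteGroups <- function(resA, resB, seed = NULL) {
  stopifnot(identical(colnames(resA), colnames(resB)))
  pooled <- rbind(resA, resB)
  nA <- nrow(resA)
  idx <- .withSeed(seed, sample.int(nrow(pooled)))
  list(a = pooled[idx[seq_len(nA)], , drop = FALSE],
       b = pooled[idx[-seq_len(nA)], , drop = FALSE])
}

#' AUC-summarized permutation test for a between-group network difference
#'
#' The observed pipeline (correlate the residualized volumes, threshold at
#' every grid density, evaluate the named summary, take the trapezoidal AUC
#' of the group A minus group B difference) is computed once on the true
#' labels, then under `nPerm` random relabelings of the pooled subjects into
#' groups of the original sizes. The two-tailed p-value is
#' `(count(|null| >= |observed|) + 1) / (nPerm + 1)` — always valid, never
#' zero, and invariant to which group is called A. With `exhaustive = TRUE`
#' all distinct splits are enumerated (identity included) and
#' `p = mean(|null| >= |observed|)` exactly.
#'
#' Residualization is done once on the pooled fit *before* permuting (the
#' permuted quantities are covariate-corrected volumes); per-density 95% null
#' envelopes are returned for difference-versus-density plots.
#'
#' @param resA,resB subjects x regions residual matrices (e.g. rows of
#'   \code{\link{residValues}} for each group).
#' @param statistic a registered summary (\code{\link{registeredStatistics}});
#'   global summaries give a scalar AUC test, nodal summaries give one AUC
#'   test per region (correct with \code{\link{fdrCorrect}}).
#' @param grid density grid (default \code{\link{sparsityGrid}()}).
#' @param nPerm number of permutations (default 1000; < 100 warns about
#'   p-value granularity).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all distinct splits (feasible for small
#'   cohorts; errors above `maxSplits`).
#' @param maxSplits guard for exhaustive enumeration (default 20000).
#' @param ranking edge ranking passed to thresholding.
#' @param options statistic options (e.g. `nSim` for robustness summaries,
#'   `nNull` for sigma).
#' @return A \linkS4class{PermResult}.
#' @export
permutationTest <- function(resA, resB, statistic = "clustering",
                            grid = sparsityGrid(), nPerm = 1000L,
                            seed = NULL, exhaustive = FALSE,
                            maxSplits = 20000L, ranking = "signed",
                            options = list()) {
  stopifnot(identical(colnames(resA), colnames(resB)))
  if (length(grid) < 2L) stop("AUC is undefined on a single-density grid")
  if (!exhaustive && nPerm < 100L)
    warning("fewer than 100 permutations: p-value granularity is coarse")
  evalCurve <- .curveEvaluator(statistic, grid, ranking, options)
  diffOf <- function(a, b) {
    ca <- evalCurve(a); cb <- evalCurve(b)
    dd <- ca - cb
    if (is.matrix(dd)) list(curve = dd, auc = apply(dd, 2, function(y) aucTrapezoid(grid, y)))
    else list(curve = matrix(dd, ncol = 1), auc = aucTrapezoid(grid, dd))
  }
  obs <- diffOf(resA, resB)
  pooled <- rbind(resA, resB)
  nA <- nrow(resA); nTot <- nrow(pooled)
  if (exhaustive) {
    if (choose(nTot, nA) > maxSplits)
      stop("too many splits for exhaustive enumeration")
    splits <- utils::combn(nTot, nA, simplify = FALSE)
    nPerm <- length(splits)
    perms <- lapply(splits, function(ix)
      diffOf(pooled[ix, , drop = FALSE], pooled[-ix, , drop = FALSE]))
  } else {
    perms <- .withSeed(seed, lapply(seq_len(nPerm), function(b) {
      ix <- sample.int(nTot)
      diffOf(pooled[ix[seq_len(nA)], , drop = FALSE],
             pooled[ix[-seq_len(nA)], , drop = FALSE])
    }))
  }
  nullAUC <- do.call(rbind, lapply(perms, function(x) x$auc))
  exceed <- vapply(seq_along(obs$auc), function(j)
    sum(abs(nullAUC[, j]) >= abs(obs$auc[j])), numeric(1))
  p <- if (exhaustive) exceed / nPerm else (exceed + 1) / (nPerm + 1)
  ci95 <- if (length(obs$auc) == 1L) {
    nullCurves <- vapply(perms, function(x) x$curve[, 1], numeric(length(grid)))
    apply(nullCurves, 1, stats::quantile, probs = c(0.025, 0.975))
  } else matrix(numeric(0), 0, 0)
  new("PermResult", statistic = statistic, grid = as.numeric(grid),
      observedAUC = unname(obs$auc), observedCurve = obs$curve,
      nullAUC = nullAUC, p = unname(p), nPerm = as.integer(nPerm),
      ci95 = ci95, exhaustive = exhaustive)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values, monotone and capped at 1, for the 90-region
#' nodal-metric comparisons.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return adjusted p-values (empty input gives empty output).
#' @examples
#' fdrCorrect(c(0.01, 0.02, 0.04, 0.5))
#' @export
fdrCorrect <- function(pValues) {
  if (!length(pValues)) return(numeric(0))
  if (any(pValues <= 0 | pValues > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(pValues, method = "BH")
}
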