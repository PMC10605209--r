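#' Specify the generating law for a synthetic GMV cohort
#'
#' Builds a validated \linkS4class{SyntheticSpec}. The generated cohort has
#' per-region volumes that are multivariate normal with a block-constant
#' inter-regional correlation (rhoIn within a block, rhoOut between blocks)
#' plus additive linear age/sex/TIV effects. Defaults emulate a young-adult
#' MRI cohort: 30 subjects per group, 90 regions in six 15-region blocks,
#' rhoIn 0.5, rhoOut 0.1, mean regional volume 8 mL with 0.8 mL residual SD,
#' age ~ N(25, 8) years, sex ~ Bernoulli(0.5), TIV ~ N(1450, 120) mL, and
#' small covariate slopes (age -0.02 mL/yr, sex 0.3 mL, TIV 0.004 mL/mL).
#'
#' @param nSubjectsPerGroup subjects per group (>= 3).
#' @param nRegions number of atlas regions (default 90).
#' @param moduleSizes integer partition of the regions into correlated blocks.
#' @param rhoIn within-block correlation in [0, 1).
#' @param rhoOut between-block correlation in [0, rhoIn].
#' @param mu per-region mean volume (mL), recycled to nRegions.
#' @param betaAge,betaSex,betaTiv per-region covariate slopes, recycled.
#' @param ageMean,ageSd,pMale,tivMean,tivSd covariate sampling distributions.
#' @param groupEffects named list (by group label) of lists with optional
#'   `rhoIn`/`rhoOut` overrides, e.g. `list(PWSD = list(rhoIn = 0.6))`.
#' @param noiseSd per-region residual standard deviation (mL).
#' @param groups group labels (default the study's PWSD / PWoSD / HC).
#' @param regionLabels node labels; AAL90 abbreviations when nRegions is 90.
#' @return A \linkS4class{SyntheticSpec}. Non-positive-semi-definite
#'   correlation requests (rhoOut > rhoIn, rhoIn >= 1, negative rhoOut) are
#'   rejected.
#' @examples
#' syntheticSpec(nSubjectsPerGroup = 10, nRegions = 30,
#'               moduleSizes = rep(10, 3))
#' @export
syntheticSpec <- function(nSubjectsPerGroup = 30L,
                          nRegions = 90L,
                          moduleSizes = NULL,
                          rhoIn = 0.5,
                          rhoOut = 0.1,
                          mu = 8,
                          betaAge = -0.02, betaSex = 0.3, betaTiv = 0.004,
                          ageMean = 25, ageSd = 8,
                          pMale = 0.5,
                          tivMean = 1450, tivSd = 120,
                          groupEffects = list(),
                          noiseSd = 0.8,
                          groups = c("PWSD", "PWoSD", "HC"),
                          regionLabels = NULL) {
  nRegions <- as.integer(nRegions)
  if (is.null(moduleSizes)) {
    nb <- max(1L, nRegions %/% 15L)
    moduleSizes <- rep(nRegions %/% nb, nb)
    moduleSizes[seq_len(nRegions - sum(moduleSizes))] <-
      moduleSizes[seq_len(max(0L, nRegions - sum(moduleSizes)))] + 1L
  }
  if (is.null(regionLabels)) regionLabels <- .defaultRegionLabels(nRegions)
  betas <- cbind(age = rep_len(betaAge, nRegions),
                 sex = rep_len(betaSex, nRegions),
                 tiv = rep_len(betaTiv, nRegions))
  new("SyntheticSpec",
      nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
      nRegions = nRegions,
      moduleSizes = as.integer(moduleSizes),
      rhoIn = rhoIn, rhoOut = rhoOut,
      mu = rep_len(mu, nRegions),
      covariateBetas = betas,
      covariateDistributions = list(ageMean = ageMean, ageSd = ageSd,
                                    pMale = pMale, tivMean = tivMean,
                                    tivSd = tivSd),
      groupEffects = groupEffects,
      noiseSd = noiseSd,
      groups = as.character(groups),
      regionLabels = as.character(regionLabels))
}

# one group's draw: latent block factors give the block-constant correlation,
# covariates enter linearly; all variance of the stochastic part is noiseSd^2
.generateGroup <- function(spec, group, n, seed) {
  .withSeed(seed, {
    p <- spec@nRegions
    eff <- spec@groupEffects[[group]]
    rin <- if (!is.null(eff$rhoIn)) eff$rhoIn else spec@rhoIn
    rout <- if (!is.null(eff$rhoOut)) eff$rhoOut else spec@rhoOut
    block <- rep(seq_along(spec@moduleSizes), spec@moduleSizes)
    cd <- spec@covariateDistributions
    age <- stats::rnorm(n, cd$ageMean, cd$ageSd)
    sex <- stats::rbinom(n, 1, cd$pMale)
    tiv <- stats::rnorm(n, cd$tivMean, cd$tivSd)
    gfac <- stats::rnorm(n)                        # shared global factor
    bfac <- matrix(stats::rnorm(n * length(spec@moduleSizes)), n)
    eps <- matrix(stats::rnorm(n * p), n)
    z <- sqrt(rout) * gfac +
      sqrt(rin - rout) * bfac[, block, drop = FALSE] +
      sqrt(1 - rin) * eps
    X <- cbind(age, sex, tiv)
    values <- matrix(spec@mu, n, p, byrow = TRUE) +
      X %*% t(spec@covariateBetas) + spec@noiseSd * z
    colnames(values) <- spec@regionLabels
    list(values = values,
         covariates = data.frame(age = age, sex = sex, tiv = tiv,
                                 group = group))
  })
}

#' Generate a synthetic cohort
#'
#' Draws every group of `spec` and stacks them into one
#' \linkS4class{GMVCohort}. Each group is generated from its own seed
#' substream derived from `seed`, so adding or reordering groups never
#' changes another group's draw; identical spec and seed reproduce identical
#' tables.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed integer seed for all randomness (NULL uses the current RNG
#'   stream, which then is not reproducible across calls).
#' @return A \linkS4class{GMVCohort} with `nSubjectsPerGroup * length(groups)`
#'   subjects.
#' @examples
#' cohort <- generateCohort(syntheticSpec(nSubjectsPerGroup = 5,
#'                                        nRegions = 10,
#'                                        moduleSizes = c(5, 5)), seed = 1)
#' table(groupLabels(cohort))
#' @export
generateCohort <- function(spec, seed = 1L) {
  validObject(spec)
  n <- spec@nSubjectsPerGroup
  parts <- lapply(seq_along(spec@groups), function(gi) {
    s <- if (is.null(seed)) NULL else .subSeed(seed, gi)
    .generateGroup(spec, spec@groups[gi], n, s)
  })
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  covariates <- do.call(rbind, lapply(parts, `[[`, "covariates"))
  ids <- sprintf("%s_%03d", rep(spec@groups, each = n), rep(seq_len(n), length(spec@groups)))
  rownames(values) <- ids
  rownames(covariates) <- ids
  gmvCohort(values, covariates)
}

#' Generate two groups from the identical distribution
#'
#' A convenience for calibrating the permutation machinery: both groups share
#' every generating parameter (any `groupEffects` of `spec` are dropped), so
#' the between-group null hypothesis holds by construction and only the seed
#' substream differs between subjects.
#'
#' @inheritParams generateCohort
#' @param labels the two group labels.
#' @return A two-group \linkS4class{GMVCohort}.
#' @export
generateNullPair <- function(spec, seed = 1L, labels = c("A", "B")) {
  spec@groups <- as.character(labels)
  spec@groupEffects <- list()
  validObject(spec)
  generateCohort(spec, seed = seed)
}

# normalized truncated power-law pmf on 1..dMax; dc = Inf drops the cutoff
.tplPmf <- function(k, dc, dMax, exponent = 1 / k) {
  d <- seq_len(dMax)
  w <- d^exponent * exp(-d / dc)
  w / sum(w)
}

#' Sample degrees from an exponentially truncated power law
#'
#' Draws i.i.d. degrees from the probability mass function proportional to
#' \eqn{d^{1/k} \exp(-d/d_c)} on the finite support \eqn{d = 1, \dots,
#' d_{max}}, by inverse-CDF lookup (exact, no rejection).
#'
#' @param k power exponent (> 0).
#' @param dc cutoff degree (> 0); `Inf` removes the exponential truncation.
#' @param dMax maximum degree of the support (>= 2), default 50.
#' @param n sample size.
#' @param seed integer seed (NULL = current RNG stream).
#' @return integer vector of `n` degrees in `[1, dMax]`.
#' @examples
#' table(sampleTruncatedPowerlaw(1, Inf, dMax = 3, n = 1000, seed = 1))
#' @export
sampleTruncatedPowerlaw <- function(k, dc, dMax = 50L, n, seed = NULL) {
  .assertScalarNumber(k, "k", lower = 0, strict_lower = TRUE)
  if (!(is.numeric(dc) && length(dc) == 1L && (is.infinite(dc) || dc > 0)))
    stop("'dc' must be a positive number (Inf allowed)")
  if (dMax < 2L) stop("'dMax' must be at least 2")
  if (n < 1L) stop("'n' must be at least 1")
  pmf <- .tplPmf(k, dc, as.integer(dMax))
  cdf <- cumsum(pmf)
  .withSeed(seed, findInterval(stats::runif(n), cdf) + 1L)
}

#' Write a cohort to delimited text
#'
#' Writes the GMV table and the covariate table as CSV files (header row,
#' subject id first column) readable back by \code{\link{loadCohort}}.
#'
#' @param cohort a \linkS4class{GMVCohort}.
#' @param gmvFile,covariatesFile output paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(cohort, gmvFile, covariatesFile) {
  gmv <- data.frame(subject_id = subjectIds(cohort), gmvValues(cohort),
                    check.names = FALSE)
  cov <- data.frame(subject_id = subjectIds(cohort),
                    as.data.frame(SummarizedExperiment::colData(cohort)),
                    check.names = FALSE)
  utils::write.csv(gmv, gmvFile, row.names = FALSE)
  utils::write.csv(cov, covariatesFile, row.names = FALSE)
  invisible(c(gmvFile, covariatesFile))
}
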