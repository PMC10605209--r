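#' Identify degree-based network hubs
#'
#' A region is a hub when its degree summary strictly exceeds the across-
#' region mean by more than 1.5 sample standard deviations (n - 1
#' denominator). With all-equal degrees the SD is zero and nothing exceeds
#' the mean, so the hub set is empty. Shifting every degree by a constant
#' shifts the threshold identically and leaves membership unchanged.
#'
#' @param degreeSummary per-region degree values (e.g. the degree averaged
#'   across the density grid, see \code{\link{hubAnalysis}}).
#' @param labels region labels (default `names(degreeSummary)`).
#' @return A \linkS4class{HubSet}, hubs sorted degree-descending.
#' @examples
#' identifyHubs(c(a = 5, b = 5, c = 5, d = 5, e = 20))   # hub: e
#' @export
identifyHubs <- function(degreeSummary, labels = names(degreeSummary)) {
  if (length(degreeSummary) < 2L) stop("need at least 2 regions")
  if (is.null(labels)) labels <- sprintf("n%02d", seq_along(degreeSummary))
  degreeSummary <- setNames(as.numeric(degreeSummary), labels)
  thr <- mean(degreeSummary) + 1.5 * stats::sd(degreeSummary)
  hubs <- degreeSummary[degreeSummary > thr]
  hubs <- hubs[order(-hubs)]
  new("HubSet", hubRegions = names(hubs), degreeBasis = degreeSummary,
      threshold = thr)
}

#' Hubs of a thresholded network
#'
#' Applies the mean + 1.5 SD rule to the per-region degree averaged across
#' the density grid (the density at which hubs are declared is otherwise
#' arbitrary; a single density can be selected instead).
#'
#' @param graphs list of \linkS4class{BinaryGraph} across the grid.
#' @param density optional single density label (name in `graphs`) to use
#'   instead of the grid average.
#' @return A \linkS4class{HubSet}.
#' @export
hubAnalysis <- function(graphs, density = NULL) {
  if (!is.null(density)) {
    deg <- rowSums(adjacency(graphs[[density]]))
  } else {
    degs <- vapply(graphs, function(g) rowSums(adjacency(g)),
                   numeric(nrow(adjacency(graphs[[1]]))))
    deg <- rowMeans(degs)
  }
  identifyHubs(deg)
}

# profile least squares for the scale: given shape g, best s = <y,g>/<g,g>
.tplSS <- function(par, d, y, form) {
  k <- exp(par[1]); dc <- exp(par[2])
  e <- if (form == "1/k") 1 / k else k - 1
  g <- d^e * exp(-d / dc)
  if (!all(is.finite(g)) || sum(g^2) == 0) return(Inf)
  s <- sum(y * g) / sum(g^2)
  sum((y - s * g)^2)
}

#' Fit an exponentially truncated power law to a degree distribution
#'
#' Nonlinear least squares of \eqn{s \, d^{1/k} \exp(-d/d_c)} against the
#' empirical degree relative-frequency table (or, with `scale = "ccdf"`, the
#' empirical complementary cumulative distribution), with the scale profiled
#' out, multi-start L-BFGS-B over (log k, log dc), and bounded parameters.
#' Degenerate inputs (fewer than 3 distinct degrees) yield a flagged failure
#' rather than an exception.
#'
#' @param degrees sample of positive integer degrees; ignored when `freq` is
#'   given.
#' @param freq optional relative frequencies on support `dSupport` (noise-free
#'   or precomputed input).
#' @param dSupport integer support matching `freq` (default `1:length(freq)`).
#' @param dMax upper end of the fitted support (default the sample maximum).
#' @param scale fit on the `"pmf"` (relative frequency, default — matching
#'   PMF-scale degree histograms) or `"ccdf"` scale.
#' @param exponentForm `"1/k"` (the printed model, default) or `"k-1"` (the
#'   common alternative typesetting of truncated power laws).
#' @return A \linkS4class{DegreeDistributionFit} with `k`, `dc`, `scale`,
#'   `r2` (1 - SS_res/SS_tot on the fitted scale) and a `converged` flag.
#' @examples
#' d <- sampleTruncatedPowerlaw(1.5, 8, dMax = 50, n = 5000, seed = 1)
#' fitTruncatedPowerlaw(d)
#' @export
fitTruncatedPowerlaw <- function(degrees = NULL, freq = NULL, dSupport = NULL,
                                 dMax = NULL,
                                 scale = c("pmf", "ccdf"),
                                 exponentForm = c("1/k", "k-1")) {
  scale <- match.arg(scale)
  form <- match.arg(exponentForm)
  failed <- new("DegreeDistributionFit", k = NA_real_, dc = NA_real_,
                scale = NA_real_, r2 = NA_real_, converged = FALSE,
                support = integer())
  if (is.null(freq)) {
    if (any(degrees < 1)) stop("all degrees must be >= 1")
    if (length(unique(degrees)) < 3L) return(failed)
    if (is.null(dMax)) dMax <- max(degrees)
    d <- seq_len(dMax)
    y <- tabulate(degrees, nbins = dMax) / length(degrees)
  } else {
    d <- if (is.null(dSupport)) seq_along(freq) else as.integer(dSupport)
    y <- freq / sum(freq)
  }
  if (scale == "ccdf") y <- rev(cumsum(rev(y)))
  if (stats::sd(y) == 0) return(failed)
  starts <- expand.grid(k = c(0.3, 0.7, 1, 1.5, 2.5, 4),
                        dc = c(1, 3, 8, 20, 50))
  lower <- log(c(0.02, 0.05))
  upper <- log(c(100, 50 * max(d)))
  best <- NULL; bestOk <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(log(c(starts$k[i], starts$dc[i])), .tplSS, d = d, y = y,
                   form = form, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0 && (is.null(bestOk) || fit$value < bestOk$value))
      bestOk <- fit
  }
  if (is.null(best)) return(failed)
  # L-BFGS-B reports a line-search failure (code 52) when a start sits on the
  # optimum; prefer an equally good cleanly converged start
  if (!is.null(bestOk) && bestOk$value <= best$value + 1e-12) best <- bestOk
  k <- exp(best$par[1]); dc <- exp(best$par[2])
  e <- if (form == "1/k") 1 / k else k - 1
  g <- d^e * exp(-d / dc)
  s <- sum(y * g) / sum(g^2)
  r2 <- 1 - best$value / sum((y - mean(y))^2)
  new("DegreeDistributionFit", k = k, dc = dc, scale = s, r2 = r2,
      converged = best$convergence == 0, support = as.integer(range(d)))
}

#' Log-rank comparison of two degree distributions
#'
#' Treats nodal degrees as uncensored event times and runs the standard
#' two-group log-rank test (chi-square with 1 df) for a difference between
#' the two degree distributions.
#'
#' @param degreesA,degreesB non-empty numeric vectors of degrees.
#' @return list with `statistic` (chi-square) and `p` (upper-tail).
#' @export
logrankDegreeTest <- function(degreesA, degreesB) {
  stopifnot(length(degreesA) >= 1, length(degreesB) >= 1)
  time <- c(degreesA, degreesB)
  grp <- rep(c("A", "B"), c(length(degreesA), length(degreesB)))
  sd_ <- survival::survdiff(survival::Surv(time, rep(1, length(time))) ~ grp)
  stat <- as.numeric(sd_$chisq)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
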