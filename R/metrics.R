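# Graph-theoretical metrics on binary undirected graphs. Cheap metrics
# (clustering, transitivity, degree) are computed by matrix algebra so the
# permutation engine can call them hundreds of thousands of times; path-based
# metrics go through igraph's C shortest-path code.

.graphOf <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

# 2 * triangles at each node
.triangles2 <- function(A) rowSums((A %*% A) * A)

.clusteringFromAdj <- function(A) {
  deg <- rowSums(A)
  t2 <- .triangles2(A)
  cc <- ifelse(deg >= 2, t2 / (deg * (deg - 1)), 0)
  names(cc) <- rownames(A)
  cc
}

.transitivityFromAdj <- function(A) {
  deg <- rowSums(A)
  triples2 <- sum(deg * (deg - 1))
  if (triples2 == 0) return(0)
  sum(.triangles2(A)) / triples2
}

# Lp / Eglob / nodal efficiency / reachable fraction from a distance matrix
.pathStatsFromDist <- function(D) {
  n <- nrow(D)
  off <- row(D) != col(D)
  finite <- off & is.finite(D)
  inv <- 1 / D
  inv[!off | !is.finite(inv)] <- 0
  list(Lp = if (any(finite)) mean(D[finite]) else NA_real_,
       Eglob = if (n > 1) sum(inv) / (n * (n - 1)) else 0,
       nodalEfficiency = if (n > 1) rowSums(inv) / (n - 1) else rep(0, n),
       reachableFraction = if (n > 1) mean(finite[off]) else 0)
}

#' Clustering coefficients and transitivity
#'
#' Nodal clustering is triangles / (deg (deg - 1) / 2), zero for nodes of
#' degree below 2; `Cp` is the mean over all nodes (network segregation) and
#' transitivity `T` is 3 x triangles / connected triples (whole-graph
#' closure).
#'
#' @param g a \linkS4class{BinaryGraph} or 0/1 adjacency matrix.
#' @return list with `nodal` (vector), `Cp`, `T`.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' clusteringMetrics(tri)$Cp   # 1
#' @export
clusteringMetrics <- function(g) {
  A <- adjacency(g)
  nodal <- .clusteringFromAdj(A)
  list(nodal = nodal, Cp = mean(nodal), T = .transitivityFromAdj(A))
}

#' Characteristic path length and efficiency
#'
#' All-pairs shortest-path (BFS) distances give the characteristic path
#' length `Lp` (mean over *reachable* ordered pairs; the unreachable fraction
#' is reported alongside), the global efficiency `Eglob` (mean inverse
#' distance over all ordered pairs, with 1/Inf = 0, so disconnection is
#' handled natively), and each node's efficiency (mean inverse distance to
#' every other node).
#'
#' @inheritParams clusteringMetrics
#' @return list with `Lp`, `Eglob`, `nodalEfficiency`, `reachableFraction`.
#' @export
pathMetrics <- function(g) {
  A <- adjacency(g)
  D <- igraph::distances(.graphOf(A))
  .pathStatsFromDist(D)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors (0 for fewer than 2 neighbors); `Eloc` is the mean over nodes, a
#' fault-tolerance measure.
#'
#' @inheritParams clusteringMetrics
#' @return list with `nodal` (vector) and `Eloc`.
#' @export
localEfficiency <- function(g) {
  A <- adjacency(g)
  n <- nrow(A)
  eff <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) next
    sub <- A[nb, nb, drop = FALSE]
    D <- igraph::distances(.graphOf(sub))
    eff[v] <- .pathStatsFromDist(D)$Eglob
  }
  names(eff) <- rownames(A)
  list(nodal = eff, Eloc = mean(eff))
}

#' Betweenness centrality
#'
#' The fraction of shortest paths between all ordered source-target pairs
#' (excluding the node itself) that pass through each node, normalized by
#' (N-1)(N-2) so values lie in [0, 1].
#'
#' @inheritParams clusteringMetrics
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(g) {
  A <- adjacency(g)
  n <- nrow(A)
  if (n < 3) return(setNames(numeric(n), rownames(A)))
  b <- igraph::betweenness(.graphOf(A), directed = FALSE, normalized = FALSE)
  setNames(2 * as.numeric(b) / ((n - 1) * (n - 2)), rownames(A))
}

#' Nodal metric table
#'
#' @inheritParams clusteringMetrics
#' @return data.frame keyed by region with degree, nodal clustering, nodal
#'   efficiency and betweenness.
#' @export
nodalMetrics <- function(g) {
  A <- adjacency(g)
  data.frame(region = rownames(A),
             degree = rowSums(A),
             clustering = .clusteringFromAdj(A),
             efficiency = pathMetrics(A)$nodalEfficiency,
             betweenness = betweennessCentrality(A),
             row.names = NULL)
}

#' Small-world indices against degree-preserving rewired nulls
#'
#' Generates `nNull` Maslov-Sneppen rewired graphs (double-edge swaps that
#' preserve every node's degree; 10 x |E| rewiring trials each) and computes
#' gamma = Cp / mean null Cp, lambda = Lp / mean null Lp, and the small-world
#' index sigma = gamma / lambda. Degree preservation (rather than
#' Erdos-Renyi nulls) avoids conflating degree-sequence effects with
#' clustering/path normalization. Graphs whose degree sequence admits no
#' rewiring (complete graphs) return 1/1/1 with a warning.
#'
#' @inheritParams clusteringMetrics
#' @param nNull number of rewired null graphs (default 100).
#' @param seed integer seed (NULL = current RNG stream).
#' @param nullGraphs optional list of adjacency matrices to use as the null
#'   ensemble instead of rewiring (testing hook).
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
smallWorld <- function(g, nNull = 100L, seed = NULL, nullGraphs = NULL) {
  A <- adjacency(g)
  n <- nrow(A)
  m <- sum(A) / 2
  if (m < 1) stop("small-world indices need at least one edge")
  if (m == n * (n - 1) / 2) {
    warning("complete graph admits no degree-preserving rewiring; sigma set to 1")
    return(list(gamma = 1, lambda = 1, sigma = 1))
  }
  Cp <- mean(.clusteringFromAdj(A))
  Lp <- pathMetrics(A)$Lp
  if (is.null(nullGraphs)) {
    gr <- .graphOf(A)
    nulls <- .withSeed(seed, lapply(seq_len(nNull), function(b) {
      igraph::rewire(gr, igraph::keeping_degseq(loops = FALSE,
                                                niter = 10 * m))
    }))
    nullCp <- vapply(nulls, function(x)
      igraph::transitivity(x, type = "localaverage", isolates = "zero"),
      numeric(1))
    nullLp <- vapply(nulls, function(x)
      igraph::mean_distance(x, directed = FALSE, unconnected = TRUE),
      numeric(1))
  } else {
    nullCp <- vapply(nullGraphs, function(x) mean(.clusteringFromAdj(adjacency(x))),
                     numeric(1))
    nullLp <- vapply(nullGraphs, function(x) pathMetrics(adjacency(x))$Lp,
                     numeric(1))
  }
  gamma <- Cp / mean(nullCp)
  lambda <- Lp / mean(nullLp)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

# registry of scalar global metrics usable in curves and permutation tests;
# each takes an adjacency matrix and an options list
.globalStatRegistry <- function() {
  list(
    clustering = function(A, opts) mean(.clusteringFromAdj(A)),
    transitivity = function(A, opts) .transitivityFromAdj(A),
    pathLength = function(A, opts) pathMetrics(A)$Lp,
    globalEfficiency = function(A, opts) pathMetrics(A)$Eglob,
    localEfficiency = function(A, opts) localEfficiency(A)$Eloc,
    sigma = function(A, opts) smallWorld(
      A, nNull = if (is.null(opts$nNull)) 100L else opts$nNull,
      seed = opts$seed)$sigma,
    robustness.random = function(A, opts) randomFailure(
      A, nSim = if (is.null(opts$nSim)) 100L else opts$nSim,
      seed = opts$seed)@auc,
    robustness.targeted = function(A, opts) targetedAttack(A)@auc
  )
}

.nodalStatRegistry <- function() {
  list(
    degree = function(A, opts) rowSums(A),
    nodalClustering = function(A, opts) .clusteringFromAdj(A),
    nodalEfficiency = function(A, opts) pathMetrics(A)$nodalEfficiency,
    betweenness = function(A, opts) betweennessCentrality(A)
  )
}

#' Registered network summaries
#'
#' @return character vector of statistic names accepted by
#'   \code{\link{metricCurve}} and \code{\link{permutationTest}}.
#' @export
registeredStatistics <- function() {
  c(names(.globalStatRegistry()), names(.nodalStatRegistry()))
}

#' Evaluate a global metric across the density grid
#'
#' @param graphs list of \linkS4class{BinaryGraph} (or adjacency matrices),
#'   one per density, e.g. from \code{\link{thresholdGrid}}.
#' @param metric a registered global metric name (see
#'   \code{\link{registeredStatistics}}).
#' @param grid the densities the graphs were thresholded at.
#' @param options list of metric options (`nNull`, `nSim`, `seed`).
#' @return A \linkS4class{MetricCurve} with trapezoidal AUC attached.
#' @export
metricCurve <- function(graphs, metric, grid = sparsityGrid(),
                        options = list()) {
  reg <- .globalStatRegistry()
  if (!metric %in% names(reg))
    stop("unknown metric '", metric, "'; see registeredStatistics()")
  if (length(graphs) != length(grid))
    stop("one graph per grid density is required")
  if (length(grid) < 2L)
    stop("AUC is undefined on a single-density grid")
  values <- vapply(graphs, function(g) reg[[metric]](adjacency(g), options),
                   numeric(1))
  new("MetricCurve", grid = as.numeric(grid), values = unname(values),
      metric = metric, auc = aucTrapezoid(grid, values))
}

#' All global metrics of one binary graph
#'
#' @inheritParams clusteringMetrics
#' @inheritParams smallWorld
#' @return named list: Cp, T, Lp, Eglob, Eloc, gamma, lambda, sigma.
#' @export
globalMetrics <- function(g, nNull = 100L, seed = NULL) {
  A <- adjacency(g)
  cl <- clusteringMetrics(A)
  pm <- pathMetrics(A)
  sw <- smallWorld(A, nNull = nNull, seed = seed)
  list(Cp = cl$Cp, T = cl$T, Lp = pm$Lp, Eglob = pm$Eglob,
       Eloc = localEfficiency(A)$Eloc,
       gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
}
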