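# Brute-force oracles, written independently of the package implementation:
# Floyd-Warshall distances, explicit neighbor-pair triangle counting, and
# shortest-path counting by matrix powers. Used to verify every graph metric
# on small graphs.

bfDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

bfClustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) next
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] > 0) links <- links + 1
    }
    cc[v] <- links / (length(nb) * (length(nb) - 1) / 2)
  }
  cc
}

bfTransitivity <- function(A) {
  n <- nrow(A)
  closed <- 0; triples <- 0
  for (v in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b || a == v || b == v) next
    if (A[v, a] > 0 && A[v, b] > 0) {
      triples <- triples + 1
      if (A[a, b] > 0) closed <- closed + 1
    }
  }
  if (triples == 0) 0 else closed / triples
}

bfPathStats <- function(A) {
  D <- bfDistances(A)
  n <- nrow(A)
  off <- row(D) != col(D)
  finite <- off & is.finite(D)
  inv <- ifelse(off & is.finite(D), 1 / D, 0)
  list(Lp = if (any(finite)) mean(D[finite]) else NA_real_,
       Eglob = if (n > 1) sum(inv) / (n * (n - 1)) else 0,
       nodalEfficiency = if (n > 1) rowSums(inv) / (n - 1) else numeric(n))
}

bfLocalEfficiency <- function(A) {
  n <- nrow(A)
  eff <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) next
    eff[v] <- bfPathStats(A[nb, nb, drop = FALSE])$Eglob
  }
  eff
}

# shortest-path counts sigma[s,t] = number of walks of length dist(s,t)
bfBetweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(numeric(n))
  D <- bfDistances(A)
  maxd <- suppressWarnings(max(D[is.finite(D)]))
  pows <- vector("list", max(1, maxd))
  P <- diag(n)
  for (d in seq_len(max(1, maxd))) { P <- P %*% A; pows[[d]] <- P }
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n))
    if (s != t && is.finite(D[s, t])) sig[s, t] <- pows[[D[s, t]]][s, t]
  b <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sig[s, v] * sig[v, t] / sig[s, t]
    }
    b[v] <- tot / ((n - 1) * (n - 2))
  }
  b
}

bfLargestComponent <- function(A) {
  if (nrow(A) == 0) return(0L)
  D <- bfDistances(A)
  max(table(apply(is.finite(D), 1, function(r) min(which(r)))))
}

# --- small named graphs used across tests ---

adjFromEdges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  labs <- sprintf("n%02d", seq_len(n))
  dimnames(A) <- list(labs, labs)
  A
}

starAdj <- function(n) adjFromEdges(n, lapply(2:n, function(i) c(1, i)))
completeAdj <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  labs <- sprintf("n%02d", seq_len(n)); dimnames(A) <- list(labs, labs); A
}
pathAdj <- function(n) adjFromEdges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
# 4-cycle 1-2-3-4 plus the 1-3 diagonal
cycleDiagAdj <- function() adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3)))
ringLatticeAdj <- function(n, k) {
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(k / 2)) {
    edges[[length(edges) + 1L]] <- c(i, (i + j - 1) %% n + 1)
  }
  adjFromEdges(n, edges)
}

randomConnectedAdj <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    A[ut] <- rbinom(length(ut), 1, p)
    A <- A + t(A)
    if (all(is.finite(bfDistances(A)))) {
      labs <- sprintf("n%02d", seq_len(n)); dimnames(A) <- list(labs, labs)
      return(A)
    }
  }
}

atlasAdj <- function(i) {
  g <- igraph::graph_from_atlas(i)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  if (nrow(A) > 0) {
    labs <- sprintf("n%02d", seq_len(nrow(A)))
    dimnames(A) <- list(labs, labs)
  }
  A
}

# a small residualized null cohort for inference tests
makeNullResiduals <- function(nPerGroup, nRegions, seed) {
  spec <- syntheticSpec(nSubjectsPerGroup = nPerGroup, nRegions = nRegions)
  co <- residualize(generateNullPair(spec, seed = seed))
  res <- residValues(co)
  gl <- groupLabels(co)
  list(a = res[gl == "A", , drop = FALSE], b = res[gl == "B", , drop = FALSE])
}
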