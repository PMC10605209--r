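# Node-removal robustness: largest-connected-component decay under random
# failure and degree-targeted attack. LCC sequences for a fixed removal order
# are computed by the reverse (addition-order) percolation trick with a
# union-find, so each simulated order costs O(N + E) instead of N component
# searches.

#' Largest connected component size
#'
#' @param g a \linkS4class{BinaryGraph} or adjacency matrix.
#' @return integer node count of the largest component (0 for an empty node
#'   set; an isolated node counts as a component of size 1).
#' @export
largestComponentSize <- function(g) {
  A <- adjacency(g)
  if (nrow(A) == 0) return(0L)
  as.integer(max(igraph::components(.graphOf(A))$csize))
}

# LCC size after m removals (m = 0..N-1) for one removal order, via
# union-find over the reversed (addition) order
.lccSequence <- function(nbr, n, removalOrder) {
  parent <- integer(n)
  size <- integer(n)
  active <- logical(n)
  lccAfterAdd <- integer(n)
  maxsize <- 0L
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  add_order <- rev(removalOrder)
  for (t in seq_len(n)) {
    v <- add_order[t]
    parent[v] <- v
    size[v] <- 1L
    active[v] <- TRUE
    if (size[v] > maxsize) maxsize <- size[v]
    for (w in nbr[[v]]) {
      if (!active[w]) next
      rv <- find(v); rw <- find(w)
      if (rv != rw) {
        if (size[rv] < size[rw]) { tmp <- rv; rv <- rw; rw <- tmp }
        parent[rw] <- rv
        size[rv] <- size[rv] + size[rw]
        if (size[rv] > maxsize) maxsize <- size[rv]
      }
    }
    lccAfterAdd[t] <- maxsize
  }
  # m removals leave n - m nodes added
  lccAfterAdd[n:1][seq_len(n)]
}

.neighborList <- function(A) apply(A > 0, 1, which, simplify = FALSE)

.robustnessCurve <- function(lcc, n, attackType, nSim) {
  fr <- (seq_len(n) - 1) / n
  new("RobustnessCurve", fractionsRemoved = fr,
      lccRelativeSize = lcc / n, attackType = attackType,
      nSim = as.integer(nSim), auc = aucTrapezoid(fr, lcc / n))
}

#' Random-failure robustness
#'
#' Simulates `nSim` uniformly random node-removal orders; after each single
#' removal the largest connected component is recorded, and the curves
#' (relative to the original N) are averaged over simulations.
#'
#' @inheritParams largestComponentSize
#' @param nSim number of simulated removal orders (default 1000).
#' @param seed integer seed (NULL = current RNG stream).
#' @return A \linkS4class{RobustnessCurve} with trapezoidal AUC.
#' @export
randomFailure <- function(g, nSim = 1000L, seed = NULL) {
  stopifnot(nSim >= 1)
  A <- adjacency(g)
  n <- nrow(A)
  nbr <- .neighborList(A)
  .withSeed(seed, {
    acc <- numeric(n)
    for (b in seq_len(nSim))
      acc <- acc + .lccSequence(nbr, n, sample.int(n))
    .robustnessCurve(acc / nSim, n, "random", nSim)
  })
}

#' Degree-targeted attack
#'
#' A single deterministic pass: at each step the remaining node with the
#' highest *current* degree is removed (degrees recomputed after every
#' removal — the adaptive percolation protocol; `adaptive = FALSE` ranks by
#' the original degrees once). Ties are broken by region-label (node index)
#' order.
#'
#' @inheritParams largestComponentSize
#' @param adaptive recompute degrees after each removal (default TRUE).
#' @return A \linkS4class{RobustnessCurve}.
#' @export
targetedAttack <- function(g, adaptive = TRUE) {
  A <- adjacency(g)
  n <- nrow(A)
  if (adaptive) {
    W <- A
    alive <- rep(TRUE, n)
    order_removed <- integer(n)
    deg <- rowSums(W)
    for (m in seq_len(n)) {
      cand <- which(alive)
      v <- cand[which.max(deg[cand])]    # which.max takes the first = lowest index on ties
      order_removed[m] <- v
      alive[v] <- FALSE
      nbv <- which(W[v, ] > 0)
      deg[nbv] <- deg[nbv] - 1
      W[v, ] <- 0; W[, v] <- 0
    }
  } else {
    deg <- rowSums(A)
    order_removed <- order(-deg, seq_len(n))
  }
  lcc <- .lccSequence(.neighborList(A), n, order_removed)
  .robustnessCurve(lcc, n, "targeted", 1L)
}

#' Trapezoidal AUC of a robustness curve
#'
#' @param curve a \linkS4class{RobustnessCurve}.
#' @return numeric area of LCC relative size over fraction removed.
#' @export
robustnessAUC <- function(curve) {
  aucTrapezoid(curve@fractionsRemoved, curve@lccRelativeSize)
}
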