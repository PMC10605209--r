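test_that("clustering and transitivity match hand counts on small graphs", {
  tri <- completeAdj(3)
  expect_equal(clusteringMetrics(tri)$Cp, 1)
  expect_equal(clusteringMetrics(tri)$T, 1)
  st <- starAdj(5)
  expect_equal(clusteringMetrics(st)$Cp, 0)
  expect_equal(clusteringMetrics(st)$T, 0)
  cd <- cycleDiagAdj()   # 4-cycle plus diagonal 1-3
  cm <- clusteringMetrics(cd)
  expect_equal(unname(cm$nodal), c(2 / 3, 1, 2 / 3, 1), tolerance = 1e-12)
  expect_equal(cm$Cp, 5 / 6, tolerance = 1e-12)
  expect_equal(cm$T, 0.75, tolerance = 1e-12)
})

test_that("path length and efficiencies match enumeration on small graphs", {
  k5 <- completeAdj(5)
  pm <- pathMetrics(k5)
  expect_equal(pm$Lp, 1)
  expect_equal(pm$Eglob, 1)
  p3 <- pathAdj(3)
  pm3 <- pathMetrics(p3)
  expect_equal(pm3$Lp, 4 / 3, tolerance = 1e-12)
  expect_equal(pm3$Eglob, 5 / 6, tolerance = 1e-12)
  empty <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  pme <- pathMetrics(empty)
  expect_equal(pme$Eglob, 0)
  expect_true(is.na(pme$Lp))
  expect_equal(pme$reachableFraction, 0)

  expect_equal(localEfficiency(completeAdj(3))$Eloc, 1)
  expect_equal(localEfficiency(starAdj(5))$Eloc, 0)
  le <- localEfficiency(cycleDiagAdj())
  expect_equal(unname(le$nodal), c(5 / 6, 1, 5 / 6, 1), tolerance = 1e-12)
  expect_equal(le$Eloc, 11 / 12, tolerance = 1e-12)
})

test_that("betweenness is the normalized shortest-path fraction", {
  expect_equal(unname(betweennessCentrality(pathAdj(3))), c(0, 1, 0))
  expect_equal(unname(betweennessCentrality(completeAdj(6))), rep(0, 6))
  expect_equal(unname(betweennessCentrality(starAdj(5)))[1], 1)
})

test_that("all metrics equal brute-force oracles on random graphs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    A <- randomConnectedAdj(n, p = runif(1, 0.3, 0.7))
    cm <- clusteringMetrics(A)
    expect_equal(unname(cm$nodal), bfClustering(A), tolerance = 1e-12)
    expect_equal(cm$T, bfTransitivity(A), tolerance = 1e-12)
    pm <- pathMetrics(A)
    bf <- bfPathStats(A)
    expect_equal(pm$Lp, bf$Lp, tolerance = 1e-12)
    expect_equal(pm$Eglob, bf$Eglob, tolerance = 1e-12)
    expect_equal(unname(pm$nodalEfficiency), bf$nodalEfficiency,
                 tolerance = 1e-12)
    expect_equal(unname(localEfficiency(A)$nodal), bfLocalEfficiency(A),
                 tolerance = 1e-12)
    expect_equal(unname(betweennessCentrality(A)), bfBetweenness(A),
                 tolerance = 1e-12)
    expect_identical(largestComponentSize(A), as.integer(bfLargestComponent(A)))
  }
})

test_that("nodal metric bookkeeping holds", {
  set.seed(7)
  A <- randomConnectedAdj(7, 0.5)
  nm <- nodalMetrics(A)
  expect_equal(sum(nm$degree), 2 * sum(A) / 2)
  expect_equal(unname(betweennessCentrality(completeAdj(5))), rep(0, 5))
})

test_that("small-world indices behave as designed", {
  # identity null: a graph against itself gives gamma = lambda = sigma = 1
  set.seed(3)
  A <- randomConnectedAdj(10, 0.4)
  sw <- smallWorld(A, nullGraphs = list(A, A, A))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)

  # complete graphs admit no rewiring
  expect_warning(swc <- smallWorld(completeAdj(6)), "complete")
  expect_equal(swc$sigma, 1)

  # ring lattice, 60 nodes, 4 nearest neighbors: strongly clustered, so
  # gamma > 2 and sigma > 1 against degree-preserving rewired nulls
  rl <- ringLatticeAdj(60, 4)
  swl <- smallWorld(rl, nNull = 50, seed = 1)
  expect_gt(swl$gamma, 2)
  expect_gt(swl$sigma, 1)
})

test_that("the null ensemble is stable across seeds", {
  co <- residualize(generateCohort(syntheticSpec(nSubjectsPerGroup = 30),
                                   seed = 7))
  g <- thresholdBySparsity(correlationNetwork(co, "PWSD"), 0.19)
  s1 <- smallWorld(g, nNull = 100, seed = 1)$sigma
  s2 <- smallWorld(g, nNull = 100, seed = 2)$sigma
  expect_lt(abs(s1 - s2) / s1, 0.05)
})

test_that("metric curves carry trapezoidal AUCs over the grid", {
  grid <- sparsityGrid()
  # constant metric value c across the grid integrates to 0.30 * c
  set.seed(9)
  A <- randomConnectedAdj(8, 0.5)
  graphs <- rep(list(A), length(grid))
  mc <- metricCurve(graphs, "clustering", grid)
  cval <- clusteringMetrics(A)$Cp
  expect_equal(curveValues(mc), rep(cval, 16))
  expect_equal(curveAUC(mc), 0.30 * cval, tolerance = 1e-12)
  # linear curve from a to b: trapezoid closed form 0.30 * (a + b) / 2
  a <- 0.2; b <- 0.8
  lin <- seq(a, b, length.out = length(grid))
  expect_equal(aucTrapezoid(grid, lin), 0.30 * (a + b) / 2, tolerance = 1e-12)
  expect_error(metricCurve(graphs[1], "clustering", grid[1]), "single-density")
  expect_error(metricCurve(graphs, "notAMetric", grid), "unknown metric")
})

test_that("Eglob is non-decreasing along the nested threshold sequence and
           Cp/T/Eloc are near-monotone on the default synthetic SCN", {
  co <- residualize(generateCohort(syntheticSpec(nSubjectsPerGroup = 30),
                                   seed = 7))
  graphs <- thresholdGrid(correlationNetwork(co, "PWSD"))
  eg <- vapply(graphs, function(g) pathMetrics(g)$Eglob, numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
  for (m in c("clustering", "transitivity", "localEfficiency")) {
    v <- curveValues(metricCurve(graphs, m))
    expect_gt(min(diff(v)), -0.05)   # small dips only; not strictly monotone
  }
})
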