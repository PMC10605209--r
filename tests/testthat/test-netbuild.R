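test_that("the sparsity grid is 0.19..0.49 step 0.02, 16 exact values", {
  g <- sparsityGrid()
  expect_length(g, 16L)
  expect_identical(g[1], 0.19)
  expect_identical(g[16], 0.49)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(g), rep(0.02, 15))
})

test_that("residualization reproduces hand-computed OLS", {
  # 1 region, volumes on ages: slope 105/500 = 0.21
  gmv <- matrix(c(10, 12, 15, 16), 4, 1,
                dimnames = list(paste0("s", 1:4), "r1"))
  cov <- data.frame(age = c(20, 30, 40, 50), sex = c(0, 1, 0, 1),
                    tiv = rep(1400, 4), group = "G",
                    row.names = rownames(gmv))
  co <- gmvCohort(gmv, cov)
  res <- residValues(suppressWarnings(residualize(co, covariates = "age")))
  expect_equal(unname(res[, 1]), c(-0.10, -0.20, 0.70, -0.40), tolerance = 1e-12)

  # all covariates constant -> column-centered volumes (intercept-only fit)
  cov2 <- cov; cov2$age <- 30; cov2$sex <- 1; cov2$tiv <- 1400
  co2 <- gmvCohort(gmv, cov2)
  expect_warning(r2 <- residValues(residualize(co2)), "constant covariate")
  expect_equal(unname(r2[, 1]), c(10, 12, 15, 16) - 13.25, tolerance = 1e-12)

  # a region exactly linear in age has all-zero residuals
  gmv3 <- cbind(gmv, r2 = 5 + 0.3 * cov$age)
  co3 <- gmvCohort(gmv3, cov)
  r3 <- residValues(suppressWarnings(residualize(co3, covariates = "age")))
  expect_equal(unname(r3[, "r2"]), rep(0, 4), tolerance = 1e-10)
})

test_that("residuals are centered and orthogonal to the covariates", {
  co <- generateCohort(syntheticSpec(nSubjectsPerGroup = 25, nRegions = 12,
                                     moduleSizes = c(6, 6)), seed = 3)
  co <- residualize(co)
  res <- residValues(co)
  expect_lt(max(abs(colSums(res))), 1e-9)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  for (v in c("age", "sex", "tiv"))
    expect_lt(max(abs(crossprod(res, cd[[v]] - mean(cd[[v]])))), 1e-8)
})

test_that("sex coding cannot affect residuals (OLS affine invariance)", {
  co <- generateCohort(syntheticSpec(nSubjectsPerGroup = 15, nRegions = 10,
                                     moduleSizes = c(5, 5)), seed = 13)
  flipped <- co
  SummarizedExperiment::colData(flipped)$sex <-
    1 - SummarizedExperiment::colData(co)$sex
  expect_equal(residValues(residualize(co)), residValues(residualize(flipped)),
               tolerance = 1e-10)
})

test_that("correlation networks match hand-computed Pearson r", {
  m <- cbind(a = c(1, 2, 4), b = c(1, 3, 3), d = c(1, 2, 4),
             x = c(1, 2, 3), y = c(3, 2, 1))
  net <- correlationNetwork(m)
  w <- networkWeights(net)
  expect_equal(w["a", "b"], 24 / sqrt(1008), tolerance = 1e-12)
  expect_equal(w["a", "d"], 1)           # identical columns
  expect_equal(w["x", "y"], -1)          # perfect anticorrelation
  expect_equal(diag(w), setNames(rep(0, 5), colnames(m)))
  expect_identical(w, t(w))
  expect_error(correlationNetwork(m[1:2, ]), "at least 3")
  expect_warning(correlationNetwork(cbind(m, e = c(1, 1, 1))), "zero-variance")
})

test_that("correlations are invariant to affine rescaling of a column", {
  set.seed(1)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, letters[1:6]))
  m2 <- m
  m2[, 3] <- 5 - 2.7 * m[, 3]
  w1 <- networkWeights(correlationNetwork(m))
  w2 <- networkWeights(correlationNetwork(m2))
  w2[3, ] <- -w2[3, ]; w2[, 3] <- -w2[, 3]; diag(w2) <- 0
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("thresholding keeps exactly round(s * N(N-1)/2) top edges", {
  co <- residualize(generateCohort(syntheticSpec(nSubjectsPerGroup = 10),
                                   seed = 2))
  net <- correlationNetwork(co, "HC")
  g <- thresholdBySparsity(net, 0.19)
  expect_identical(edgeCount(g), 761L)        # round(0.19 * 4005)
  expect_identical(dim(adjacency(g)), c(90L, 90L))
  gFull <- thresholdBySparsity(net, 1)
  expect_identical(edgeCount(gFull), 4005L)   # complete graph

  # 4-node network with distinct weights at sparsity 0.5: top 3 of 6 edges
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w[upper.tri(w)] <- c(0.9, 0.1, 0.7, -0.3, 0.5, 0.2)
  w <- w + t(w)
  net4 <- new("CovarianceNetwork", weights = w, groupLabel = "x",
              nSubjects = 5L)
  g4 <- thresholdBySparsity(net4, 0.5)
  expect_identical(edgeCount(g4), 3L)
  a <- adjacency(g4)
  expect_equal(a["a", "b"], 1)  # 0.9
  expect_equal(a["b", "c"], 1)  # 0.7
  expect_equal(a["b", "d"], 1)  # 0.5
  expect_equal(sum(a), 6)
  expect_error(thresholdBySparsity(net4, 0), "sparsity")
  expect_error(thresholdBySparsity(net4, 1.2), "sparsity")
})

test_that("edge sets are nested across increasing sparsity", {
  co <- residualize(generateCohort(syntheticSpec(nSubjectsPerGroup = 12),
                                   seed = 5))
  net <- correlationNetwork(co, "PWSD")
  graphs <- thresholdGrid(net)
  for (i in seq_len(length(graphs) - 1)) {
    a1 <- adjacency(graphs[[i]]); a2 <- adjacency(graphs[[i + 1]])
    expect_true(all(a2[a1 == 1] == 1))
  }
  # absolute ranking can pick strong negative correlations
  gAbs <- thresholdBySparsity(net, 0.19, ranking = "absolute")
  expect_identical(edgeCount(gAbs), 761L)
})

test_that("adjacency round-trips through TSV and .edge formats", {
  co <- residualize(generateCohort(syntheticSpec(nSubjectsPerGroup = 10,
                                                 nRegions = 8,
                                                 moduleSizes = c(4, 4)),
                                   seed = 6))
  g <- thresholdBySparsity(correlationNetwork(co, "PWSD"), 0.4)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".edge")
  writeAdjacency(g, f1, "tsv")
  writeAdjacency(g, f2, "edge")
  back1 <- as.matrix(read.delim(f1, row.names = 1, check.names = FALSE))
  back2 <- as.matrix(read.delim(f2, header = FALSE))
  expect_equal(unname(back1), unname(adjacency(g)))
  expect_equal(unname(back2), unname(adjacency(g)))
})
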