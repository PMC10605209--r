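test_that("generated cohorts have the right shape and are seed-deterministic", {
  spec <- syntheticSpec(nSubjectsPerGroup = 30)
  co1 <- generateCohort(spec, seed = 11)
  co2 <- generateCohort(spec, seed = 11)
  expect_equal(dim(gmvValues(co1)), c(90L, 90L))
  expect_equal(unname(table(groupLabels(co1))), array(rep(30L, 3)),
               ignore_attr = TRUE)
  expect_identical(gmvValues(co1), gmvValues(co2))
  expect_identical(
    as.data.frame(SummarizedExperiment::colData(co1)),
    as.data.frame(SummarizedExperiment::colData(co2)))
  co3 <- generateCohort(spec, seed = 12)
  expect_false(identical(gmvValues(co1), gmvValues(co3)))
})

test_that("invalid generating specs are rejected", {
  expect_error(syntheticSpec(nSubjectsPerGroup = 2), "3 subjects")
  expect_error(syntheticSpec(rhoIn = 0.3, rhoOut = 0.5), "positive semi-definite")
  expect_error(syntheticSpec(rhoIn = 1.0), "positive semi-definite")
  expect_error(syntheticSpec(rhoOut = -0.1), "positive semi-definite")
  expect_error(syntheticSpec(nRegions = 30, moduleSizes = c(10, 10)), "partition")
  expect_error(
    syntheticSpec(groupEffects = list(PWSD = list(rhoIn = 0.05))),
    "positive semi-definite")  # rhoOut default 0.1 > per-group rhoIn
})

test_that("empirical block correlations match the generating values", {
  # one large group, no covariate effects: within-block r ~ 0.5, between ~ 0.1
  spec <- syntheticSpec(nSubjectsPerGroup = 2000, nRegions = 30,
                        moduleSizes = c(15, 15), betaAge = 0, betaSex = 0,
                        betaTiv = 0, groups = "G")
  co <- generateCohort(spec, seed = 5)
  r <- cor(gmvValues(co))
  block <- rep(1:2, each = 15)
  same <- outer(block, block, "==") & upper.tri(r)
  diff_ <- outer(block, block, "!=") & upper.tri(r)
  expect_lt(abs(mean(r[same]) - 0.5), 0.03)
  expect_lt(abs(mean(r[diff_]) - 0.1), 0.03)
})

test_that("block structure survives the network build with a clear margin", {
  spec <- syntheticSpec(nSubjectsPerGroup = 100, groups = "G")
  co <- residualize(generateCohort(spec, seed = 21))
  r <- networkWeights(correlationNetwork(co, "G"))
  block <- rep(1:6, each = 15)
  same <- outer(block, block, "==") & upper.tri(r)
  diff_ <- outer(block, block, "!=") & upper.tri(r)
  expect_gt(mean(abs(r[same])) - mean(abs(r[diff_])), 0.1)
})

test_that("covariate effects are removable by residualization", {
  spec <- syntheticSpec(nSubjectsPerGroup = 500, nRegions = 30,
                        moduleSizes = c(15, 15), groups = "G",
                        betaAge = -0.05, betaSex = 0.5, betaTiv = 0.01)
  co <- residualize(generateCohort(spec, seed = 31))
  res <- residValues(co)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  for (v in c("age", "sex", "tiv")) {
    cors <- abs(cor(res, cd[[v]]))
    expect_lt(max(cors), 0.05)
  }
})

test_that("truncated power-law sampling follows the exact PMF", {
  # k = 1, dc = Inf on {1,2,3}: PMF proportional to d -> (1/6, 2/6, 3/6)
  d <- sampleTruncatedPowerlaw(1, Inf, dMax = 3, n = 1e5, seed = 2)
  freq <- tabulate(d, 3) / length(d)
  expect_equal(freq, c(1, 2, 3) / 6, tolerance = 0.02)
  expect_true(all(d >= 1 & d <= 3))

  # sample mean matches the model mean by direct PMF summation (printed
  # PWSD-style parameters)
  k <- 1.1687; dc <- 10.4879
  pmf <- (1:50)^(1 / k) * exp(-(1:50) / dc)
  pmf <- pmf / sum(pmf)
  modelMean <- sum((1:50) * pmf)
  s <- sampleTruncatedPowerlaw(k, dc, dMax = 50, n = 1e5, seed = 3)
  expect_lt(abs(mean(s) - modelMean) / modelMean, 0.02)
  expect_true(all(s >= 1 & s <= 50))

  expect_error(sampleTruncatedPowerlaw(-1, 5, 50, 10), "k")
  expect_error(sampleTruncatedPowerlaw(1, -5, 50, 10), "dc")
  expect_identical(sampleTruncatedPowerlaw(1.5, 8, 50, 100, seed = 9),
                   sampleTruncatedPowerlaw(1.5, 8, 50, 100, seed = 9))
})

test_that("null pairs share the generating law and reproduce under a seed", {
  spec <- syntheticSpec(nSubjectsPerGroup = 20, nRegions = 30,
                        groupEffects = list(PWSD = list(rhoIn = 0.6)))
  co1 <- generateNullPair(spec, seed = 4)
  co2 <- generateNullPair(spec, seed = 4)
  expect_identical(gmvValues(co1), gmvValues(co2))
  expect_setequal(unique(groupLabels(co1)), c("A", "B"))
  # group effects are dropped: both groups come from the identical law, so
  # with a large n their correlation structures agree closely
  big <- syntheticSpec(nSubjectsPerGroup = 1500, nRegions = 20,
                       moduleSizes = c(10, 10),
                       groupEffects = list(A = list(rhoIn = 0.9)))
  coBig <- generateNullPair(big, seed = 6)
  gl <- groupLabels(coBig)
  rA <- cor(gmvValues(coBig)[gl == "A", ])
  rB <- cor(gmvValues(coBig)[gl == "B", ])
  expect_lt(max(abs(rA - rB)), 0.12)   # sampling noise only
})

test_that("cohorts round-trip through CSV", {
  spec <- syntheticSpec(nSubjectsPerGroup = 5, nRegions = 8,
                        moduleSizes = c(4, 4))
  co <- generateCohort(spec, seed = 8)
  gfile <- tempfile(fileext = ".csv"); cfile <- tempfile(fileext = ".csv")
  writeCohort(co, gfile, cfile)
  back <- loadCohort(pipelineConfig(gmvCsv = gfile, covariatesCsv = cfile))
  expect_equal(gmvValues(back), gmvValues(co), tolerance = 1e-12)
  expect_identical(groupLabels(back), groupLabels(co))
})
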