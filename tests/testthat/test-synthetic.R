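test_that("library generation is seeded, distinct and standardization-stable", {
  lib <- genMoleculeLibrary(10, seed = 1)
  expect_equal(nMolecules(lib), 10L)
  smis <- vapply(lib@records, function(r) r@smiles, character(1))
  expect_equal(anyDuplicated(smis), 0L)
  lib2 <- genMoleculeLibrary(10, seed = 1)
  expect_identical(smis, vapply(lib2@records, function(r) r@smiles,
                                character(1)))
  lib3 <- genMoleculeLibrary(10, seed = 2)
  expect_false(identical(smis, vapply(lib3@records, function(r) r@smiles,
                                      character(1))))
  # every generated molecule survives standardization unchanged
  for (r in lib@records) {
    expect_equal(standardizeMolecule(r)@smiles, r@smiles)
  }
})

test_that("planted labels carry the declared linear signal", {
  lib <- smallLibrary()
  act0 <- plantActivityLabels(lib, sigma = 0, seed = 1)
  z <- attr(act0, "descriptors")
  ols <- lm(act0$pic50 ~ ., data = z)
  # a perfect fit makes summary() warn about unreliable inference; only
  # the R-squared itself matters here
  expect_gt(suppressWarnings(summary(ols)$r.squared), 1 - 1e-9)
  act <- plantActivityLabels(lib, sigma = 0.2, seed = 1)
  actB <- plantActivityLabels(lib, sigma = 0.2, seed = 1)
  expect_identical(act$pic50, actB$pic50)
  # labels differ from the pure signal by the injected noise only
  noiseSd <- sd(act$pic50 - act0$pic50)
  expect_gt(noiseSd, 0.1); expect_lt(noiseSd, 0.3)
})

test_that("score tables hit requested marginals and rank correlations", {
  tab <- genScoreTable(10000, list(score = list(dist = "normal", mean = -8,
                                                sd = 1)), seed = 3)
  expect_equal(mean(tab$score), -8, tolerance = 0.05)
  expect_equal(sd(tab$score), 1, tolerance = 0.05)

  tab2 <- genScoreTable(10000, list(
    a = list(dist = "normal", mean = 0, sd = 1),
    b = list(dist = "normal", mean = -5, sd = 2)), seed = 4, spearman = 0.8)
  expect_equal(cor(tab2$a, tab2$b, method = "spearman"), 0.8,
               tolerance = 0.05)
  tab2B <- genScoreTable(10000, list(
    a = list(dist = "normal", mean = 0, sd = 1),
    b = list(dist = "normal", mean = -5, sd = 2)), seed = 4, spearman = 0.8)
  expect_identical(tab2, tab2B)
})

test_that("trajectory generation realizes schedules and spec constraints", {
  ts <- genTrajectorySet(nFrames = 20, nReplicates = 3, seed = 5)
  expect_s4_class(ts, "TrajectorySet")
  expect_equal(length(ts@replicates), 3L)
  expect_equal(dim(ts@replicates[[1]])[1], 20L)
  # byte-identical reproducibility
  ts2 <- genTrajectorySet(nFrames = 20, nReplicates = 3, seed = 5)
  expect_identical(ts@replicates, ts2@replicates)
  # stable with zero jitter: frozen at the reference
  tsf <- genTrajectorySet(nFrames = 5, nReplicates = 1, jitterSigma = 0,
                          seed = 1)
  expect_equal(poseScore(tsf), 0)
  expect_error(genTrajectorySet(occupancy = 1.5), "occupanc")
})

test_that("generated fixtures satisfy downstream preconditions end to end", {
  lib <- genMoleculeLibrary(12, seed = 9)
  act <- plantActivityLabels(lib, sigma = 0.1, seed = 9)
  graphs <- lapply(lib@records, buildGraph)
  expect_equal(length(graphs), nrow(act))
  tcfg <- methods::new("TrainConfig", seed = 1L, epochs = 2L, batchSize = 6L)
  fit <- trainModel(graphs, setNames(act$pic50, act$id), tcfg = tcfg)
  expect_s4_class(fit$model, "GNNModel")
  ts <- genTrajectorySet(nFrames = 25, nReplicates = 2, seed = 9,
                         occupancy = 0.5)
  res <- poseStability(ts)
  expect_s4_class(res, "PoseStabilityResult")
  expect_gte(res@persScore, 0); expect_lte(res@persScore, 1)
})
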