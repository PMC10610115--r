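test_that("8:1:1 split uses floor allocation with remainder to train", {
  sp <- splitDataset(as.character(1:10), seed = 1)
  expect_equal(c(length(sp@trainIds), length(sp@valIds), length(sp@testIds)),
               c(8L, 1L, 1L))
  sp2 <- splitDataset(sprintf("m%04d", 1:1072), seed = 5)
  expect_equal(c(length(sp2@trainIds), length(sp2@valIds),
                 length(sp2@testIds)), c(858L, 107L, 107L))
  expect_error(splitDataset(as.character(1:9)), "at least 10")
})

test_that("splits are deterministic, seed-sensitive and disjoint for many n", {
  for (n in c(10, 37, 100, 1000)) {
    ids <- sprintf("x%04d", seq_len(n))
    a <- splitDataset(ids, seed = 7)
    b <- splitDataset(ids, seed = 7)
    expect_identical(a@trainIds, b@trainIds)
    expect_identical(a@testIds, b@testIds)
    all3 <- c(a@trainIds, a@valIds, a@testIds)
    expect_setequal(all3, ids)
    expect_equal(anyDuplicated(all3), 0L)
  }
  a <- splitDataset(sprintf("x%04d", 1:1000), seed = 1)
  b <- splitDataset(sprintf("x%04d", 1:1000), seed = 2)
  expect_false(identical(sort(a@testIds), sort(b@testIds)))
})

test_that("rSquared matches hand arithmetic and a brute-force formula", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rSquared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SS_res 1 / SS_tot 2
  brute <- function(y, yhat) {
    num <- 0; den <- 0; m <- sum(y) / length(y)
    for (i in seq_along(y)) {
      num <- num + (y[i] - yhat[i])^2
      den <- den + (y[i] - m)^2
    }
    1 - num / den
  }
  set.seed(42)
  for (rep in 1:20) {
    y <- rnorm(50); yhat <- y + rnorm(50, 0, 0.5)
    expect_equal(rSquared(y, yhat), brute(y, yhat), tolerance = 1e-12)
  }
  expect_error(rSquared(rep(1, 5), rnorm(5)), "variance")
})

test_that("the regressor memorizes a tiny dataset without early stopping", {
  # molecules distinct by molecular weight: a permutation-invariant model
  # cannot memorize label differences between (near-)isomorphic graphs,
  # so the memorization check uses structurally separated molecules
  lib <- smallLibrary()
  desc <- descriptorTable(lib)
  keep <- which(!duplicated(round(desc$mw, 1)))[1:20]
  graphs <- smallGraphs()[keep]
  labels <- setNames(smallActivity()$pic50[keep], molIds(lib)[keep])
  tcfg <- methods::new("TrainConfig", seed = 3L, epochs = 2000L,
                       learningRate = 5e-3, batchSize = 20L,
                       earlyStopPatience = 0L)
  mcfg <- methods::new("ModelConfig", nGatLayers = 2L, attentionHeads = 2L,
                       hiddenDim = 32L, mlpDims = c(32L), dropout = 0,
                       readout = "mean")
  fit <- trainModel(graphs, labels, mcfg, tcfg)
  expect_gte(fit$report@r2Train, 0.99)
  # identical seeds give identical reports (full CPU determinism)
  fitB <- trainModel(graphs, labels, mcfg, tcfg)
  expect_identical(fit$report@r2Train, fitB$report@r2Train)
  expect_identical(fit$report@lossCurve, fitB$report@lossCurve)
  # convergence on the training set: predictions near labels
  pred <- predictActivity(fit$model, graphs)
  trainIds <- fit$model@split@trainIds
  expect_lt(median(abs(pred[trainIds] - labels[trainIds])), 0.2)
})

test_that("training rejects degenerate labels and predictions are well-formed", {
  graphs <- smallGraphs()[1:12]
  ids <- vapply(graphs, function(g) g@molId, character(1))
  expect_error(trainModel(graphs, setNames(rep(1, 12), ids)), "variance")
  expect_error(trainModel(graphs, setNames(c(NA, rnorm(11)), ids)), "finite")

  labels <- setNames(rnorm(12), ids)
  tcfg <- methods::new("TrainConfig", seed = 1L, epochs = 3L, batchSize = 6L)
  fit <- trainModel(graphs, labels, tcfg = tcfg)
  expect_equal(predictActivity(fit$model, list()), numeric(0))
  p <- predictActivity(fit$model, graphs)
  expect_true(all(is.finite(p)))
  expect_equal(length(p), 12L)
})

test_that("predictions are invariant to atom input order", {
  graphs <- smallGraphs()[1:12]
  labels <- setNames(smallActivity()$pic50[1:12],
                     vapply(graphs, function(g) g@molId, character(1)))
  tcfg <- methods::new("TrainConfig", seed = 2L, epochs = 5L, batchSize = 6L)
  fit <- trainModel(graphs, labels, tcfg = tcfg)
  g1 <- buildGraph(moleculeFromSmiles("c1ccccc1CCO", "perm"))
  g2 <- buildGraph(moleculeFromSmiles("OCCc1ccccc1", "perm"))
  p1 <- predictActivity(fit$model, list(g1))
  p2 <- predictActivity(fit$model, list(g2))
  expect_equal(unname(p1), unname(p2), tolerance = 1e-10)
})

test_that("model save/load round-trips predictions bitwise", {
  graphs <- smallGraphs()[1:12]
  labels <- setNames(smallActivity()$pic50[1:12],
                     vapply(graphs, function(g) g@molId, character(1)))
  tcfg <- methods::new("TrainConfig", seed = 4L, epochs = 4L, batchSize = 6L)
  fit <- trainModel(graphs, labels, tcfg = tcfg)
  dir <- withr::local_tempdir()
  saveModel(fit$model, dir)
  m2 <- loadModel(dir)
  probes <- smallGraphs()[13:22]
  expect_identical(predictActivity(fit$model, probes),
                   predictActivity(m2, probes))
  # corrupt/truncated artifacts are rejected with a clear error
  writeLines("not json {", file.path(dir, "config.json"))
  expect_error(loadModel(dir), "corrupt")
  expect_error(loadModel(withr::local_tempdir()), "not a model directory")
})

test_that("hyperparameter search is seeded and finds a known-good config", {
  graphs <- smallGraphs()[1:20]
  labels <- setNames(smallActivity()$pic50[1:20],
                     vapply(graphs, function(g) g@molId, character(1)))
  tcfg <- methods::new("TrainConfig", seed = 5L, epochs = 15L,
                       batchSize = 10L, earlyStopPatience = 0L)
  space <- list(nGatLayers = 1:2, hiddenDim = c(8L, 16L))
  one <- hyperparameterSearch(space, budget = 1, seed = 9, graphs, labels,
                              tcfg = tcfg)
  expect_s4_class(one$best, "ModelConfig")
  expect_equal(nrow(one$trials), 1L)
  oneB <- hyperparameterSearch(space, budget = 1, seed = 9, graphs, labels,
                               tcfg = tcfg)
  expect_identical(one$trials, oneB$trials)

  # exhaustive oracle over a small space: the search (full budget) must
  # match the best exhaustively evaluated configuration
  space2 <- list(hiddenDim = c(8L, 16L))
  res <- hyperparameterSearch(space2, budget = 6, seed = 2, graphs, labels,
                              tcfg = tcfg)
  exhaustive <- vapply(c(8L, 16L), function(h) {
    mcfg <- methods::new("ModelConfig", hiddenDim = h,
                         attentionHeads = 4L)
    trainModel(graphs, labels, mcfg, tcfg)$report@r2Val
  }, numeric(1))
  expect_gte(res$bestR2Val, max(exhaustive) - 1e-9)
  expect_error(hyperparameterSearch(list(), 1, 1, graphs, labels), "empty")
})
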