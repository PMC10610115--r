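test_that("a stage retains scores at or below the threshold, inclusive", {
  t <- data.frame(id = sprintf("m%02d", 1:5),
                  score = c(-10.0, -9.5, -8.2, -8.101, -7.0))
  out <- applyStage(t, funnelStage("XP", "score", -8.101))
  expect_equal(nrow(out), 4L)  # boundary value survives
  expect_true(all(out$score <= -8.101))

  capped <- applyStage(t, funnelStage("XP", "score", -8.101, maxRetained = 3L))
  expect_equal(sort(capped$score), c(-10.0, -9.5, -8.2))

  empty <- applyStage(t[0, ], funnelStage("XP", "score", -8))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "inputCount"), 0L)
  expect_error(applyStage(t, funnelStage("XP", "nope", -8)), "unknown")
})

test_that("stage filtering matches the brute-force sort-and-filter oracle", {
  set.seed(99)
  n <- 10000
  tab <- data.frame(id = sprintf("mol%05d", 1:n),
                    score = rnorm(n, -8, 1.5))
  tab$score[sample(n, 50)] <- NA
  for (thr in c(-9.5, -8, -6.532)) {
    for (cap in c(NA, 100L, 2000L)) {
      got <- applyStage(tab, funnelStage("s", "score", thr,
                                         maxRetained = cap))
      expect_equal(sort(got$id), oracleStage(tab, "score", thr, cap),
                   info = sprintf("thr=%g cap=%s", thr, cap))
    }
  }
})

test_that("applying the same stage twice equals applying it once", {
  set.seed(1)
  tab <- data.frame(id = sprintf("m%04d", 1:500), score = rnorm(500, -8, 1))
  s <- funnelStage("SP", "score", -8.3, maxRetained = 80L)
  once <- applyStage(tab, s)
  twice <- applyStage(once, s)
  expect_equal(twice$id, once$id)
})

test_that("quantile-placed thresholds give exact survivor counts", {
  set.seed(7)
  n <- 10000
  tab <- data.frame(id = sprintf("m%05d", 1:n), score = rnorm(n, -8, 2))
  thr1 <- sort(tab$score)[5000]               # exact order statistic
  s1 <- funnelStage("stage1", "score", thr1)
  surv1 <- applyStage(tab, s1)
  thr2 <- sort(surv1$score)[2000]
  rep <- runFunnel(tab, list(s1, funnelStage("stage2", "score", thr2)))
  expect_equal(rep@counts$output, c(5000L, 2000L))
  expect_true(all(diff(rep@counts$output) <= 0))

  # funnel survivors are invariant to input row order
  rep2 <- runFunnel(tab[sample(n), ], list(s1, funnelStage("s2", "score", thr2)))
  expect_setequal(rep2@finalTable$id, rep@finalTable$id)

  # threshold below every score: no survivors
  rep3 <- runFunnel(tab, list(funnelStage("all", "score", -Inf)))
  expect_equal(rep3@counts$output, 0L)
})

test_that("pose collapse keeps the best score per ligand before filtering", {
  tab <- data.frame(id = c("a", "a", "b"), score = c(-9, -11, -8))
  col <- collapseBestPose(tab)
  expect_equal(col$score[col$id == "a"], -11)
  rep <- runFunnel(tab, list(funnelStage("s", "score", -10)))
  expect_equal(rep@finalTable$id, "a")
})

test_that("consensus assembly joins per-method tables in report layout", {
  t1 <- data.frame(id = c("c1", "c2", "c3"), score_xp = c(-13.9, -11.9, -13.1))
  t2 <- data.frame(id = c("c1", "c2"), mmgbsa_dg = c(-86.1, -80.9))
  t3 <- data.frame(id = c("c2", "c1"), pic50_pred = c(5.89, 6.25))
  cons <- assembleConsensus(list(t1, t2, t3))
  expect_equal(nrow(cons), 2L)  # inner join
  expect_equal(names(cons), c("id", "score_xp", "mmgbsa_dg", "pic50_pred"))
  outer <- assembleConsensus(list(t1, t2, t3), outer = TRUE)
  expect_equal(nrow(outer), 3L)
  expect_true(is.na(outer$mmgbsa_dg[outer$id == "c3"]))
  expect_error(assembleConsensus(list(data.frame(id = c("a", "a"), s = 1:2))),
               "duplicate")
  # projecting the join back returns each original table on shared ids
  expect_equal(cons[c("id", "score_xp")],
               t1[t1$id %in% cons$id, ], ignore_attr = TRUE)
})

test_that("a published consensus row survives a CSV write/read round trip", {
  row <- data.frame(id = "compound6", score_htvs = -8.401, score_sp = -11.535,
                    score_xp = -13.065, mmgbsa_dg = -82.05,
                    external_score = -173.73, pic50_pred = 5.82)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(row, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back, row)
})

test_that("candidate ranking is a deterministic dominance-respecting composite", {
  t <- data.frame(id = c("worse", "better"),
                  score_xp = c(-9, -13), mmgbsa_dg = c(-70, -85),
                  external_score = c(-100, -180), pic50_pred = c(5.1, 6.5))
  r <- rankCandidates(t)
  expect_equal(r$id[1], "better")  # dominates on every column

  single <- rankCandidates(data.frame(id = "only", score_xp = -9,
                                      mmgbsa_dg = -80,
                                      external_score = -150,
                                      pic50_pred = 6))
  expect_equal(single$rank, 1L)

  # hand-recomputed composite on 5 synthetic rows
  set.seed(3)
  t5 <- data.frame(id = letters[1:5], score_xp = rnorm(5, -10),
                   mmgbsa_dg = rnorm(5, -80), external_score = rnorm(5, -150),
                   pic50_pred = rnorm(5, 6))
  zpop <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  comp <- -zpop(t5$score_xp) - zpop(t5$mmgbsa_dg) - zpop(t5$external_score) +
    zpop(t5$pic50_pred)
  r5 <- rankCandidates(t5)
  expect_equal(r5$id, t5$id[order(-comp, t5$id)])
  expect_equal(sort(r5$composite, decreasing = TRUE), r5$composite)
})
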