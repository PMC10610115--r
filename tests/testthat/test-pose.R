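test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  idfit <- kabschSuperpose(ref, ref)
  expect_lt(idfit$rmsd, 1e-12)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-10)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- ref %*% R + matrix(rep(c(5, -3, 2), each = 10), 10, 3)
  fit <- kabschSuperpose(ref, mob)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # collinear mask is degenerate
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschSuperpose(line, line + 1), "collinear")
})

test_that("Kabsch RMSD agrees with an independent quaternion-method oracle", {
  set.seed(21)
  for (rep in 1:5) {
    ref <- matrix(rnorm(12), 4, 3)
    mob <- ref + matrix(rnorm(12, 0, 0.5), 4, 3)
    mob[4, ] <- mob[4, ] + c(1, 0, 0)  # one atom displaced further
    fit <- kabschSuperpose(ref, mob)
    expect_equal(fit$rmsd, hornSuperpose(ref, mob), tolerance = 1e-6)
  }
})

test_that("ligand RMSD series behaves under identity, translation and known displacement", {
  ts <- genTrajectorySet(nFrames = 10, nReplicates = 1, jitterSigma = 0,
                         seed = 2)
  s <- ligandRmsdSeries(ts, 1)
  expect_equal(s$rmsd, rep(0, 10))

  # rigid translation of protein + ligand together: still zero after fit
  ts2 <- ts
  arr <- ts2@replicates[[1]]
  for (f in seq_len(dim(arr)[1])) arr[f, , ] <- arr[f, , ] +
      matrix(rep(c(10, -5, 3), each = dim(arr)[2]), dim(arr)[2], 3)
  ts2@replicates[[1]] <- arr
  expect_lt(max(ligandRmsdSeries(ts2, 1)$rmsd), 1e-10)

  # every ligand atom displaced by (1,0,0): RMSD exactly 1
  ts3 <- ts
  lig <- which(ts3@topology$segment == "ligand" & !ts3@topology$isHydrogen)
  arr <- ts3@replicates[[1]]
  for (f in seq_len(dim(arr)[1])) arr[f, lig, 1] <- arr[f, lig, 1] + 1
  ts3@replicates[[1]] <- arr
  expect_equal(ligandRmsdSeries(ts3, 1)$rmsd, rep(1, 10), tolerance = 1e-10)
})

test_that("PoseScore is the mean RMSD over frames and replicates", {
  ts <- genTrajectorySet(nFrames = 8, nReplicates = 2, jitterSigma = 0,
                         seed = 3)
  # shift replicate ligands by constant offsets: RMSDs 0.5 and 1.5
  lig <- which(ts@topology$segment == "ligand" & !ts@topology$isHydrogen)
  for (r in 1:2) {
    arr <- ts@replicates[[r]]
    for (f in seq_len(dim(arr)[1]))
      arr[f, lig, 1] <- arr[f, lig, 1] + c(0.5, 1.5)[r]
    ts@replicates[[r]] <- arr
  }
  expect_equal(poseScore(ts), 1.0, tolerance = 1e-10)
})

test_that("stable poses score lower than drifting poses for every seed", {
  for (seed in 1:10) {
    stable <- genTrajectorySet(nFrames = 60, nReplicates = 5,
                               motion = "stable", jitterSigma = 0.3,
                               seed = seed)
    drifting <- genTrajectorySet(nFrames = 60, nReplicates = 5,
                                 motion = "drifting", driftStep = 0.2,
                                 seed = seed)
    expect_lt(poseScore(stable), poseScore(drifting))
  }
})

test_that("hydrogen-bond detection respects inclusive geometric boundaries", {
  topo <- data.frame(
    name = c("N", "H", "O"), element = c("N", "H", "O"),
    segment = c("protein", "protein", "ligand"),
    isHydrogen = c(FALSE, TRUE, FALSE),
    isDonor = c(TRUE, FALSE, FALSE),
    isAcceptor = c(FALSE, FALSE, TRUE),
    hParent = c(NA, 1L, NA))
  # D-A 2.8 A, angle 180 degrees: detected
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))
  expect_equal(nrow(detectHBonds(xyz, topo)), 1L)
  # D-A 5.0 A: not detected
  xyz2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0))
  expect_equal(nrow(detectHBonds(xyz2, topo)), 0L)
  # exact boundary: D-A exactly 3.5 A and D-H-A exactly 120 degrees
  d <- 3.5
  # place H so that the D-H-A angle is exactly 120 degrees
  hpos <- c(cos(pi / 3), sin(pi / 3), 0)  # |DH| = 1
  apos <- c(d, 0, 0)
  v1 <- c(0, 0, 0) - hpos; v2 <- apos - hpos
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  xyz3 <- rbind(c(0, 0, 0), hpos, apos)
  crit <- methods::new("HBondCriteria", distCutoff = 3.5, angleCutoff = ang)
  expect_equal(nrow(detectHBonds(xyz3, topo, crit)), 1L)
  # donor without an attached hydrogen is a topology error
  badTopo <- topo; badTopo$hParent[2] <- NA
  expect_error(detectHBonds(xyz, badTopo[c(1, 3), ]), "hydrogen")
})

test_that("PersScore pools (bond, frame) pairs and hits scheduled occupancies", {
  # 2 bonds, one always present and one never present in the final window
  ts <- genTrajectorySet(nFrames = 100, nReplicates = 3, jitterSigma = 0,
                         nHBonds = 2, occupancy = c(1, 0), seed = 4)
  expect_equal(persScore(ts), 0.5)
  # single bond present in exactly 30% of final-window frames
  ts2 <- genTrajectorySet(nFrames = 100, nReplicates = 2, jitterSigma = 0,
                          nHBonds = 1, occupancy = 0.3, seed = 5)
  expect_equal(persScore(ts2), 0.3)
  # full persistence
  ts3 <- genTrajectorySet(nFrames = 50, nReplicates = 1, jitterSigma = 0,
                          nHBonds = 2, occupancy = 1, seed = 6)
  expect_equal(persScore(ts3), 1.0)
  # window longer than the trajectory errors
  expect_error(persScore(ts3, finalWindow = 100), "longer")
})

test_that("PersScore stays within [0,1] for random occupancy schedules", {
  set.seed(77)
  for (rep in 1:8) {
    occ <- runif(2)
    ts <- genTrajectorySet(nFrames = 40, nReplicates = 2, jitterSigma = 0,
                           nHBonds = 2, occupancy = occ, seed = rep)
    p <- persScore(ts)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("scores are invariant to a global rigid motion of all frames", {
  ts <- genTrajectorySet(nFrames = 30, nReplicates = 2, jitterSigma = 0.3,
                         occupancy = 0.5, nHBonds = 2, seed = 8)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(12, -7, 4)
  ts2 <- ts
  ts2@reference <- sweep(ts@reference %*% R, 2, shift, "+")
  for (r in seq_along(ts@replicates)) {
    arr <- ts@replicates[[r]]
    for (f in seq_len(dim(arr)[1]))
      arr[f, , ] <- sweep(arr[f, , ] %*% R, 2, shift, "+")
    ts2@replicates[[r]] <- arr
  }
  expect_equal(poseScore(ts2), poseScore(ts), tolerance = 1e-8)
  expect_equal(persScore(ts2), persScore(ts), tolerance = 1e-12)
})

test_that("increasing ligand displacement never decreases PoseScore", {
  base <- genTrajectorySet(nFrames = 15, nReplicates = 1, jitterSigma = 0,
                           seed = 9)
  lig <- which(base@topology$segment == "ligand" & !base@topology$isHydrogen)
  scores <- vapply(c(0, 0.5, 1, 2, 4), function(dx) {
    ts <- base
    arr <- ts@replicates[[1]]
    for (f in seq_len(dim(arr)[1])) arr[f, lig, 1] <- arr[f, lig, 1] + dx
    ts@replicates[[1]] <- arr
    poseScore(ts)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("pose selection ranks by PoseScore then PersScore then label", {
  mk <- function(ps, prs) methods::new("PoseStabilityResult", poseScore = ps,
                                       persScore = prs, rmsdSeries = list(),
                                       initialHBonds = data.frame())
  best <- selectStablePose(list(A = mk(0.8, 0.9), B = mk(2.5, 0.2)))
  expect_equal(as.character(best), "A")
  single <- selectStablePose(list(only = mk(1, 0.5)))
  expect_equal(as.character(single), "only")
  tie <- selectStablePose(list(x = mk(1, 0.4), y = mk(1, 0.7)))
  expect_equal(as.character(tie), "y")
  expect_error(selectStablePose(list()), "empty")
})
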