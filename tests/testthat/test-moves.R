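test_that("local start with pure spin keeps the antigen center fixed", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  ag <- which(poseAtoms(native)$group == 3L)
  set.seed(3)
  p <- localPerturbStart(native, tree, transSigma = 0, tiltSigma = 0)
  expect_equal(colMeans(poseCoords(p)[ag, ]), colMeans(poseCoords(native)[ag, ]),
               tolerance = 1e-9)
  # internal geometry preserved
  expect_lt(max(abs(dist(poseCoords(p)[ag, ]) - dist(poseCoords(native)[ag, ]))),
            1e-9)
  # antibody untouched
  expect_identical(poseCoords(p)[-ag, ], poseCoords(native)[-ag, ])
})

test_that("spin angles are uniform on [0, 360)", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  ag <- which(poseAtoms(native)$group == 3L)
  abIdx <- setdiff(seq_len(nAtoms(native)), ag)
  comAb <- colMeans(poseCoords(native)[abIdx, ])
  comAg <- colMeans(poseCoords(native)[ag, ])
  u <- (comAg - comAb) / sqrt(sum((comAg - comAb)^2))
  marker <- poseCoords(native)[ag[1], ]
  mPerp <- marker - comAg
  mPerp <- mPerp - sum(mPerp * u) * u
  set.seed(11)
  angles <- replicate(4000, {
    p <- localPerturbStart(native, tree, transSigma = 0, tiltSigma = 0)
    v <- poseCoords(p)[ag[1], ] - comAg
    v <- v - sum(v * u) * u
    a <- atan2(sum(u * AbAgDock:::cross3(mPerp, v)), sum(mPerp * v))
    (a / pi * 180) %% 360
  })
  ks <- suppressWarnings(ks.test(angles, "punif", 0, 360))
  expect_gt(ks$p.value, 0.01)
})

test_that("default initializer magnitudes are 8 A and 8 degrees", {
  p <- defaultPerturbParams()
  expect_equal(p$initTransSigma, 8)
  expect_equal(p$initTiltSigma, 8)
})

test_that("global start points the paratope toward the antigen", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  para <- cachedParatope()
  set.seed(5)
  for (i in 1:10) {
    p <- globalRandomizeStart(native, tree, para)
    ag <- which(poseAtoms(p)$group == 3L)
    abIdx <- setdiff(seq_len(nAtoms(p)), ag)
    comAb <- colMeans(poseCoords(p)[abIdx, ])
    rs <- poseResidues(p)
    pk <- paste(paratopeResidues(para)$chain, paratopeResidues(para)$resno)
    pu <- rs$resUid[paste(rs$chain, rs$resno) %in% pk]
    pIdx <- which(poseAtoms(p)$resUid %in% pu)
    a <- colMeans(poseCoords(p)[pIdx, ]) - comAb
    t <- colMeans(poseCoords(p)[ag, ]) - comAb
    ang <- acos(sum(a * t) / sqrt(sum(a^2) * sum(t^2))) / pi * 180
    expect_lte(ang, 45)
  }
})

test_that("uniform rotations have the closed-form mean rotation angle", {
  set.seed(9)
  angles <- replicate(10000, AbAgDock:::rotationAngle(AbAgDock:::randomRotation()))
  # E[theta] = 126.476 degrees for the uniform measure on SO(3)
  expect_equal(mean(angles), 126.476, tolerance = 2 / 126.476)
})

test_that("randomized starts are reproducible under a fixed seed", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  para <- cachedParatope()
  set.seed(21); p1 <- globalRandomizeStart(native, tree, para)
  set.seed(21); p2 <- globalRandomizeStart(native, tree, para)
  expect_identical(poseCoords(p1), poseCoords(p2))
})

test_that("slide-into-contact reaches glancing contact from afar", {
  # two effectively single-atom partners with r_vdw 1.7 each, 20 A apart:
  # the final nearest-atom distance must be within 1 A of vdW contact,
  # i.e. in (3.4, 4.4]
  pose <- miniPose(lightAt = c(0, 0, 0), heavyAt = c(0, 0, 0.001),
                   antigenAt = c(20, 0, 0))
  tree <- buildDockingFoldTree(pose)
  slid <- slideIntoContact(pose, tree)
  d <- sqrt(sum((poseCoords(slid)[3, ] - poseCoords(slid)[1, ])^2))
  expect_gt(d, 3.4)
  expect_lte(d, 4.4)
})

test_that("slide-into-contact matches a bisection oracle on the gap", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  set.seed(2)
  start <- localPerturbStart(native, tree)
  slid <- slideIntoContact(start, tree)
  a <- poseAtoms(slid)
  ab <- which(a$group %in% c(1L, 2L) & !a$isHydrogen)
  ag <- which(a$group == 3L & !a$isHydrogen)
  gaps <- vapply(ag, function(j) {
    min(sqrt(colSums((t(poseCoords(slid)[ab, ]) - poseCoords(slid)[j, ])^2)) -
          a$vdw[ab] - a$vdw[j])
  }, 1)
  expect_equal(min(gaps), 1.0, tolerance = 0.01)
  # an already-touching pose barely moves
  again <- slideIntoContact(slid, tree)
  expect_lt(max(abs(poseCoords(again) - poseCoords(slid))), 0.5)
})

test_that("rigid-body perturbation has the requested statistics", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  ag <- which(poseAtoms(native)$group == 3L)
  set.seed(13)
  zero <- rigidBodyPerturb(native, tree, "abag", 0, 0)
  expect_lt(max(abs(poseCoords(zero) - poseCoords(native))), 1e-9)
  disp <- t(replicate(10000, {
    p <- rigidBodyPerturb(native, tree, "abag", 0.5, 0)
    colMeans(poseCoords(p)[ag, ]) - colMeans(poseCoords(native)[ag, ])
  }))
  expect_equal(unname(apply(disp, 2, sd)), rep(0.5, 3), tolerance = 0.02)
  expect_error(rigidBodyPerturb(native, cachedLoopTree(), "vlvh", 1, 1),
               "frozen")
})

test_that("small and shear moves stay inside the loop and invert cleanly", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  set.seed(17)
  expect_identical(poseCoords(smallMove(native, tree, "H3", 0)),
                   poseCoords(native))
  p <- smallMove(native, tree, "H3", 6)
  a <- poseAtoms(native)
  outside <- which(!(a$chain == "H" & a$resno %in% 16:23))
  expect_identical(poseCoords(p)[outside, ], poseCoords(native)[outside, ])
  # a shear pair (+delta on phi i, -delta on psi i-1) undone by the inverse
  # pair restores the original coordinates
  s0 <- setBackboneTorsion(native, tree, "H", 18, "phi", 2.5, delta = TRUE)
  s0 <- setBackboneTorsion(s0, tree, "H", 17, "psi", -2.5, delta = TRUE)
  undo <- setBackboneTorsion(s0, tree, "H", 18, "phi", -2.5, delta = TRUE)
  undo <- setBackboneTorsion(undo, tree, "H", 17, "psi", 2.5, delta = TRUE)
  expect_lt(max(abs(poseCoords(undo) - poseCoords(native))), 1e-6)
})

test_that("single-torsion CCD updates never increase the anchor objective", {
  set.seed(23)
  for (rep in 1:20) {
    M <- matrix(rnorm(9, sd = 3), 3)
    F <- matrix(rnorm(9, sd = 3), 3)
    o <- rnorm(3); u <- rnorm(3)
    th <- AbAgDock:::ccdAngle(M, F, o, u)
    obj <- function(ang) {
      Mr <- AbAgDock:::rotateAbout(M, o, u, ang)
      sum((Mr - F)^2)
    }
    expect_lte(obj(th), obj(0) + 1e-9)
    expect_lte(obj(th), obj(th + 5) + 1e-9)
    expect_lte(obj(th), obj(th - 5) + 1e-9)
  }
})

test_that("CCD closes a perturbed loop and is a no-op when closed", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  done <- ccdClose(native, tree, "H3")
  expect_equal(done$sweeps, 0L)
  expect_identical(poseCoords(done$pose), poseCoords(native))
  set.seed(31)
  p <- native
  for (rn in 16:23)
    for (ang in c("phi", "psi"))
      p <- setBackboneTorsion(p, tree, "H", rn, ang, runif(1, -30, 30),
                              delta = TRUE)
  res <- ccdClose(p, tree, "H3")
  expect_true(res$converged)
  expect_lte(res$deviation, 0.15)
})

test_that("conformer swap preserves the antigen and samples uniformly", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  ab <- subsetPose(native, c("light", "heavy"))
  # size-1 ensemble leaves the pose unchanged (superposed onto itself)
  set.seed(41)
  same <- conformerSwap(native, list(ab), tree)
  expect_lt(max(abs(poseCoords(same) - poseCoords(native))), 1e-6)
  # equal-score members are selected uniformly
  ens <- replicate(10, ab, simplify = FALSE)
  set.seed(43)
  picks <- replicate(3000, {
    s <- conformerSwap(native, ens, tree)
    attr(s, "member")
  })
  freq <- tabulate(picks, 10) / length(picks)
  expect_true(all(abs(freq - 0.1) < 0.02))
  # antigen coordinates bit-identical across any swap
  ag <- which(poseAtoms(native)$group == 3L)
  mim <- cachedMimic()
  set.seed(47)
  sw <- conformerSwap(native, mim$ensemble, tree)
  expect_identical(poseCoords(sw)[ag, ], poseCoords(native)[ag, ])
  bad <- subsetPose(native, "antigen")
  expect_error(conformerSwap(native, list(bad), tree), "layout")
})

test_that("move selection follows the configured weights", {
  ms <- defaultMoveSet()
  expect_equal(sum(ms$weight), 1)
  only <- data.frame(name = letters[1:5], weight = c(1, 0, 0, 0, 0))
  set.seed(53)
  expect_true(all(selectMove(only, 100) == "a"))
  expect_error(selectMove(data.frame(name = "a", weight = 0)), "zero")
  # empirical CDF equals cumulative weights
  set.seed(59)
  draws <- selectMove(ms, 20000)
  freq <- table(factor(draws, levels = ms$name)) / 20000
  expect_true(all(abs(cumsum(as.numeric(freq)) - cumsum(ms$weight)) < 0.02))
})

test_that("loop relaxation keeps the loop closed and local", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  set.seed(61)
  p <- loopRelax(native, tree, "H3", scoreWeights(), maxAngle = 6)
  expect_lte(chainbreakDeviation(p, "H", 19),
             max(0.15, chainbreakDeviation(native, "H", 19)))
  a <- poseAtoms(native)
  outside <- which(!(a$chain == "H" & a$resno %in% 16:23))
  expect_identical(poseCoords(p)[outside, ], poseCoords(native)[outside, ])
  set.seed(67); p1 <- loopRelax(native, tree, "H3", scoreWeights(), 3)
  set.seed(67); p2 <- loopRelax(native, tree, "H3", scoreWeights(), 3)
  expect_identical(poseCoords(p1), poseCoords(p2))
})
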