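test_that("interface energy is exactly zero for separated partners", {
  native <- cachedNative()
  ag <- which(poseAtoms(native)$group == 3L)
  far <- native
  far@xyz[ag, 1] <- far@xyz[ag, 1] + 500
  rep <- scorePose(far)
  expect_identical(interfaceEnergy(rep), 0)
  expect_identical(unname(energyTerms(rep)[["interchain_ab_ag"]]), 0)
})

test_that("pair terms switch sign at the van der Waals contact distance", {
  # two carbon atoms in one chain, three residues apart, at exact contact
  atoms <- data.frame(chain = c("L", "L", "H", "A"), resno = c(1L, 4L, 1L, 1L),
                      insert = "", resid = "GLY", elety = "CA",
                      element = "C", occ = 1, bbComplete = FALSE,
                      stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(3.4, 0, 0), c(0, 0, 300), c(0, 0, 600))
  pose <- newPose(atoms, xyz, "fullatom",
                  c(L = "light", H = "heavy", A = "antigen"))
  terms <- energyTerms(scorePose(pose))
  expect_equal(unname(terms[["vdw_repulsive"]]), 0)
  expect_lt(terms[["contact_attractive"]], 0)
  # pushed 0.4 A inside contact, repulsion switches on
  pose@xyz[2, 1] <- 3.0
  expect_gt(energyTerms(scorePose(pose))[["vdw_repulsive"]], 0)
})

test_that("interface energy equals the separation-difference oracle", {
  native <- cachedNative()
  rep <- scorePose(native)
  ag <- which(poseAtoms(native)$group == 3L)
  far <- native
  far@xyz[ag, 1] <- far@xyz[ag, 1] + 500
  diffOracle <- energyTotal(rep) - energyTotal(scorePose(far))
  expect_equal(unname(interfaceEnergy(rep)), unname(diffOracle),
               tolerance = 1e-9)
})

test_that("scores are invariant under global rigid motion", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  moved <- rigidMove(native)
  treeM <- buildLoopFoldTree(moved, cachedParatope())
  e0 <- scorePose(native, tree = tree)
  e1 <- scorePose(moved, tree = treeM)
  expect_equal(energyTotal(e0), energyTotal(e1), tolerance = 1e-6)
  expect_equal(interfaceEnergy(e0), interfaceEnergy(e1), tolerance = 1e-6)
})

test_that("total equals the weighted sum of reported terms", {
  native <- cachedNative()
  w <- scoreWeights()
  rep <- scorePose(native, w, tree = cachedLoopTree())
  expect_equal(energyTotal(rep),
               sum(w@weights[names(energyTerms(rep))] * energyTerms(rep)),
               tolerance = 1e-9)
  expect_error(scoreWeights(chainbreak = -1), "chainbreak")
})

test_that("non-finite coordinates are rejected by the scorer", {
  native <- cachedNative()
  native@xyz[5, 2] <- NaN
  expect_error(scorePose(native), "finite")
})

test_that("Metropolis criterion accepts downhill always, uphill by kT", {
  expect_true(metropolisAccept(-1, 0.8))
  expect_true(metropolisAccept(0, 0.8))
  expect_false(metropolisAccept(Inf, 0.8))
  expect_error(metropolisAccept(1, 0), "kT")
  set.seed(7)
  acc <- mean(vapply(1:20000, function(i) metropolisAccept(0.8, 0.8), TRUE))
  expect_equal(acc, exp(-1), tolerance = 0.015)
})

test_that("minimization is monotone and touches only the selected DOF", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  w <- scoreWeights()
  # push the antigen into a mild clash, then free only the docking jump
  ag <- which(poseAtoms(native)$group == 3L)
  clashed <- native
  com <- colMeans(clashed@xyz[ag, ])
  dir <- colMeans(clashed@xyz[-ag, ]) - com
  clashed@xyz[ag, ] <- sweep(clashed@xyz[ag, ], 2,
                             1.8 * dir / sqrt(sum(dir^2)), "+")
  e0 <- scorePose(clashed, w)
  out <- minimizeDof(clashed, tree, moveMap(jumpsFree = "abag"), w)
  e1 <- scorePose(out, w)
  expect_lte(energyTotal(e1), energyTotal(e0))
  expect_lt(energyTerms(e1)[["interchain_ab_ag"]],
            energyTerms(e0)[["interchain_ab_ag"]])
  # frozen DOFs bit-identical
  expect_identical(poseCoords(out)[-ag, ], poseCoords(clashed)[-ag, ])
})

test_that("a pose at a local minimum is returned unchanged within tolerance", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  w <- scoreWeights()
  m1 <- minimizeDof(native, tree, moveMap(jumpsFree = "abag"), w,
                    maxSweeps = 100, maxEval = 2000)
  m2 <- minimizeDof(m1, tree, moveMap(jumpsFree = "abag"), w,
                    maxSweeps = 100, maxEval = 2000)
  expect_lte(energyTotal(scorePose(m2, w)), energyTotal(scorePose(m1, w)))
  expect_lt(abs(energyTotal(scorePose(m2, w)) - energyTotal(scorePose(m1, w))),
            0.05)
  expect_warning(minimizeDof(native, tree, moveMap(), w), "empty")
})

test_that("side-chain packing relieves a constructed clash", {
  # a serine whose OG is rotated into a fixed atom; packing must find the
  # chi minimizing the repulsion, matching an exhaustive 10-degree scan
  native <- cachedNative()
  a <- poseAtoms(native)
  serUid <- poseResidues(native)$resUid[poseResidues(native)$resid == "SER"][1]
  pose <- AbAgDock:::setChi(native, serUid, 1, 35)
  og <- which(a$resUid == serUid & a$elety == "OG")
  # place a blocking antigen atom 1.2 A from OG
  agCa <- which(a$group == 3L & a$elety == "CA")[1]
  pose@xyz[agCa, ] <- pose@xyz[og, ] + c(1.2, 0, 0)
  w <- scoreWeights()
  e0 <- energyTotal(scorePose(pose, w))
  packed <- packSidechains(pose, serUid, w)
  e1 <- energyTotal(scorePose(packed, w))
  expect_lt(e1, e0)
  # exhaustive 10-degree oracle over chi1
  grid <- seq(-180, 170, by = 10)
  oracle <- min(vapply(grid, function(chi)
    energyTotal(scorePose(AbAgDock:::setChi(pose, serUid, 1, chi), w)), 1))
  expect_lte(e1, oracle + 0.05)
  # backbone is untouched
  bb <- which(a$isBackbone)
  expect_identical(poseCoords(packed)[bb, ], poseCoords(pose)[bb, ])
  # empty selection is the identity
  expect_identical(poseCoords(packSidechains(pose, integer(), w)),
                   poseCoords(pose))
  expect_error(packSidechains(toCentroid(pose), serUid, w), "full-atom")
})
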