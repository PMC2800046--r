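test_that("ligand rmsd is zero on self and exact for pure translations", {
  native <- cachedNative()
  expect_lt(ligandRmsd(native, native), 1e-9)
  ag <- which(poseAtoms(native)$group == 3L)
  p <- native
  p@xyz[ag, ] <- sweep(p@xyz[ag, ], 2, c(3, 0, 0), "+")
  expect_equal(ligandRmsd(p, native), 3, tolerance = 1e-9)
})

test_that("interface rmsd uses the native interface set only", {
  native <- cachedNative()
  expect_lt(interfaceRmsd(native, native), 1e-9)
  # moving only residues outside the native interface changes nothing
  uids <- bruteInterfaceUids(native, 10)
  a <- poseAtoms(native)
  out <- which(!a$resUid %in% uids)
  p <- native
  p@xyz[out, ] <- p@xyz[out, ] + 5
  expect_lt(interfaceRmsd(p, native), 1e-9)
})

test_that("metrics agree with independent brute-force implementations", {
  native <- cachedNative()
  decoys <- makeDecoyCloud(native, n = 12, magnitude = 15, rotSigma = 10,
                           seed = 77)
  for (d in decoys) {
    expect_equal(ligandRmsd(d, native), bruteLigandRmsd(d, native),
                 tolerance = 1e-6)
    expect_equal(interfaceRmsd(d, native), bruteInterfaceRmsd(d, native),
                 tolerance = 1e-6)
    expect_equal(fnat(d, native), bruteFnat(d, native), tolerance = 1e-9)
  }
})

test_that("fnat is 1 on self, 0 for separated partners, exact at 5 A", {
  native <- cachedNative()
  expect_equal(fnat(native, native), 1)
  ag <- which(poseAtoms(native)$group == 3L)
  far <- native
  far@xyz[ag, 1] <- far@xyz[ag, 1] + 500
  expect_equal(fnat(far, native), 0)
  expect_error(fnat(native, far), "contacts")
  # a single contact flips exactly at the 5 A threshold
  base <- miniPose(lightAt = c(0, 0, 0), heavyAt = c(0, 0, 3),
                   antigenAt = c(4.5, 0, 0))
  mk <- function(d) miniPose(lightAt = c(0, 0, 0), heavyAt = c(0, 0, 3),
                             antigenAt = c(d, 0, 0))
  expect_equal(fnat(mk(4.99), base), 1)
  expect_equal(fnat(mk(5.00), base), 1)
  expect_equal(fnat(mk(5.01), base), 0)
})

test_that("CAPRI ratings reproduce the anchor worked examples", {
  expect_equal(capriRate(8.9, 4.2, 0.39), "acceptable")
  expect_equal(capriRate(6.6, 3.5, 0.55), "medium")
  expect_equal(capriRate(12, 5, 0.0), "incorrect")
  expect_equal(capriRate(0.5, 0.4, 0.9), "high")
})

test_that("CAPRI rating is monotone in fnat at fixed rmsds", {
  rank <- function(x) match(x, c("incorrect", "acceptable", "medium", "high"))
  for (L in c(0.5, 2, 6, 12)) {
    for (I in c(0.5, 1.5, 3, 5)) {
      r <- rank(capriRate(L, I, seq(0, 1, by = 0.05)))
      expect_true(all(diff(r) >= 0))
    }
  }
})

test_that("funnel detection implements the 5-of-10 rule", {
  energies <- 1:12
  five <- c(rep("medium", 5), rep("incorrect", 7))
  four <- c(rep("medium", 4), rep("incorrect", 8))
  expect_true(detectFunnel(five, energies))
  expect_false(detectFunnel(four, energies))
  expect_true(detectFunnel(rep("high", 12), energies))
  # strict reading counts only medium
  expect_false(detectFunnel(rep("high", 12), energies, strictMedium = TRUE))
  expect_error(detectFunnel(five[1:8], energies[1:8]), "at least 10")
  # funnel judged on the 10 lowest energies, not the full set
  ratings <- c(rep("incorrect", 10), rep("medium", 5))
  expect_false(detectFunnel(ratings, 1:15))
  expect_true(detectFunnel(ratings, c(rep(100, 10), 1:5)))
})

test_that("diversity statistics isolate the moved segment", {
  ab <- cachedAntibody()
  para <- cachedParatope()
  expect_true(all(diversityStats(list(ab, ab), ab, para)$mean_rmsd < 1e-9))
  # translate H3 rigidly by 1 A: its rmsd is 1, the other CDRs stay 0
  a <- poseAtoms(ab)
  h3 <- which(a$chain == "H" & a$resno %in% 16:23)
  p <- ab
  p@xyz[h3, ] <- sweep(p@xyz[h3, ], 2, c(1, 0, 0), "+")
  st <- diversityStats(list(p), ab, para)
  expect_equal(st$mean_rmsd[st$segment == "H3"], 1, tolerance = 1e-9)
  expect_lt(max(st$mean_rmsd[st$segment %in% c("L1", "L2", "L3", "H1", "H2")]),
            1e-9)
})

test_that("perturbation tables carry the rescored native as reference", {
  native <- cachedNative()
  decoys <- makeDecoyCloud(native, n = 4, magnitude = 8, seed = 5)
  set <- methods::new("DecoySet",
    decoys = lapply(seq_along(decoys), function(i)
      methods::new("Decoy", pose = decoys[[i]], bestPose = decoys[[i]],
                   energy = scorePose(decoys[[i]]), stats = list(),
                   seed = i)),
    table = data.frame(decoy = 1:4, seed = 1:4,
                       total = vapply(decoys, function(p)
                         energyTotal(scorePose(p)), 1),
                       interface_energy = vapply(decoys, function(p)
                         interfaceEnergy(scorePose(p)), 1)))
  tab <- perturbationTable(set, native)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$ligand_rmsd[1], 0)
  expect_equal(tab$rating,
               c("high", capriRate(tab$ligand_rmsd[-1], tab$interface_rmsd[-1],
                                   tab$fnat[-1])))
})

test_that("metrics are invariant under a common rigid motion", {
  native <- cachedNative()
  d <- makeDecoyCloud(native, n = 1, magnitude = 6, rotSigma = 15,
                      seed = 9)[[1]]
  dM <- rigidMove(d); nM <- rigidMove(native)
  expect_equal(ligandRmsd(dM, nM), ligandRmsd(d, native), tolerance = 1e-6)
  expect_equal(interfaceRmsd(dM, nM), interfaceRmsd(d, native),
               tolerance = 1e-6)
  expect_equal(fnat(dM, nM), fnat(d, native), tolerance = 1e-9)
})
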