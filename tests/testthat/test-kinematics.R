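test_that("docking fold tree has two flexible jumps over three segments", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  expect_named(tree@jumps, c("vlvh", "abag"))
  expect_true(all(vapply(tree@jumps, function(j) j$flexible, TRUE)))
  expect_equal(nrow(tree@cutpoints), 0)
  expect_error(buildDockingFoldTree(subsetPose(native, c("light", "heavy"))),
               "antigen")
})

test_that("identity jump transform leaves all coordinates unchanged", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  same <- applyJump(native, tree, "abag")
  expect_lt(max(abs(poseCoords(same) - poseCoords(native))), 1e-12)
})

test_that("jump translation displaces exactly the downstream body", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  p <- applyJump(native, tree, "abag", t = c(5, 0, 0))
  ag <- which(poseAtoms(native)$group == 3L)
  expect_equal(poseCoords(p)[ag, ],
               sweep(poseCoords(native)[ag, ], 2, c(5, 0, 0), "+"),
               tolerance = 1e-12)
  expect_identical(poseCoords(p)[-ag, ], poseCoords(native)[-ag, ])
  # and a vlvh jump never touches the antigen
  p2 <- applyJump(native, tree, "vlvh",
                  R = AbAgDock:::rotationMatrix(c(0, 0, 1), 12), t = c(1, 1, 0))
  expect_identical(poseCoords(p2)[ag, ], poseCoords(native)[ag, ])
})

test_that("jump transforms are exact isometries of the downstream body", {
  native <- cachedNative()
  tree <- buildDockingFoldTree(native)
  set.seed(1)
  p <- rigidBodyPerturb(native, tree, "abag", 2, 20)
  ag <- which(poseAtoms(native)$group == 3L)
  d0 <- dist(poseCoords(native)[ag, ])
  d1 <- dist(poseCoords(p)[ag, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("loop fold tree anchors stems and cuts at the loop middle", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  expect_equal(nrow(tree@cutpoints), 6)
  expect_false(tree@jumps$vlvh$flexible)
  # torsion change inside H3 leaves everything outside the loop unchanged
  p <- setBackboneTorsion(native, tree, "H", 18, "phi", -120)
  a <- poseAtoms(native)
  outside <- which(!(a$chain == "H" & a$resno %in% 16:23))
  expect_identical(poseCoords(p)[outside, ], poseCoords(native)[outside, ])
  # a loop touching the chain terminus has no stem
  noStem <- fixtureSpec()$loops
  noStem[[6]]$stop <- 24
  expect_error(buildLoopFoldTree(native,
               loadLoopDefinitions(noStem, native)), "stem")
})

test_that("setting a torsion to its current value is the identity", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  phi <- measureTorsion(native, "H", 18, "phi")
  p <- setBackboneTorsion(native, tree, "H", 18, "phi", phi)
  expect_lt(max(abs(poseCoords(p) - poseCoords(native))), 1e-9)
})

test_that("set torsion reads back the requested value", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  for (case in list(c("H", 17, "phi"), c("H", 18, "psi"),
                    c("H", 21, "phi"), c("H", 22, "psi"),
                    c("L", 9, "phi"))) {
    p <- setBackboneTorsion(native, tree, case[1], as.integer(case[2]),
                            case[3], -77.5)
    expect_equal(measureTorsion(p, case[1], as.integer(case[2]), case[3]),
                 -77.5, tolerance = 1e-6)
  }
})

test_that("torsion propagation matches an explicit rotation oracle", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  a <- poseAtoms(native)
  # rotate psi of H17 by +10 degrees; the N-terminal half of H3 (up to the
  # cutpoint at 19) downstream of the bond must rotate about CA-C of H17
  p <- setBackboneTorsion(native, tree, "H", 17, "psi", 10, delta = TRUE)
  ca <- poseCoords(native)[which(a$chain == "H" & a$resno == 17 & a$elety == "CA"), ]
  cc <- poseCoords(native)[which(a$chain == "H" & a$resno == 17 & a$elety == "C"), ]
  # independent rotation: local Rodrigues formula, not the package helper
  rot <- function(X, p0, u, th) {
    u <- u / sqrt(sum(u^2)); th <- th * pi / 180
    t(apply(X, 1, function(v) {
      v <- v - p0
      v * cos(th) + c(u[2] * v[3] - u[3] * v[2],
                      u[3] * v[1] - u[1] * v[3],
                      u[1] * v[2] - u[2] * v[1]) * sin(th) +
        u * sum(u * v) * (1 - cos(th)) + p0
    }))
  }
  moved <- which(a$chain == "H" & a$resno %in% 18:19)
  oracle <- rot(poseCoords(native)[moved, ], ca, cc - ca, 10)
  expect_lt(max(abs(poseCoords(p)[moved, ] - oracle)), 1e-6)
  # downstream of the cutpoint nothing moves (contrast with a plain chain,
  # where everything C-terminal of residue 17 would rotate)
  beyondCut <- which(a$chain == "H" & a$resno %in% 20:24)
  expect_identical(poseCoords(p)[beyondCut, ], poseCoords(native)[beyondCut, ])
})

test_that("torsion moves preserve bond lengths and angles", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  p <- setBackboneTorsion(native, tree, "H", 18, "phi", -150)
  a <- poseAtoms(native)
  idx <- function(rn, at) which(a$chain == "H" & a$resno == rn & a$elety == at)
  bond <- function(pose, i, j)
    sqrt(sum((poseCoords(pose)[i, ] - poseCoords(pose)[j, ])^2))
  for (rn in 16:22) {
    expect_equal(bond(p, idx(rn, "N"), idx(rn, "CA")),
                 bond(native, idx(rn, "N"), idx(rn, "CA")), tolerance = 1e-9)
    expect_equal(bond(p, idx(rn, "CA"), idx(rn, "C")),
                 bond(native, idx(rn, "CA"), idx(rn, "C")), tolerance = 1e-9)
  }
})

test_that("movemap freezes residues against torsion changes", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  mm <- moveMap(backboneFree = integer())
  expect_error(setBackboneTorsion(native, tree, "H", 18, "phi", 0,
                                  movemap = mm), "frozen")
})

test_that("chainbreak deviation behaves like a closure measure", {
  native <- cachedNative()
  tree <- cachedLoopTree()
  # ideal-geometry fixture loop is essentially closed
  expect_lt(chainbreakDeviation(native, "H", 19), 0.1)
  # randomized torsions open the cut wide
  set.seed(42)
  p <- native
  for (rn in 16:19)
    for (ang in c("phi", "psi"))
      p <- setBackboneTorsion(p, tree, "H", rn, ang, runif(1, -180, 180))
  expect_gt(chainbreakDeviation(p, "H", 19), 1)
  # isometry invariance
  moved <- rigidMove(p)
  expect_equal(chainbreakDeviation(moved, "H", 19),
               chainbreakDeviation(p, "H", 19), tolerance = 1e-9)
})
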