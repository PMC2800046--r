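test_that("PDB write/read round trip preserves atoms and coordinates", {
  native <- cachedNative()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdb(native, f)
  back <- readPdb(f, posePartition(native))
  expect_equal(nAtoms(back), nAtoms(native))
  expect_equal(poseAtoms(back)$elety, poseAtoms(native)$elety)
  expect_equal(poseAtoms(back)$chain, poseAtoms(native)$chain)
  # coordinates are written to 3 decimals
  expect_lt(max(abs(poseCoords(back) - poseCoords(native))), 1e-3)
  expect_lt(max(abs(poseCoords(back) - poseCoords(native))), 5e-4 + 5e-4)
})

test_that("altloc records collapse to the highest occupancy copy", {
  rec <- function(serial, name, alt, res, chain, resno, x, y, z, occ,
                  type = "ATOM") {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, paste0(" ", name), alt, res, chain, resno,
            x, y, z, occ, 0, substr(name, 1, 1))
  }
  lines <- c(
    rec(1, "N", " ", "ALA", "L", 1, 0, 0, 0, 1),
    rec(2, "CA", "A", "ALA", "L", 1, 1.458, 0, 0, 0.40),
    rec(3, "CA", "B", "ALA", "L", 1, 9.999, 0, 0, 0.60),
    rec(4, "C", " ", "ALA", "L", 1, 2.009, 1.421, 0, 1),
    rec(5, "O", " ", "ALA", "L", 1, 1.251, 2.390, 0, 1),
    rec(6, "N", " ", "GLY", "H", 1, 0, 5, 0, 1),
    rec(7, "CA", " ", "GLY", "H", 1, 1.458, 5, 0, 1),
    rec(8, "C", " ", "GLY", "H", 1, 2.009, 6.421, 0, 1),
    rec(9, "O", " ", "GLY", "H", 1, 1.251, 7.390, 0, 1),
    rec(10, "O", " ", "HOH", "A", 1, 8, 8, 8, 1, type = "HETATM"),
    rec(11, "N", " ", "ALA", "A", 1, 0, 10, 0, 1),
    rec(12, "CA", " ", "ALA", "A", 1, 1.458, 10, 0, 1),
    rec(13, "C", " ", "ALA", "A", 1, 2.009, 11.421, 0, 1),
    rec(14, "O", " ", "ALA", "A", 1, 1.251, 12.390, 0, 1),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  pose <- readPdb(f, c(L = "light", H = "heavy", A = "antigen"))
  a <- poseAtoms(pose)
  ca <- which(a$chain == "L" & a$elety == "CA")
  expect_length(ca, 1)
  expect_equal(poseCoords(pose)[ca, 1], 9.999)  # occupancy 0.60 wins
  expect_false(any(a$resid == "HOH"))           # water dropped
})

test_that("missing partition chain is a fatal configuration error", {
  native <- cachedNative()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdb(native, f)
  expect_error(readPdb(f, c(L = "light", H = "heavy", Z = "antigen")),
               "absent")
  empty <- subsetPose(native, "antigen")
  empty@atoms <- empty@atoms[0, ]
  empty@xyz <- empty@xyz[0, , drop = FALSE]
  expect_error(writePdb(empty, f), "empty")
})

test_that("centroid conversion replaces side chains by one pseudo-atom", {
  native <- cachedNative()
  cen <- toCentroid(native)
  expect_equal(poseResolution(cen), "centroid")
  rs <- poseResidues(cen)
  expect_true(all(rs$last - rs$first + 1 == 5))  # N,CA,C,O + CEN

  a <- poseAtoms(native)
  ac <- poseAtoms(cen)
  # alanine: pseudo-atom at CB
  iAla <- which(a$resid == "ALA" & a$elety == "CB")[1]
  uid <- a$resUid[iAla]
  cenIdx <- which(ac$resUid == uid & ac$elety == "CEN")
  expect_equal(poseCoords(cen)[cenIdx, ], unname(poseCoords(native)[iAla, ]),
               tolerance = 1e-12)
  # glycine: pseudo-atom coincides with CA
  gUid <- poseResidues(native)$resUid[poseResidues(native)$resid == "GLY"][1]
  gCen <- which(ac$resUid == gUid & ac$elety == "CEN")
  gCa <- which(ac$resUid == gUid & ac$elety == "CA")
  expect_equal(poseCoords(cen)[gCen, ], poseCoords(cen)[gCa, ])
  # multi-atom side chain: pseudo-atom is the brute-force heavy-atom mean
  kUid <- poseResidues(native)$resUid[poseResidues(native)$resid == "LYS"][1]
  sc <- which(a$resUid == kUid & !a$elety %in% c("N", "CA", "C", "O"))
  kCen <- which(ac$resUid == kUid & ac$elety == "CEN")
  expect_equal(poseCoords(cen)[kCen, ],
               colMeans(poseCoords(native)[sc, , drop = FALSE]),
               tolerance = 1e-12)
  expect_warning(toCentroid(cen), "already centroid")
})

test_that("full-atom rebuild from donors is exact for an unmoved backbone", {
  native <- cachedNative()
  fa <- toFullatom(toCentroid(native), donors = native)
  a <- poseAtoms(native); b <- poseAtoms(fa)
  keyA <- paste(a$chain, a$resno, a$elety)
  keyB <- paste(b$chain, b$resno, b$elety)
  expect_setequal(keyA, keyB)
  m <- match(keyA, keyB)
  expect_lt(max(abs(poseCoords(native) - poseCoords(fa)[m, ])), 1e-6)
  # glycine gains no side-chain atoms
  g <- poseResidues(fa)[poseResidues(fa)$resid == "GLY", ]
  expect_true(all(g$last - g$first + 1 == 4))
})

test_that("rigidly moved backbone carries grafted side chains along", {
  native <- cachedNative()
  moved <- rigidMove(native)
  fa <- toFullatom(toCentroid(moved), donors = native)
  # side chains must equal the rigidly moved originals to 1e-6
  a <- poseAtoms(moved); b <- poseAtoms(fa)
  keyA <- paste(a$chain, a$resno, a$elety)
  keyB <- paste(b$chain, b$resno, b$elety)
  m <- match(keyA, keyB)
  expect_lt(max(abs(poseCoords(moved) - poseCoords(fa)[m, ])), 1e-6)
})

test_that("donor residue name mismatch raises an error", {
  native <- cachedNative()
  bad <- native
  bad@atoms$resid[bad@atoms$resUid == 1] <- "SER"
  attr(bad@atoms, "resTable") <- NULL
  expect_error(toFullatom(toCentroid(native), donors = bad), "mismatch")
})

test_that("pose invariants hold on generated fixtures", {
  native <- cachedNative()
  a <- poseAtoms(native)
  expect_true(all(a$vdw > 0))
  expect_true(all(is.finite(poseCoords(native))))
  expect_true(all(a$elety[a$isBackbone] %in% c("N", "CA", "C", "O")))
  rs <- poseResidues(native)
  for (ch in unique(rs$chain))
    expect_false(is.unsorted(rs$resno[rs$chain == ch], strictly = TRUE))
})
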