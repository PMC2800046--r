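# Fold-tree kinematics: jump transforms, torsion propagation with loop
# cutpoints, and chainbreak measurement.
#
# Two trees are used.  The docking tree has two flexible jumps -- light<->
# heavy and antibody<->antigen -- and no cutpoints: jump moves are exact
# isometries of the downstream body (heavy chain, or antigen).  The loop tree
# has a fixed stem jump per CDR loop and a cut at the loop middle, so torsion
# changes inside a loop never displace atoms outside it: the N-terminal half
# (start..cut) propagates forward from the start stem, the C-terminal half
# (cut+1..stop) propagates backward from the stop stem.

# Idealized peptide geometry used at cutpoints (Engh-Huber-like values).
PEP_C_N <- 1.329
PEP_N_CA <- 1.458
PEP_ANG_CACN <- 116.2
PEP_ANG_CNCA <- 121.7

#' Build the docking fold tree
#'
#' Two flexible jumps: `vlvh` moves the heavy chain relative to the light
#' chain, `abag` moves the antigen relative to the whole antibody. No
#' cutpoints: chains stay rigid.
#'
#' @param pose a partitioned [Pose-class] (light + heavy + antigen).
#' @return a [FoldTree-class] of kind `"dock"`.
#' @export
buildDockingFoldTree <- function(pose) {
  for (role in c("light", "heavy", "antigen"))
    if (!any(pose@partition == role))
      stop("pose is missing the ", role, " partner")
  jumps <- list(
    vlvh = list(down = groupAtomIdx(pose, "heavy"), flexible = TRUE),
    abag = list(down = groupAtomIdx(pose, "antigen"), flexible = TRUE)
  )
  methods::new("FoldTree", kind = "dock", jumps = jumps,
               cutpoints = data.frame(), loops = data.frame())
}

#' Build the loop-relaxation fold tree
#'
#' Per loop: a fixed jump joining the stem residues (start-1, stop+1) and a
#' cutpoint at the loop middle. The light-heavy jump is frozen unless
#' `allowVlVh`; this is the tree used during CDR relaxation so loop moves
#' cannot drag the antigen or reorient the Fv.
#'
#' @param pose a [Pose-class].
#' @param loops a [ParatopeMap-class] or its `loops` data.frame (possibly a
#'   subset of the six CDRs).
#' @param allowVlVh keep the light-heavy jump flexible? Default `FALSE`.
#' @return a [FoldTree-class] of kind `"loop"`.
#' @export
buildLoopFoldTree <- function(pose, loops, allowVlVh = FALSE) {
  lp <- if (methods::is(loops, "ParatopeMap")) loops@loops else loops
  rs <- poseResidues(pose)
  uidOf <- function(ch, rn) {
    u <- rs$resUid[rs$chain == ch & rs$resno == rn]
    if (length(u) != 1) stop(sprintf("residue %s%d not in pose", ch, rn))
    u
  }
  lp$uidStart <- mapply(uidOf, lp$chain, lp$start)
  lp$uidStop <- mapply(uidOf, lp$chain, lp$stop)
  lp$uidCut <- mapply(uidOf, lp$chain, lp$cutpoint)
  for (i in seq_len(nrow(lp))) {
    have <- rs$resno[rs$chain == lp$chain[i]]
    if (!(lp$start[i] - 1) %in% have || !(lp$stop[i] + 1) %in% have)
      stop(sprintf("loop %s lacks a stem residue at one terminus", lp$name[i]))
  }
  jumps <- list(
    vlvh = list(down = groupAtomIdx(pose, "heavy"), flexible = allowVlVh)
  )
  for (i in seq_len(nrow(lp)))
    jumps[[paste0("stem_", lp$name[i])]] <-
      list(down = integer(), flexible = FALSE)
  cuts <- data.frame(chain = lp$chain, resno = lp$cutpoint,
                     resUid = lp$uidCut, stringsAsFactors = FALSE)
  methods::new("FoldTree", kind = "loop", jumps = jumps, cutpoints = cuts,
               loops = lp)
}

#' Apply a rigid transform to a jump's downstream body
#'
#' Rotation about the downstream body's center of mass followed by a
#' translation: an exact isometry of that body; all other atoms untouched.
#'
#' @param pose a [Pose-class].
#' @param tree the [FoldTree-class] holding the jump.
#' @param jump jump name (`"vlvh"` or `"abag"`).
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation (default zero).
#' @return the transformed [Pose-class].
#' @export
applyJump <- function(pose, tree, jump, R = diag(3), t = c(0, 0, 0)) {
  j <- tree@jumps[[jump]]
  if (is.null(j)) stop("no jump named ", jump)
  if (!isTRUE(j$flexible)) stop("jump ", jump, " is frozen in this fold tree")
  idx <- j$down
  com <- colMeans(pose@xyz[idx, , drop = FALSE])
  X <- sweep(pose@xyz[idx, , drop = FALSE], 2, com)
  pose@xyz[idx, ] <- sweep(X %*% t(R), 2, com + t, FUN = "+")
  pose
}

bbIdxOfResidue <- function(pose, uid) {
  a <- pose@atoms
  span <- which(a$resUid == uid)
  sapply(c("N", "CA", "C", "O"), function(n) {
    i <- span[match(n, a$elety[span])]
    if (is.na(i)) NA_integer_ else i
  })
}

#' Measure a backbone torsion
#'
#' @param pose a [Pose-class].
#' @param chain,resno residue identity.
#' @param angle `"phi"`, `"psi"` or `"omega"`.
#' @return angle in degrees, `NA` at chain termini.
#' @export
measureTorsion <- function(pose, chain, resno, angle = c("phi", "psi", "omega")) {
  angle <- match.arg(angle)
  rs <- poseResidues(pose)
  i <- which(rs$chain == chain & rs$resno == resno)
  if (length(i) != 1) stop("residue not found")
  uid <- rs$resUid[i]
  bb <- bbIdxOfResidue(pose, uid)
  prevU <- which(rs$chain == chain & rs$resno == resno - 1)
  nextU <- which(rs$chain == chain & rs$resno == resno + 1)
  x <- pose@xyz
  if (angle == "phi") {
    if (!length(prevU)) return(NA_real_)
    pb <- bbIdxOfResidue(pose, rs$resUid[prevU])
    dihedral4(x[pb["C"], ], x[bb["N"], ], x[bb["CA"], ], x[bb["C"], ])
  } else if (angle == "psi") {
    if (!length(nextU)) return(NA_real_)
    nb <- bbIdxOfResidue(pose, rs$resUid[nextU])
    dihedral4(x[bb["N"], ], x[bb["CA"], ], x[bb["C"], ], x[nb["N"], ])
  } else {
    if (!length(nextU)) return(NA_real_)
    nb <- bbIdxOfResidue(pose, rs$resUid[nextU])
    dihedral4(x[bb["CA"], ], x[bb["C"], ], x[nb["N"], ], x[nb["CA"], ])
  }
}

# Which loop of a loop tree contains residue uid; NULL if none.
loopOfResidue <- function(tree, uid) {
  lp <- tree@loops
  i <- which(lp$uidStart <= uid & uid <= lp$uidStop)
  if (!length(i)) NULL else lp[i[1], ]
}

# Atom indices moved by a torsion change, with the axis (point, direction
# toward the moving side). Forward half: start..cut anchored at the start
# stem; backward half: cut+1..stop anchored at the stop stem.
torsionMoveSet <- function(pose, tree, uid, angle) {
  lp <- loopOfResidue(tree, uid)
  if (is.null(lp)) stop("residue is not inside a loop of this fold tree")
  a <- pose@atoms
  span <- which(a$resUid == uid)
  bb <- bbIdxOfResidue(pose, uid)
  forward <- uid <= lp$uidCut
  resRange <- function(from, to)
    if (from > to) integer() else which(a$resUid %in% from:to)
  if (forward) {
    if (angle == "phi") {
      axisP <- pose@xyz[bb["N"], ]; axisD <- pose@xyz[bb["CA"], ] - axisP
      mov <- c(span[!a$elety[span] %in% c("N", "H")],
               resRange(uid + 1, lp$uidCut))
    } else {
      axisP <- pose@xyz[bb["CA"], ]; axisD <- pose@xyz[bb["C"], ] - axisP
      mov <- c(span[a$elety[span] == "O"], resRange(uid + 1, lp$uidCut))
    }
  } else {
    if (angle == "psi") {
      axisP <- pose@xyz[bb["C"], ]; axisD <- pose@xyz[bb["CA"], ] - axisP
      mov <- c(span[!a$elety[span] %in% c("C", "O")],
               resRange(lp$uidCut + 1, uid - 1))
    } else {
      axisP <- pose@xyz[bb["CA"], ]; axisD <- pose@xyz[bb["N"], ] - axisP
      mov <- c(span[a$elety[span] == "H"],
               resRange(lp$uidCut + 1, uid - 1))
    }
  }
  list(axisPoint = axisP, axisDir = axisD, moving = mov, forward = forward)
}

#' Set a backbone torsion with fold-tree propagation
#'
#' Rebuilds Cartesian coordinates by rotating the loop half on the moving
#' side of the torsion about the bond axis; bond lengths and angles are
#' untouched, and atoms outside the loop never move (stems are anchored by
#' the fixed jumps, propagation stops at the cutpoint).
#'
#' @param pose a [Pose-class].
#' @param tree a loop [FoldTree-class] whose loops contain the residue.
#' @param chain,resno residue identity.
#' @param angle `"phi"` or `"psi"`.
#' @param value target angle in degrees (absolute, unless `delta`).
#' @param delta if `TRUE`, `value` is added to the current angle.
#' @param movemap optional [MoveMap-class]; an error is raised if the residue
#'   backbone is frozen in it.
#' @return the modified [Pose-class].
#' @export
setBackboneTorsion <- function(pose, tree, chain, resno,
                               angle = c("phi", "psi"), value,
                               delta = FALSE, movemap = NULL) {
  angle <- match.arg(angle)
  rs <- poseResidues(pose)
  i <- which(rs$chain == chain & rs$resno == resno)
  if (length(i) != 1) stop("residue not found")
  uid <- rs$resUid[i]
  if (!is.null(movemap) && !uid %in% movemap@backboneFree)
    stop("residue backbone is frozen in the move map")
  cur <- measureTorsion(pose, chain, resno, angle)
  if (is.na(cur)) stop("torsion undefined at chain terminus")
  rot <- if (delta) value else value - cur
  ms <- torsionMoveSet(pose, tree, uid, angle)
  if (length(ms$moving))
    pose@xyz[ms$moving, ] <- rotateAbout(pose@xyz[ms$moving, , drop = FALSE],
                                         ms$axisPoint, ms$axisDir, rot)
  pose
}

#' Chainbreak deviation at a loop cutpoint
#'
#' Euclidean mismatch between the actual position of the first backbone
#' nitrogen after the cutpoint and its ideal position continued from the
#' residue before the cut with standard peptide geometry (C-N 1.329 A,
#' CA-C-N 116.2 deg). Zero for a perfectly closed loop; invariant under
#' global rigid motion.
#'
#' @param pose a [Pose-class].
#' @param chain,cutResno the cutpoint residue (the cut lies between
#'   `cutResno` and `cutResno + 1`).
#' @return deviation in Angstrom.
#' @export
chainbreakDeviation <- function(pose, chain, cutResno) {
  rs <- poseResidues(pose)
  i <- which(rs$chain == chain & rs$resno == cutResno)
  j <- which(rs$chain == chain & rs$resno == cutResno + 1)
  if (length(i) != 1 || length(j) != 1) stop("cutpoint residues not found")
  bb <- bbIdxOfResidue(pose, rs$resUid[i])
  nb <- bbIdxOfResidue(pose, rs$resUid[j])
  x <- pose@xyz
  psi <- dihedral4(x[bb["N"], ], x[bb["CA"], ], x[bb["C"], ], x[nb["N"], ])
  ideal <- placeAtom(x[bb["N"], ], x[bb["CA"], ], x[bb["C"], ],
                     PEP_C_N, PEP_ANG_CACN, psi)
  vnorm(x[nb["N"], ] - ideal)
}

# Sum of squared chainbreak deviations over a tree's cutpoints.
chainbreakTerm <- function(pose, tree) {
  if (is.null(tree) || !nrow(tree@cutpoints)) return(0)
  s <- 0
  for (i in seq_len(nrow(tree@cutpoints)))
    s <- s + chainbreakDeviation(pose, tree@cutpoints$chain[i],
                                 tree@cutpoints$resno[i])^2
  s
}

# Precomputed torsion DOFs of one loop: for each phi/psi, the axis atom
# index pair (ordered toward the moving side), the moving atom indices and
# the half flag. Indices stay valid as long as the atom layout is unchanged.
loopDofInfo <- function(pose, tree, loopName) {
  lp <- tree@loops[tree@loops$name == loopName, ]
  if (!nrow(lp)) stop("loop ", loopName, " not in fold tree")
  rs <- poseResidues(pose)
  dofTable <- expand.grid(resno = lp$start:lp$stop,
                          angle = c("phi", "psi"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(dofTable)), function(d) {
    resno <- dofTable$resno[d]; angle <- dofTable$angle[d]
    uid <- rs$resUid[rs$chain == lp$chain & rs$resno == resno]
    ms <- torsionMoveSet(pose, tree, uid, angle)
    bb <- bbIdxOfResidue(pose, uid)
    axIdx <- if (ms$forward) {
      if (angle == "phi") c(bb["N"], bb["CA"]) else c(bb["CA"], bb["C"])
    } else {
      if (angle == "psi") c(bb["C"], bb["CA"]) else c(bb["CA"], bb["N"])
    }
    list(axIdx = unname(axIdx), moving = ms$moving, forward = ms$forward,
         resno = resno, angle = angle)
  })
}

#' Construct a move map
#'
#' @param backboneFree residue uids with free phi/psi.
#' @param jumpsFree names of free jumps.
#' @param sidechainFree residue uids with free chi angles.
#' @return a [MoveMap-class].
#' @export
moveMap <- function(backboneFree = integer(), jumpsFree = character(),
                    sidechainFree = integer()) {
  methods::new("MoveMap", backboneFree = as.integer(backboneFree),
               jumpsFree = as.character(jumpsFree),
               sidechainFree = as.integer(sidechainFree))
}
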