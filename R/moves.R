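# Structural perturbation operators: starting-position generators,
# slide-into-contact, rigid-body perturbations, small/shear backbone moves,
# CCD loop closure, composite loop relaxation, ensemble conformer swapping
# and the weighted move selector.

#' Default high-resolution move set
#'
#' Five moves with selection probabilities 40/40/10/5/5 (%): antigen
#' rigid-body perturbation, light-heavy rigid-body perturbation, backbone
#' minimization of all six CDRs, CDR H3 relaxation, CDR H2 relaxation.
#'
#' @return data.frame with columns `name`, `weight`.
#' @export
defaultMoveSet <- function() {
  data.frame(name = c("dock_rb", "vlvh_rb", "cdr_min", "h3_relax", "h2_relax"),
             weight = c(0.40, 0.40, 0.10, 0.05, 0.05),
             stringsAsFactors = FALSE)
}

#' Default perturbation magnitudes
#'
#' Local-start spin is uniform on 0-360 degrees; the tilt and translation of
#' the local start are Gaussian with sigma 8 degrees / 8 Angstrom. The
#' low-resolution antibody perturbation uses 0.7 A / 5 deg; the
#' high-resolution rigid-body perturbations 0.1 A / 3 deg on both jumps.
#' Small/shear move caps are 6 deg (low resolution) and 3 deg (high);
#' each loop relaxation applies 5 small and 5 shear moves then closes the
#' loop by CCD (tolerance 0.15 A, at most 100 sweeps).
#'
#' @return named list of magnitudes.
#' @export
defaultPerturbParams <- function() {
  list(initTransSigma = 8, initTiltSigma = 8,
       lowResTrans = 0.7, lowResRot = 5,
       dockTrans = 0.1, dockRot = 3,
       vlvhTrans = 0.1, vlvhRot = 3,
       smallMaxLow = 6, smallMaxHigh = 3,
       nSmall = 5, nShear = 5,
       ccdTol = 0.15, ccdMaxSweeps = 100,
       globalSmallRot = 10)
}

#' Local starting-position perturbation
#'
#' From a superposition near the bound orientation: spin the antigen
#' uniformly 0-360 degrees about the axis connecting the antibody and
#' antigen centers of mass, tilt it off that axis by a Gaussian draw
#' (sigma = `tiltSigma` degrees) and translate it along the axis by a
#' Gaussian draw (sigma = `transSigma` Angstrom). The antibody is untouched.
#'
#' @param pose a [Pose-class].
#' @param tree the docking [FoldTree-class].
#' @param transSigma,tiltSigma magnitudes (defaults 8 A / 8 deg).
#' @return the perturbed [Pose-class].
#' @export
localPerturbStart <- function(pose, tree, transSigma = 8, tiltSigma = 8) {
  agIdx <- tree@jumps$abag$down
  abIdx <- setdiff(seq_len(nAtoms(pose)), agIdx)
  comAb <- colMeans(pose@xyz[abIdx, , drop = FALSE])
  comAg <- colMeans(pose@xyz[agIdx, , drop = FALSE])
  axis <- comAg - comAb
  if (vnorm(axis) < 1e-6) stop("antibody and antigen centers of mass coincide")
  u <- unitv(axis)
  spin <- stats::runif(1, 0, 360)
  pose@xyz[agIdx, ] <- rotateAbout(pose@xyz[agIdx, , drop = FALSE],
                                   comAb, u, spin)
  # tilt off-axis about a random perpendicular through the antibody center
  perp <- cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  perp <- unitv(perp)
  phi <- stats::runif(1, 0, 360)
  tiltAxis <- as.numeric(rotationMatrix(u, phi) %*% perp)
  tilt <- stats::rnorm(1, 0, tiltSigma)
  pose@xyz[agIdx, ] <- rotateAbout(pose@xyz[agIdx, , drop = FALSE],
                                   comAb, tiltAxis, tilt)
  shift <- stats::rnorm(1, 0, transSigma)
  pose@xyz[agIdx, ] <- sweep(pose@xyz[agIdx, , drop = FALSE], 2, shift * u,
                             FUN = "+")
  pose
}

#' Global starting-position randomization
#'
#' Draws the antigen orientation uniformly over rotations (about its own
#' center of mass), then rotates the antibody so its paratope points toward
#' the antigen center, plus a small random perturbation so the paratope is
#' only generally directed at the antigen.
#'
#' @param pose a [Pose-class].
#' @param tree the docking [FoldTree-class].
#' @param paratope a [ParatopeMap-class].
#' @param smallRotSigma sigma (degrees) of the antibody perturbation.
#' @return the randomized [Pose-class].
#' @export
globalRandomizeStart <- function(pose, tree, paratope, smallRotSigma = 10) {
  agIdx <- tree@jumps$abag$down
  abIdx <- setdiff(seq_len(nAtoms(pose)), agIdx)
  comAg <- colMeans(pose@xyz[agIdx, , drop = FALSE])
  R <- randomRotation()
  pose@xyz[agIdx, ] <- sweep(sweep(pose@xyz[agIdx, , drop = FALSE], 2, comAg)
                             %*% t(R), 2, comAg, FUN = "+")
  # point the paratope-outward axis at the antigen center
  comAb <- colMeans(pose@xyz[abIdx, , drop = FALSE])
  rs <- poseResidues(pose)
  pk <- paste(paratope@paratope$chain, paratope@paratope$resno)
  pu <- rs$resUid[paste(rs$chain, rs$resno) %in% pk]
  pIdx <- which(pose@atoms$resUid %in% pu)
  comPara <- colMeans(pose@xyz[pIdx, , drop = FALSE])
  a <- unitv(comPara - comAb)
  t <- unitv(comAg - comAb)
  ax <- cross3(a, t)
  if (vnorm(ax) > 1e-8) {
    ang <- acos(max(-1, min(1, sum(a * t)))) / DEG
    pose@xyz[abIdx, ] <- rotateAbout(pose@xyz[abIdx, , drop = FALSE],
                                     comAb, ax, ang)
  }
  wob <- stats::rnorm(1, 0, smallRotSigma)
  wobAxis <- unitv(stats::rnorm(3))
  pose@xyz[abIdx, ] <- rotateAbout(pose@xyz[abIdx, , drop = FALSE],
                                   comAb, wobAxis, wob)
  pose
}

# Gap function for slide-into-contact: minimal cross-partner vdW gap when
# the antigen is displaced by t along the centers axis.
slideGap <- function(pose, agIdx, abIdx, u, t) {
  xyz <- pose@xyz
  xyz[agIdx, ] <- sweep(xyz[agIdx, , drop = FALSE], 2, t * u, FUN = "+")
  minGapCpp(xyz, pose@atoms$vdw, !pose@atoms$isHydrogen,
            as.integer(abIdx), as.integer(agIdx))
}

#' Slide the antigen into glancing contact
#'
#' Translates the antigen along the axis of partner centers until the
#' closest antibody-antigen atom pair sits within 1 Angstrom of van der
#' Waals contact (minimal gap d - ri - rj equal to `targetGap`), approaching
#' from the outside; overlapping partners are pushed apart to the same
#' criterion. The contact distance is found by bisection.
#'
#' @param pose a [Pose-class].
#' @param tree the docking [FoldTree-class].
#' @param targetGap gap at glancing contact (default 1.0 A).
#' @param tol bisection tolerance on the gap (A).
#' @return the translated [Pose-class].
#' @export
slideIntoContact <- function(pose, tree, targetGap = 1.0, tol = 0.005) {
  agIdx <- tree@jumps$abag$down
  abIdx <- setdiff(seq_len(nAtoms(pose)), agIdx)
  comAb <- colMeans(pose@xyz[abIdx, , drop = FALSE])
  comAg <- colMeans(pose@xyz[agIdx, , drop = FALSE])
  if (vnorm(comAg - comAb) < 1e-6)
    stop("antibody and antigen centers of mass coincide")
  u <- unitv(comAg - comAb)
  g0 <- slideGap(pose, agIdx, abIdx, u, 0)
  # bracket the root of gap(t) = targetGap with unit steps (exponential
  # stepping could jump across the narrow contact window)
  lo <- 0; hi <- 0
  if (g0 > targetGap) {
    repeat {
      lo <- lo - 1
      if (slideGap(pose, agIdx, abIdx, u, lo) <= targetGap) break
      if (lo < -600) stop("no contact achievable along the centers axis")
    }
    hi <- lo + 1
  } else {
    repeat {
      hi <- hi + 1
      if (slideGap(pose, agIdx, abIdx, u, hi) >= targetGap) break
      if (hi > 600) stop("cannot separate partners along the centers axis")
    }
    lo <- hi - 1
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    g <- slideGap(pose, agIdx, abIdx, u, mid)
    if (g > targetGap) hi <- mid else lo <- mid
    if (abs(g - targetGap) <= tol && g <= targetGap) break
  }
  # lo always satisfies the contact criterion (gap <= targetGap)
  t <- lo
  pose@xyz[agIdx, ] <- sweep(pose@xyz[agIdx, , drop = FALSE], 2, t * u,
                             FUN = "+")
  pose
}

#' Gaussian rigid-body perturbation of a jump
#'
#' Gaussian translation (sigma per axis) plus a Gaussian-magnitude rotation
#' about a uniformly random axis, applied to the jump's downstream body
#' about its center of mass.
#'
#' @param pose a [Pose-class].
#' @param tree a [FoldTree-class].
#' @param jump jump name.
#' @param transSigma,rotSigma magnitudes (Angstrom / degrees).
#' @return the perturbed [Pose-class].
#' @export
rigidBodyPerturb <- function(pose, tree, jump, transSigma, rotSigma) {
  j <- tree@jumps[[jump]]
  if (is.null(j)) stop("no jump named ", jump)
  if (!isTRUE(j$flexible)) stop("jump ", jump, " is frozen in this fold tree")
  t <- stats::rnorm(3, 0, transSigma)
  axis <- unitv(stats::rnorm(3))
  ang <- stats::rnorm(1, 0, rotSigma)
  applyJump(pose, tree, jump, R = rotationMatrix(axis, ang), t = t)
}

#' Small backbone move
#'
#' Perturbs one uniformly chosen phi or psi of a uniformly chosen loop
#' residue by an angle uniform in +/- `maxAngle`; propagation is confined to
#' the loop by the loop fold tree.
#'
#' @param pose a [Pose-class].
#' @param tree a loop [FoldTree-class].
#' @param loopName which loop (`"H3"`, ...).
#' @param maxAngle cap in degrees.
#' @return the perturbed [Pose-class].
#' @export
smallMove <- function(pose, tree, loopName, maxAngle) {
  if (maxAngle == 0) return(pose)
  lp <- tree@loops[tree@loops$name == loopName, ]
  if (!nrow(lp)) stop("loop ", loopName, " not in fold tree")
  resno <- sample(lp$start:lp$stop, 1)
  angle <- sample(c("phi", "psi"), 1)
  delta <- stats::runif(1, -maxAngle, maxAngle)
  setBackboneTorsion(pose, tree, lp$chain, resno, angle, delta, delta = TRUE)
}

#' Shear backbone move
#'
#' Compensating pair: phi of residue i changes by +delta and psi of residue
#' i-1 by -delta, limiting the lever-arm propagation of the perturbation.
#'
#' @inheritParams smallMove
#' @param delta optional fixed delta (degrees); drawn uniform in
#'   +/- `maxAngle` when missing.
#' @return the perturbed [Pose-class].
#' @export
shearMove <- function(pose, tree, loopName, maxAngle, delta = NULL) {
  lp <- tree@loops[tree@loops$name == loopName, ]
  if (!nrow(lp)) stop("loop ", loopName, " not in fold tree")
  if (is.null(delta)) delta <- stats::runif(1, -maxAngle, maxAngle)
  if (delta == 0) return(pose)
  resno <- if (lp$stop > lp$start + 1) sample((lp$start + 1):lp$stop, 1)
           else lp$stop
  pose <- setBackboneTorsion(pose, tree, lp$chain, resno, "phi", delta,
                             delta = TRUE)
  setBackboneTorsion(pose, tree, lp$chain, resno - 1, "psi", -delta,
                     delta = TRUE)
}

# Virtual overlap atoms across a cutpoint, built with ideal peptide
# geometry: OVL1/OVL2 extend the N-terminal half past the cut (ideal N and
# CA of residue cut+1), OVU1 extends the C-terminal half backward (ideal C
# of residue cut). Perfect closure superposes them onto their real
# counterparts.
ccdVirtuals <- function(xyz, ct) {
  psi <- dihedral4(xyz[ct["N"], ], xyz[ct["CA"], ], xyz[ct["C"], ],
                   xyz[ct["Nn"], ])
  ovl1 <- placeAtom(xyz[ct["N"], ], xyz[ct["CA"], ], xyz[ct["C"], ],
                    PEP_C_N, PEP_ANG_CACN, psi)
  ovl2 <- placeAtom(xyz[ct["CA"], ], xyz[ct["C"], ], ovl1,
                    PEP_N_CA, PEP_ANG_CNCA, 180)
  phi <- dihedral4(xyz[ct["Cn"], ], xyz[ct["CAn"], ], xyz[ct["Nn"], ],
                   xyz[ct["C"], ])
  ovu1 <- placeAtom(xyz[ct["Cn"], ], xyz[ct["CAn"], ], xyz[ct["Nn"], ],
                    PEP_C_N, PEP_ANG_CNCA, phi)
  list(ovl1 = ovl1, ovl2 = ovl2, ovu1 = ovu1)
}

# Analytic single-torsion CCD update: the rotation angle about (o, u)
# minimizing sum_k |R(theta)(m_k) - f_k|^2.
ccdAngle <- function(M, F, o, u) {
  u <- unitv(u)
  a <- 0; b <- 0
  for (k in seq_len(nrow(M))) {
    m <- M[k, ]; f <- F[k, ]
    ck <- o + sum((m - o) * u) * u
    r <- m - ck
    s <- vnorm(r)
    if (s < 1e-9) next
    rh <- r / s
    th <- cross3(u, rh)
    fv <- f - ck
    a <- a + s * sum(fv * rh)
    b <- b + s * sum(fv * th)
  }
  if (a == 0 && b == 0) 0 else atan2(b, a) / DEG
}

#' Close a cut loop by cyclic coordinate descent
#'
#' Iterates over the loop's phi/psi torsions; each single-torsion update
#' analytically minimizes the squared distance between the three anchor-atom
#' pairs across the cut (real and ideal-geometry N/CA/C overlap positions),
#' so each update is monotone in the closure objective. Stops when the
#' chainbreak deviation drops to `tol` or after `maxSweeps` sweeps.
#'
#' @param pose a [Pose-class].
#' @param tree a loop [FoldTree-class].
#' @param loopName which loop to close.
#' @param maxSweeps sweep cap (default 100).
#' @param tol chainbreak deviation target in Angstrom (default 0.15).
#' @return list with `pose`, `converged`, `sweeps`, `deviation`.
#' @export
ccdClose <- function(pose, tree, loopName, maxSweeps = 100, tol = 0.15) {
  lp <- tree@loops[tree@loops$name == loopName, ]
  if (!nrow(lp)) stop("loop ", loopName, " not in fold tree")
  rs <- poseResidues(pose)
  cutUid <- lp$uidCut
  bbC <- bbIdxOfResidue(pose, cutUid)
  bbN <- bbIdxOfResidue(pose, cutUid + 1L)
  ct <- c(N = unname(bbC["N"]), CA = unname(bbC["CA"]), C = unname(bbC["C"]),
          Nn = unname(bbN["N"]), CAn = unname(bbN["CA"]), Cn = unname(bbN["C"]))

  dev <- chainbreakDeviation(pose, lp$chain, lp$cutpoint)
  if (dev <= tol)
    return(list(pose = pose, converged = TRUE, sweeps = 0L, deviation = dev))

  # precompute the static part of every torsion DOF (indices never change)
  dofs <- loopDofInfo(pose, tree, loopName)
  res <- ccdRunCpp(pose@xyz,
                   do.call(rbind, lapply(dofs, function(d) d$axIdx)),
                   lapply(dofs, function(d) as.integer(d$moving)),
                   vapply(dofs, function(d) d$forward, TRUE),
                   as.integer(ct), as.integer(maxSweeps), tol,
                   PEP_C_N, PEP_ANG_CACN, PEP_ANG_CNCA, PEP_N_CA)
  pose@xyz <- res$xyz
  list(pose = pose, converged = res$converged, sweeps = res$sweeps,
       deviation = res$deviation)
}

#' Composite loop relaxation
#'
#' Applies `nSmall` small and `nShear` shear moves, closes the loop by CCD,
#' and minimizes the loop torsions (objective includes the chainbreak
#' penalty, keeping the loop closed). Used for CDR H2/H3 in both the
#' centroid and full-atom stages; the light-heavy jump is frozen by the loop
#' fold tree throughout.
#'
#' @param pose a [Pose-class].
#' @param tree a loop [FoldTree-class] containing the loop.
#' @param loopName loop to relax.
#' @param weights a [ScoreWeights-class].
#' @param maxAngle small/shear cap (degrees).
#' @param nSmall,nShear move counts.
#' @param ccdTol,ccdMaxSweeps CCD settings.
#' @param minimize run the torsion minimization after closure?
#' @param minMaxEval evaluation budget of that minimization.
#' @return the relaxed [Pose-class].
#' @export
loopRelax <- function(pose, tree, loopName, weights = scoreWeights(),
                      maxAngle = 3, nSmall = 5, nShear = 5, ccdTol = 0.15,
                      ccdMaxSweeps = 100, minimize = TRUE, minMaxEval = 150) {
  for (i in seq_len(nSmall)) pose <- smallMove(pose, tree, loopName, maxAngle)
  for (i in seq_len(nShear)) pose <- shearMove(pose, tree, loopName, maxAngle)
  pose <- ccdClose(pose, tree, loopName, maxSweeps = ccdMaxSweeps,
                   tol = ccdTol)$pose
  if (minimize) {
    lp <- tree@loops[tree@loops$name == loopName, ]
    uids <- lp$uidStart:lp$uidStop
    mm <- moveMap(backboneFree = uids)
    pose <- minimizeDof(pose, tree, mm, weights, cbTree = tree,
                        maxEval = minMaxEval)
  }
  pose
}

#' Monte Carlo conformer swap from an ensemble
#'
#' Selects a random ensemble member, superposes its antibody onto the
#' current antibody placement (backbone least-squares fit) and replaces the
#' antibody coordinates; the swap is accepted or rejected by the Metropolis
#' criterion on the score change. The antigen is untouched.
#'
#' @param pose the current [Pose-class] (antibody + antigen).
#' @param ensemble list of antibody [Pose-class] objects sharing the current
#'   antibody's chain/residue/atom layout and resolution.
#' @param tree the docking [FoldTree-class].
#' @param weights a [ScoreWeights-class].
#' @param kT Metropolis temperature.
#' @return the (possibly) swapped [Pose-class]; attribute `"member"` holds
#'   the accepted member index (`NA` when the swap was rejected).
#' @export
conformerSwap <- function(pose, ensemble, tree, weights = scoreWeights(),
                          kT = 0.8) {
  stopifnot(length(ensemble) >= 1)
  pick <- sample.int(length(ensemble), 1)
  memb <- ensemble[[pick]]
  abIdx <- sort(c(groupAtomIdx(pose, "light"), groupAtomIdx(pose, "heavy")))
  a <- pose@atoms[abIdx, ]
  b <- memb@atoms
  if (nrow(b) != length(abIdx) ||
      !all(a$elety == b$elety & a$resno == b$resno & a$chain == b$chain))
    stop("ensemble member layout does not match the current antibody")
  bbCur <- abIdx[a$isBackbone]
  bbMem <- which(b$isBackbone)
  fit <- kabsch(memb@xyz[bbMem, , drop = FALSE],
                pose@xyz[bbCur, , drop = FALSE])
  trial <- pose
  trial@xyz[abIdx, ] <- applyFit(memb@xyz, fit)
  st <- poseStatic(pose)
  dE <- scoreFast(trial@xyz, st, weights)$total -
    scoreFast(pose@xyz, st, weights)$total
  if (metropolisAccept(dE, kT)) {
    attr(trial, "member") <- pick
    trial
  } else {
    attr(pose, "member") <- NA_integer_
    pose
  }
}

#' Weighted move selection
#'
#' Categorical draw from the move set by selection weight.
#'
#' @param moveSet data.frame with `name` and `weight` (weights need not be
#'   normalized but must not all be zero).
#' @param n number of draws.
#' @return character vector of move names.
#' @export
selectMove <- function(moveSet, n = 1) {
  w <- moveSet$weight
  if (any(w < 0) || sum(w) <= 0) stop("move weights must be >= 0, not all zero")
  moveSet$name[sample.int(nrow(moveSet), n, replace = TRUE, prob = w)]
}
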