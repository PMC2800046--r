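# Programmatic toy fixtures: idealized antibody-like complexes, homology-
# model mimics with calibrated CDR error, ensembles, and rigid-body decoy
# clouds with known ground truth. Chains are poly-alanine/glycine with a few
# long side chains so packing and electrostatics have something to do;
# realism is not the goal -- exercising every code path deterministically is.

#' Fixture specification
#'
#' @param nRes named residue counts `c(light=, heavy=, antigen=)`.
#' @param loops CDR loop ranges (list usable by [loadLoopDefinitions()]);
#'   the default places the six loops in the upper half of the two helical
#'   framework chains with an 8-residue H3.
#' @param homologyError target per-loop backbone rmsd (Angstrom) of the
#'   homology mimic; a named vector per loop is allowed.
#' @param vlvhTrans,vlvhRot light-heavy jump perturbation of the mimic
#'   (Angstrom / degrees).
#' @param ensembleSize ensemble draws for [makeHomologyMimic()].
#' @param seed fixture seed; generation is a pure function of spec + seed.
#' @return a list spec.
#' @export
fixtureSpec <- function(nRes = c(light = 20, heavy = 24, antigen = 10),
                        loops = NULL, homologyError = 2, vlvhTrans = 0.5,
                        vlvhRot = 3, ensembleSize = 10, seed = 42) {
  if (is.null(loops)) {
    loops <- list(
      list(name = "L1", chain = "light", start = 8, stop = 11),
      list(name = "L2", chain = "light", start = 13, stop = 15),
      list(name = "L3", chain = "light", start = 17, stop = 19),
      list(name = "H1", chain = "heavy", start = 8, stop = 10),
      list(name = "H2", chain = "heavy", start = 12, stop = 14),
      list(name = "H3", chain = "heavy", start = 16, stop = 23)
    )
  }
  h3 <- Filter(function(l) l$name == "H3", loops)[[1]]
  h3len <- h3$stop - h3$start + 1
  if (h3len < 7 || h3len > 11)
    warning("H3 length ", h3len, " outside the default 7-11 fixture range")
  if (sum(nRes) > 60) stop("fixture too large for a desk-scale test (> 60 residues)")
  list(nRes = nRes, loops = loops, homologyError = homologyError,
       vlvhTrans = vlvhTrans, vlvhRot = vlvhRot,
       ensembleSize = ensembleSize, seed = seed)
}

# Default toy sequences: ALA background, one GLY and a few rotatable/charged
# residues per chain.
fixtureSequence <- function(n, role) {
  seqs <- rep("ALA", n)
  put <- function(pos, what) {
    pos <- pos[pos <= n]
    seqs[pos] <<- what[seq_along(pos)]
  }
  if (role == "light") {
    put(c(9, 14, 18), c("LYS", "SER", "LEU")); put(11, "GLY")
  } else if (role == "heavy") {
    put(c(13, 18, 22), c("SER", "LYS", "LEU")); put(20, "GLY")
  } else {
    put(c(3, 5, 7), c("LYS", "GLU", "LEU")); put(4, "GLY")
  }
  seqs
}

# Build one chain from phi/psi sequences with ideal geometry; returns the
# atom table and coordinates (backbone N/CA/C/O + template side chains).
buildChainAtoms <- function(resnames, phis, psis, chain) {
  n <- length(resnames)
  stopifnot(length(phis) == n, length(psis) == n)
  bbN <- bbCA <- bbC <- vector("list", n)
  bbN[[1]] <- c(0, 0, 0)
  bbCA[[1]] <- c(PEP_N_CA, 0, 0)
  bbC[[1]] <- placeAtom(c(0, -1, 0), bbN[[1]], bbCA[[1]], 1.525, 111.2, 150)
  for (i in 2:n) {
    bbN[[i]] <- placeAtom(bbN[[i - 1]], bbCA[[i - 1]], bbC[[i - 1]],
                          PEP_C_N, PEP_ANG_CACN, psis[i - 1])
    bbCA[[i]] <- placeAtom(bbCA[[i - 1]], bbC[[i - 1]], bbN[[i]],
                           PEP_N_CA, PEP_ANG_CNCA, 180)
    bbC[[i]] <- placeAtom(bbC[[i - 1]], bbN[[i]], bbCA[[i]],
                          1.525, 111.2, phis[i])
  }
  rows <- list(); coords <- list()
  for (i in seq_len(n)) {
    psiO <- if (i < n) psis[i] else -47
    O <- placeAtom(bbN[[i]], bbCA[[i]], bbC[[i]], 1.231, 120.1, psiO + 180)
    sc <- buildSidechain(resnames[i], bbN[[i]], bbCA[[i]], bbC[[i]])
    names <- c("N", "CA", "C", "O", rownames(sc))
    rows[[i]] <- data.frame(chain = chain, resno = i, insert = "",
                            resid = resnames[i], elety = names,
                            element = elementFromName(names), occ = 1,
                            stringsAsFactors = FALSE)
    coords[[i]] <- rbind(bbN[[i]], bbCA[[i]], bbC[[i]], O, sc)
  }
  list(atoms = do.call(rbind, rows), xyz = do.call(rbind, coords))
}

# Rotate/translate a coordinate block so the first->last CA axis lies along
# +z with the first CA at `origin`.
alignChain <- function(blk, origin = c(0, 0, 0)) {
  ca <- which(blk$atoms$elety == "CA")
  axis <- blk$xyz[ca[length(ca)], ] - blk$xyz[ca[1], ]
  u <- unitv(axis); z <- c(0, 0, 1)
  ax <- cross3(u, z)
  if (vnorm(ax) > 1e-9) {
    ang <- acos(max(-1, min(1, sum(u * z)))) / DEG
    blk$xyz <- rotateAbout(blk$xyz, blk$xyz[ca[1], ], ax, ang)
  }
  blk$xyz <- sweep(blk$xyz, 2, blk$xyz[ca[1], ] - origin)
  blk
}

#' Generate a toy antibody-antigen complex
#'
#' Three idealized chains: two packed helical "framework" chains (light L,
#' heavy H) whose designated CDR stretches form the paratope, and a short
#' helical antigen (A) slid into contact against the paratope with at least
#' five cross-partner residue contacts at the 5 Angstrom criterion.
#'
#' @param spec a [fixtureSpec()].
#' @return the native complex [Pose-class] (full-atom).
#' @export
makeToyComplex <- function(spec = fixtureSpec()) {
  set.seed(spec$seed)
  helix <- function(n) list(phi = rep(-57, n), psi = rep(-47, n))
  nL <- spec$nRes[["light"]]; nH <- spec$nRes[["heavy"]]
  nA <- spec$nRes[["antigen"]]
  hL <- helix(nL); hH <- helix(nH); hA <- helix(nA)
  light <- alignChain(buildChainAtoms(fixtureSequence(nL, "light"),
                                      hL$phi, hL$psi, "L"))
  heavy <- alignChain(buildChainAtoms(fixtureSequence(nH, "heavy"),
                                      hH$phi, hH$psi, "H"),
                      origin = c(10.5, 0, 0))
  antigen <- alignChain(buildChainAtoms(fixtureSequence(nA, "antigen"),
                                        hA$phi, hA$psi, "A"))
  # splay the two framework helices into a V that opens toward the CDR end
  # (high z): the paratope becomes a concave cup that narrows below the
  # antigen seat, so the native site is the maximal-contact placement
  light$xyz <- rotateAbout(light$xyz, c(0, 0, 0), c(0, 1, 0), -12)
  heavy$xyz <- rotateAbout(heavy$xyz, c(10.5, 0, 0), c(0, 1, 0), 12)

  pose <- newPose(rbind(light$atoms, heavy$atoms),
                  rbind(light$xyz, heavy$xyz), "fullatom",
                  c(L = "light", H = "heavy"))
  paratope <- loadLoopDefinitions(spec$loops, pose)

  # approach direction: antibody center -> paratope centroid
  rs <- poseResidues(pose)
  pk <- paste(paratope@paratope$chain, paratope@paratope$resno)
  pIdx <- which(pose@atoms$resUid %in% rs$resUid[paste(rs$chain, rs$resno) %in% pk])
  comAb <- colMeans(pose@xyz)
  comPara <- colMeans(pose@xyz[pIdx, , drop = FALSE])
  dir <- unitv(comPara - comAb)

  # lay the antigen across the V cup, axis along the groove line (roughly
  # y), so the native placement touches both walls along its full length --
  # the maximal-contact site of the concave paratope
  agCa <- which(antigen$atoms$elety == "CA")
  agAxis <- unitv(antigen$xyz[agCa[length(agCa)], ] - antigen$xyz[agCa[1], ])
  groove <- unitv(cross3(dir, c(1, 0, 0)))
  ax <- cross3(agAxis, groove)
  if (vnorm(ax) > 1e-9) {
    ang <- acos(max(-1, min(1, sum(agAxis * groove)))) / DEG
    antigen$xyz <- rotateAbout(antigen$xyz, colMeans(antigen$xyz), ax, ang)
  }
  antigen$xyz <- sweep(antigen$xyz, 2,
                       comPara + 12 * dir - colMeans(antigen$xyz), FUN = "+")

  full <- newPose(rbind(light$atoms, heavy$atoms, antigen$atoms),
                  rbind(light$xyz, heavy$xyz, antigen$xyz), "fullatom",
                  c(L = "light", H = "heavy", A = "antigen"))
  # seat the antigen: slide to glancing contact, then relax the rigid-body
  # placement so the native complex sits at an energy minimum of the
  # concave paratope site (as a native structure should)
  tree <- buildDockingFoldTree(full)
  # settle the light-heavy packing first so the Fv itself is at an energy
  # minimum, then seat the antigen
  full <- minimizeDof(full, tree, moveMap(jumpsFree = "vlvh"),
                      scoreWeights(), maxSweeps = 100, maxEval = 1500)
  for (gap in seq(0.75, -0.5, by = -0.25)) {
    cand <- slideIntoContact(full, tree, targetGap = gap)
    cand <- minimizeDof(cand, tree, moveMap(jumpsFree = "abag"),
                        scoreWeights(), maxSweeps = 100, maxEval = 1500)
    cand <- minimizeDof(cand, tree, moveMap(jumpsFree = "vlvh"),
                        scoreWeights(), maxSweeps = 100, maxEval = 1000)
    cand <- minimizeDof(cand, tree, moveMap(jumpsFree = "abag"),
                        scoreWeights(), maxSweeps = 100, maxEval = 1000)
    if (nrow(contactPairs(cand, 5)) >= 5) return(cand)
  }
  stop("infeasible fixture spec: fewer than 5 native contacts achievable")
}

#' Paratope map of a fixture complex
#'
#' Convenience wrapper: the loop definitions of `spec` resolved against a
#' pose generated from it.
#'
#' @param pose a [Pose-class] from [makeToyComplex()].
#' @param spec the [fixtureSpec()] that generated it.
#' @return a [ParatopeMap-class].
#' @export
fixtureParatope <- function(pose, spec = fixtureSpec()) {
  loadLoopDefinitions(spec$loops, pose)
}

# Perturb one loop's torsions by mag * unit draws (precomputed DOF info),
# re-close by CCD, return loop backbone rmsd to the reference coordinates.
perturbLoopOnce <- function(ab, tree, lprow, dofs, u, mag, refXyz, ccdTol) {
  pose <- ab
  for (k in seq_along(dofs)) {
    d <- dofs[[k]]
    if (!length(d$moving)) next
    p <- pose@xyz[d$axIdx[1], ]
    pose@xyz[d$moving, ] <- rotateAbout(pose@xyz[d$moving, , drop = FALSE],
                                        p, pose@xyz[d$axIdx[2], ] - p,
                                        mag * u[k])
  }
  pose <- ccdClose(pose, tree, lprow$name, tol = ccdTol)$pose
  span <- which(pose@atoms$resUid %in% (lprow$uidStart:lprow$uidStop) &
                  pose@atoms$isBackbone)
  list(pose = pose, rmsd = rmsdCoords(pose@xyz[span, , drop = FALSE],
                                      refXyz[span, , drop = FALSE]))
}

#' Homology-model mimic of a fixture antibody
#'
#' Emulates the error structure of an antibody homology model: each CDR's
#' torsions are perturbed and the loop re-closed by CCD, with the
#' perturbation magnitude calibrated by bisection until the loop's backbone
#' rmsd to the native lies within 20 percent of the requested error; the
#' light-heavy orientation is then jittered by a rigid jump perturbation.
#' Loops for which the target rmsd is unreachable (e.g. very short loops)
#' are returned best-effort with a warning.
#'
#' @param native the native complex from [makeToyComplex()].
#' @param spec the [fixtureSpec()] (fields `homologyError`, `vlvhTrans`,
#'   `vlvhRot`, `ensembleSize`, `seed`).
#' @return list with `antibody` (the mimic [Pose-class], light + heavy) and
#'   `ensemble` (list of `ensembleSize` independent mimics; the first one is
#'   `antibody`).
#' @export
makeHomologyMimic <- function(native, spec = fixtureSpec()) {
  set.seed(spec$seed + 1)
  ab0 <- subsetPose(native, c("light", "heavy"))
  paratope <- loadLoopDefinitions(spec$loops, ab0)
  tree <- buildLoopFoldTree(ab0, paratope, allowVlVh = FALSE)
  err <- spec$homologyError
  errOf <- function(nm) if (length(err) > 1) unname(err[nm]) else unname(err)

  dofsByLoop <- lapply(tree@loops$name, function(nm) loopDofInfo(ab0, tree, nm))
  names(dofsByLoop) <- tree@loops$name

  oneDraw <- function() {
    ab <- ab0
    for (i in seq_len(nrow(tree@loops))) {
      lprow <- tree@loops[i, ]
      target <- errOf(lprow$name)
      if (is.na(target) || target <= 0) next
      dofs <- dofsByLoop[[lprow$name]]
      u <- stats::rnorm(length(dofs))
      f <- function(mag) perturbLoopOnce(ab, tree, lprow, dofs, u, mag,
                                         ab0@xyz, 0.1)
      lo <- 0; hi <- 10
      res <- f(hi)
      tries <- 0
      while (res$rmsd < target && hi < 160 && tries < 6) {
        hi <- hi * 2; res <- f(hi); tries <- tries + 1
      }
      best <- res
      for (it in 1:20) {
        mid <- (lo + hi) / 2
        res <- f(mid)
        if (abs(res$rmsd - target) < abs(best$rmsd - target)) best <- res
        if (abs(res$rmsd - target) <= 0.2 * target) { best <- res; break }
        if (res$rmsd > target) hi <- mid else lo <- mid
      }
      if (abs(best$rmsd - target) > 0.2 * target)
        warning(sprintf("loop %s: reached %.2f A instead of %.2f A (best effort)",
                        lprow$name, best$rmsd, target))
      ab <- best$pose
    }
    # light-heavy orientation jitter
    if (spec$vlvhRot > 0 || spec$vlvhTrans > 0) {
      hIdx <- groupAtomIdx(ab, "heavy")
      com <- colMeans(ab@xyz[hIdx, , drop = FALSE])
      R <- rotationMatrix(unitv(stats::rnorm(3)),
                          stats::rnorm(1, 0, spec$vlvhRot))
      t <- stats::rnorm(3, 0, spec$vlvhTrans)
      X <- sweep(ab@xyz[hIdx, , drop = FALSE], 2, com)
      ab@xyz[hIdx, ] <- sweep(X %*% t(R), 2, com + t, FUN = "+")
    }
    ab
  }
  ensemble <- lapply(seq_len(max(1, spec$ensembleSize)), function(i) oneDraw())
  list(antibody = ensemble[[1]], ensemble = ensemble)
}

#' Rigid-body decoy cloud with known ground truth
#'
#' `n` copies of the native with the antigen displaced by a uniform random
#' direction and a distance uniform in (0, `magnitude`], plus an optional
#' Gaussian rotation about the antigen center. For pure translations the
#' ligand rmsd of each decoy equals its displacement exactly.
#'
#' @param native the native complex [Pose-class].
#' @param n number of decoys.
#' @param magnitude maximal displacement (Angstrom).
#' @param rotSigma rotation sigma in degrees (default 0: pure translations).
#' @param seed RNG seed.
#' @return list of [Pose-class] decoys; attribute `"displacement"` carries
#'   the drawn translation norms.
#' @export
makeDecoyCloud <- function(native, n = 100, magnitude = 20, rotSigma = 0,
                           seed = 1) {
  set.seed(seed)
  agIdx <- groupAtomIdx(native, "antigen")
  out <- vector("list", n)
  disp <- numeric(n)
  for (i in seq_len(n)) {
    p <- native
    d <- if (magnitude > 0) stats::runif(1, 0, magnitude) else 0
    dir <- unitv(stats::rnorm(3))
    if (rotSigma > 0) {
      com <- colMeans(p@xyz[agIdx, , drop = FALSE])
      p@xyz[agIdx, ] <- rotateAbout(p@xyz[agIdx, , drop = FALSE], com,
                                    unitv(stats::rnorm(3)),
                                    stats::rnorm(1, 0, rotSigma))
    }
    p@xyz[agIdx, ] <- sweep(p@xyz[agIdx, , drop = FALSE], 2, d * dir,
                            FUN = "+")
    disp[i] <- d
    out[[i]] <- p
  }
  attr(out, "displacement") <- disp
  out
}
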