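# Scoring, Metropolis acceptance, isolated-DOF minimization and side-chain
# packing.
#
# The score is a transparent docking energy: per heavy-atom pair within a
# 12 A cutoff, a soft-sphere repulsion max(0, (rsum-d)/rsum)^2, a Gaussian
# contact well -exp(-(d-rsum)^2/(2 sigma^2)) with sigma = 1.5 A, and Coulomb
# electrostatics with distance-dependent dielectric (eps = 4d) on charged
# side-chain tips. Pairs are bucketed by partner group: intra-group pairs
# feed the three base terms, light<->heavy pairs the `interchain_vl_vh` term
# and antibody<->antigen pairs the `interchain_ab_ag` term (each interchain
# term is the weight-combined pair energy over its cross pairs). Loop
# cutpoints add a quadratic chainbreak penalty. The interface energy used to
# rank decoys is the weighted antibody-antigen interchain component, so it
# equals score(complex) - score(partners separated) with internal degrees of
# freedom frozen, and is exactly 0 for separated partners.

#' Score weights constructor
#'
#' @param vdw_repulsive,contact_attractive,electrostatic,chainbreak,interchain_ab_ag,interchain_vl_vh
#'   term weights.
#' @param sigma contact-well width in Angstrom.
#' @param cutoff pair cutoff in Angstrom.
#' @return a [ScoreWeights-class].
#' @export
scoreWeights <- function(vdw_repulsive = 100, contact_attractive = 0.5,
                         electrostatic = 0.25, chainbreak = 10,
                         interchain_ab_ag = 1, interchain_vl_vh = 1,
                         sigma = 1.5, cutoff = 12) {
  methods::new("ScoreWeights",
               weights = c(vdw_repulsive = vdw_repulsive,
                           contact_attractive = contact_attractive,
                           electrostatic = electrostatic,
                           chainbreak = chainbreak,
                           interchain_ab_ag = interchain_ab_ag,
                           interchain_vl_vh = interchain_vl_vh),
               sigma = sigma, cutoff = cutoff)
}

# Precomputed static per-atom vectors and cutpoint atom indices for the fast
# scoring path (valid as long as the pose's atom layout is unchanged).
poseStatic <- function(pose, tree = NULL) {
  a <- pose@atoms
  cuts <- NULL
  if (!is.null(tree) && nrow(tree@cutpoints)) {
    cuts <- lapply(seq_len(nrow(tree@cutpoints)), function(i) {
      rs <- poseResidues(pose)
      ci <- which(rs$chain == tree@cutpoints$chain[i] &
                    rs$resno == tree@cutpoints$resno[i])
      ni <- which(rs$chain == tree@cutpoints$chain[i] &
                    rs$resno == tree@cutpoints$resno[i] + 1)
      bb <- bbIdxOfResidue(pose, rs$resUid[ci])
      nb <- bbIdxOfResidue(pose, rs$resUid[ni])
      c(N = unname(bb["N"]), CA = unname(bb["CA"]), C = unname(bb["C"]),
        Nn = unname(nb["N"]))
    })
  }
  list(vdw = a$vdw, charge = a$charge, group = a$group, resUid = a$resUid,
       resno = a$resno, chainIdx = a$chainIdx, heavy = !a$isHydrogen,
       cuts = if (is.null(cuts)) NULL else do.call(rbind, cuts))
}

cbTermFast <- function(xyz, cuts) {
  if (is.null(cuts)) return(0)
  cbTermCpp(xyz, cuts, PEP_C_N, PEP_ANG_CACN)
}

# weighted total from a raw 9-term pair sum plus a chainbreak value
rawTotal <- function(raw, cb, w) {
  comb <- function(pre) {
    w[["vdw_repulsive"]] * raw[[paste0("rep_", pre)]] +
      w[["contact_attractive"]] * raw[[paste0("att_", pre)]] +
      w[["electrostatic"]] * raw[[paste0("elec_", pre)]]
  }
  comb("intra") + w[["chainbreak"]] * cb +
    w[["interchain_ab_ag"]] * comb("abag") +
    w[["interchain_vl_vh"]] * comb("vlvh")
}

# flattened 9-term weight vector matching the kernel's output order
weights9 <- function(sw) {
  w <- sw@weights
  b <- c(w[["vdw_repulsive"]], w[["contact_attractive"]],
         w[["electrostatic"]])
  unname(c(b, b * w[["interchain_vl_vh"]], b * w[["interchain_ab_ag"]]))
}

# incremental objective change when only the atoms in `idx` moved rigidly
subTotal <- function(xyz, st, sw, idx, wv9 = weights9(sw)) {
  sum(subsetTermsCpp(xyz, st$vdw, st$charge, st$group, st$resUid, st$resno,
                     st$chainIdx, st$heavy, sw@cutoff, sw@sigma, idx) * wv9)
}

scoreFast <- function(xyz, st, sw) {
  raw <- pairTermsCpp(xyz, st$vdw, st$charge, st$group, st$resUid, st$resno,
                      st$chainIdx, st$heavy, sw@cutoff, sw@sigma)
  w <- sw@weights
  comb <- function(pre) {
    w[["vdw_repulsive"]] * raw[[paste0("rep_", pre)]] +
      w[["contact_attractive"]] * raw[[paste0("att_", pre)]] +
      w[["electrostatic"]] * raw[[paste0("elec_", pre)]]
  }
  terms <- c(vdw_repulsive = raw[["rep_intra"]],
             contact_attractive = raw[["att_intra"]],
             electrostatic = raw[["elec_intra"]],
             chainbreak = cbTermFast(xyz, st$cuts),
             interchain_ab_ag = comb("abag"),
             interchain_vl_vh = comb("vlvh"))
  total <- sum(w[names(terms)] * terms)
  list(total = total, terms = terms,
       interface = w[["interchain_ab_ag"]] * terms[["interchain_ab_ag"]])
}

#' Score a pose
#'
#' @param pose a [Pose-class] (either resolution; centroid poses score their
#'   pseudo-atoms with a 2.0 A radius).
#' @param weights a [ScoreWeights-class].
#' @param tree optional loop [FoldTree-class]; its cutpoints contribute the
#'   chainbreak term.
#' @return an [EnergyReport-class].
#' @export
scorePose <- function(pose, weights = scoreWeights(), tree = NULL) {
  if (any(!is.finite(pose@xyz))) stop("pose has non-finite coordinates")
  st <- poseStatic(pose, tree)
  s <- scoreFast(pose@xyz, st, weights)
  methods::new("EnergyReport", total = s$total, terms = s$terms,
               interfaceEnergy = unname(s$interface))
}

#' Metropolis acceptance criterion
#'
#' Accept if the energy change is non-positive, otherwise with probability
#' `exp(-deltaE / kT)`. Default temperature kT = 0.8 score units.
#'
#' @param deltaE energy change (score units).
#' @param kT temperature (score units), must be > 0.
#' @return logical.
#' @export
metropolisAccept <- function(deltaE, kT = 0.8) {
  if (kT <= 0) stop("kT must be > 0")
  if (is.na(deltaE)) return(FALSE)
  if (deltaE <= 0) return(TRUE)
  stats::runif(1) < exp(-deltaE / kT)
}

# Closures applying +delta to one degree of freedom of a coordinate matrix.
jumpDofs <- function(tree, jump) {
  idx <- tree@jumps[[jump]]$down
  mk <- function(kind, k) {
    force(kind); force(k)
    function(xyz, delta) {
      if (kind == "t") {
        xyz[idx, k] <- xyz[idx, k] + delta
      } else {
        com <- colMeans(xyz[idx, , drop = FALSE])
        ax <- c(0, 0, 0); ax[k] <- 1
        xyz[idx, ] <- rotateAbout(xyz[idx, , drop = FALSE], com, ax, delta)
      }
      xyz
    }
  }
  list(
    list(apply = mk("t", 1), step = 0.2, moving = idx),
    list(apply = mk("t", 2), step = 0.2, moving = idx),
    list(apply = mk("t", 3), step = 0.2, moving = idx),
    list(apply = mk("r", 1), step = 1, moving = idx),
    list(apply = mk("r", 2), step = 1, moving = idx),
    list(apply = mk("r", 3), step = 1, moving = idx)
  )
}

torsionDofs <- function(pose, tree, uids) {
  dofs <- list()
  for (uid in uids) {
    lp <- loopOfResidue(tree, uid)
    if (is.null(lp)) next
    for (angle in c("phi", "psi")) {
      ms <- try(torsionMoveSet(pose, tree, uid, angle), silent = TRUE)
      if (inherits(ms, "try-error") || !length(ms$moving)) next
      bb <- bbIdxOfResidue(pose, uid)
      axIdx <- if (ms$forward) {
        if (angle == "phi") c(bb["N"], bb["CA"]) else c(bb["CA"], bb["C"])
      } else {
        if (angle == "psi") c(bb["C"], bb["CA"]) else c(bb["CA"], bb["N"])
      }
      mov <- ms$moving
      mkf <- local({
        ai <- axIdx; mv <- mov
        function(xyz, delta) {
          p <- xyz[ai[1], ]
          xyz[mv, ] <- rotateAbout(xyz[mv, , drop = FALSE], p,
                                   xyz[ai[2], ] - p, delta)
          xyz
        }
      })
      dofs[[length(dofs) + 1]] <- list(apply = mkf, step = 2, moving = mov)
    }
  }
  dofs
}

#' Minimize one isolated degree-of-freedom set
#'
#' Derivative-free coordinate descent with adaptive step halving over the
#' degrees of freedom selected by the move map: either one jump (6 rigid-body
#' DOFs) or a set of loop backbone torsions. The objective (the weighted
#' total score including the chainbreak penalty) never increases; frozen
#' degrees of freedom are untouched. Multiple rounds over one isolated DOF
#' set at a time sample better and run faster than simultaneous minimization
#' of everything.
#'
#' @param pose a [Pose-class].
#' @param tree the [FoldTree-class] the move map refers to.
#' @param movemap a [MoveMap-class] selecting one jump or a torsion set.
#' @param weights a [ScoreWeights-class].
#' @param cbTree optional loop tree supplying cutpoints for the chainbreak
#'   term of the objective (defaults to `tree` when that has cutpoints).
#' @param maxSweeps,maxEval,tol iteration limits and convergence tolerance
#'   (score units).
#' @return the minimized [Pose-class].
#' @export
minimizeDof <- function(pose, tree, movemap, weights = scoreWeights(),
                        cbTree = NULL, maxSweeps = 30, maxEval = 400,
                        tol = 1e-4) {
  if (is.null(cbTree)) cbTree <- if (nrow(tree@cutpoints)) tree else NULL
  dofs <- list()
  for (j in movemap@jumpsFree) {
    if (!isTRUE(tree@jumps[[j]]$flexible))
      stop("jump ", j, " is frozen in this fold tree")
    dofs <- c(dofs, jumpDofs(tree, j))
  }
  if (length(movemap@backboneFree))
    dofs <- c(dofs, torsionDofs(pose, tree, movemap@backboneFree))
  if (!length(dofs)) {
    warning("empty move map: nothing to minimize")
    return(pose)
  }
  st <- poseStatic(pose, cbTree)
  wcb <- weights@weights[["chainbreak"]]
  wv9 <- weights9(weights)
  for (d in seq_along(dofs)) dofs[[d]]$moving <- as.integer(dofs[[d]]$moving)
  xyz <- pose@xyz
  cur <- scoreFast(xyz, st, weights)$total
  cbCur <- cbTermFast(xyz, st$cuts)
  steps <- vapply(dofs, function(d) d$step, 1)
  nev <- 1
  for (sweep in seq_len(maxSweeps)) {
    sweepStart <- cur
    for (d in seq_along(dofs)) {
      mov <- dofs[[d]]$moving
      improved <- FALSE
      for (sgn in c(1, -1)) {
        subOld <- subTotal(xyz, st, weights, mov, wv9)
        trial <- dofs[[d]]$apply(xyz, sgn * steps[d])
        cbNew <- cbTermFast(trial, st$cuts)
        v <- cur + subTotal(trial, st, weights, mov, wv9) - subOld +
          wcb * (cbNew - cbCur)
        nev <- nev + 1
        if (v < cur - 1e-12) {
          xyz <- trial; cur <- v; cbCur <- cbNew; improved <- TRUE
          # extend along the successful direction while it keeps helping
          while (nev < maxEval) {
            steps[d] <- min(steps[d] * 1.5, 4 * dofs[[d]]$step)
            subOld <- subTotal(xyz, st, weights, mov, wv9)
            trial <- dofs[[d]]$apply(xyz, sgn * steps[d])
            cbNew <- cbTermFast(trial, st$cuts)
            v <- cur + subTotal(trial, st, weights, mov, wv9) - subOld +
              wcb * (cbNew - cbCur)
            nev <- nev + 1
            if (v < cur - 1e-12) {
              xyz <- trial; cur <- v; cbCur <- cbNew
            } else {
              steps[d] <- steps[d] / 1.5
              break
            }
          }
          break
        }
      }
      if (!improved) steps[d] <- steps[d] / 2
      if (nev >= maxEval) break
    }
    if (nev >= maxEval) break
    if (sweepStart - cur < tol && all(steps < 1e-3)) break
  }
  pose@xyz <- xyz
  pose
}

#' Optimize side-chain conformations by chi-grid search
#'
#' Greedy per-residue packing in random residue order: each chi angle is
#' scanned on a 30-degree grid and then refined on a 10-degree grid around
#' the best value, keeping a change only when the total score improves
#' (monotone non-increase). Backbone atoms never move.
#'
#' @param pose a full-atom [Pose-class].
#' @param residues residue uids to repack.
#' @param weights a [ScoreWeights-class].
#' @param tree optional loop tree for the chainbreak objective term.
#' @param gridCoarse,gridFine grid spacings in degrees.
#' @return the repacked [Pose-class].
#' @export
packSidechains <- function(pose, residues, weights = scoreWeights(),
                           tree = NULL, gridCoarse = 30, gridFine = 10) {
  if (pose@resolution != "fullatom")
    stop("side-chain packing requires a full-atom pose")
  if (!length(residues)) return(pose)
  rs <- poseResidues(pose)
  sel <- rs[rs$resUid %in% residues & nchar(rs$resid) == 3, ]
  sel <- sel[vapply(sel$resid, nChi, 1L) > 0, ]
  if (!nrow(sel)) return(pose)
  st <- poseStatic(pose, tree)

  # precompute chi axis/moving atom indices per (residue, chi)
  a <- pose@atoms
  chiInfo <- list()
  for (i in seq_len(nrow(sel))) {
    span <- sel$first[i]:sel$last[i]
    resname <- sel$resid[i]
    tpl <- SC_TEMPLATES[[resname]]
    for (k in seq_len(nChi(resname))) {
      quad <- span[match(CHI_DEFS[[resname]][[k]], a$elety[span])]
      if (any(is.na(quad))) next
      mov <- span[a$elety[span] %in% tpl$atom[tpl$chi >= k]]
      if (!length(mov)) next
      chiInfo[[length(chiInfo) + 1]] <-
        list(res = i, quad = quad, mov = as.integer(mov))
    }
  }
  if (!length(chiInfo)) return(pose)
  resOf <- vapply(chiInfo, function(x) x$res, 1L)
  wv9 <- weights9(weights)
  xyz <- pose@xyz
  setTo <- function(xyz, ci, value) {
    q <- ci$quad
    curAng <- dihedral4(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    p <- xyz[q[2], ]
    xyz[ci$mov, ] <- rotateAbout(xyz[ci$mov, , drop = FALSE], p,
                                 xyz[q[3], ] - p, value - curAng)
    xyz
  }
  scan <- function(xyz, ci, cand) {
    chiScanCpp(xyz, as.integer(ci$quad), ci$mov, cand, st$vdw, st$charge,
               st$group, st$resUid, st$resno, st$chainIdx, st$heavy,
               weights@cutoff, weights@sigma, wv9)
  }
  for (i in sample(seq_len(nrow(sel)))) {
    for (ci in chiInfo[resOf == i]) {
      coarse <- scan(xyz, ci, seq(-180 + gridCoarse, 180, by = gridCoarse))
      best <- coarse[1]; bestV <- coarse[2]
      fine <- setdiff(seq(best - gridCoarse + gridFine,
                          best + gridCoarse - gridFine, by = gridFine), best)
      f <- scan(xyz, ci, fine)
      if (f[2] < bestV - 1e-12) { best <- f[1]; bestV <- f[2] }
      if (bestV < -1e-12) xyz <- setTo(xyz, ci, best)
    }
  }
  pose@xyz <- xyz
  pose
}
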