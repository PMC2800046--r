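# The decoy-generation pipeline: initialization, low-resolution Monte Carlo
# with optional ensemble conformer swapping, centroid CDR H2/H3 relaxation,
# resolution switch with side-chain rebuilding and packing, the five-move
# high-resolution Monte Carlo stage, and lowest-interface-energy output.

#' Protocol configuration constructor
#'
#' @param mode `"local"` (perturb around the input placement) or `"global"`
#'   (randomize the antigen orientation, point the paratope at it).
#' @param nDecoys trajectories per simulation; defaults to 1000 in local and
#'   5000 in global mode.
#' @param lowResCycles,highResCycles Monte Carlo cycles per stage
#'   (default 50 each).
#' @param kT Metropolis temperature in score units (default 0.8).
#' @param moveSet high-resolution move set (default [defaultMoveSet()]).
#' @param perturb magnitudes (default [defaultPerturbParams()]); partial
#'   lists are merged over the defaults.
#' @param weights a [ScoreWeights-class].
#' @param seed base seed; decoy i runs with `seed + i`.
#' @param options extra switches: `loopRelaxEachCycle` (run the centroid
#'   H2/H3 relaxation inside every low-res cycle instead of once after
#'   them), `minMaxEval` (evaluation budget per minimization call).
#' @return a [ProtocolConfig-class].
#' @export
protocolConfig <- function(mode = c("local", "global"), nDecoys = NULL,
                           lowResCycles = 50, highResCycles = 50, kT = 0.8,
                           moveSet = defaultMoveSet(),
                           perturb = list(), weights = scoreWeights(),
                           seed = 1, options = list()) {
  mode <- match.arg(mode)
  if (is.null(nDecoys)) nDecoys <- if (mode == "local") 1000 else 5000
  p <- defaultPerturbParams()
  p[names(perturb)] <- perturb
  o <- list(loopRelaxEachCycle = FALSE, minMaxEval = 80, pack = TRUE)
  o[names(options)] <- options
  methods::new("ProtocolConfig", mode = mode, nDecoys = nDecoys,
               lowResCycles = lowResCycles, highResCycles = highResCycles,
               kT = kT, moveSet = moveSet, perturb = p, weights = weights,
               seed = seed, options = o)
}

# Residue uids to repack after each kind of move.
packSelection <- function(pose, paratope, kind) {
  lp <- paratope@loops
  rs <- poseResidues(pose)
  loopUids <- function(names) {
    sel <- lp$name %in% names
    unlist(lapply(which(sel), function(i) {
      rs$resUid[rs$chain == lp$chain[i] & rs$resno %in% (lp$start[i]:lp$stop[i])]
    }))
  }
  if (kind == "dock_rb") {
    unique(interfaceResidues(pose, c("light", "heavy"), "antigen", 10)$resUid)
  } else if (kind == "vlvh_rb") {
    unique(interfaceResidues(pose, "light", "heavy", 10)$resUid)
  } else if (kind == "cdr_min") {
    neighborResidues(pose, loopUids(c("L1", "L2", "L3", "H1", "H2", "H3")), 8)
  } else if (kind == "h3_relax") {
    neighborResidues(pose, loopUids("H3"), 8)
  } else if (kind == "h2_relax") {
    neighborResidues(pose, loopUids("H2"), 8)
  } else {
    integer()
  }
}

#' Run one docking trajectory
#'
#' Executes the full pipeline: starting-position initialization (local
#' perturbation or global randomization), slide into glancing contact,
#' `lowResCycles` centroid Monte Carlo cycles of antibody rigid-body
#' perturbation (with an ensemble conformer swap per cycle when an ensemble
#' is supplied), centroid relaxation of CDRs H2 and H3 with the light-heavy
#' jump frozen, switch to full atoms with side chains from the donors,
#' interface and CDR-neighborhood packing, `highResCycles` cycles of the
#' weighted five-move set (each followed by targeted packing, isolated-DOF
#' minimization where due, and Metropolis acceptance at `kT`), and finally
#' returns the lowest-interface-energy snapshot observed.
#'
#' @param antibody a full-atom antibody [Pose-class] (light + heavy), or a
#'   list of such poses (an ensemble; the first member starts the run).
#' @param antigen a full-atom antigen [Pose-class].
#' @param loops loop config (path/list, see [loadLoopDefinitions()]) or a
#'   [ParatopeMap-class].
#' @param config a [ProtocolConfig-class].
#' @param seed seed for this trajectory.
#' @return a [Decoy-class].
#' @export
runDecoy <- function(antibody, antigen, loops, config = protocolConfig(),
                     seed = config@seed) {
  set.seed(seed)
  ensemble <- NULL
  if (is.list(antibody) && !methods::is(antibody, "Pose")) {
    ensemble <- antibody
    antibody <- ensemble[[1]]
  }
  pose <- combinePoses(list(antibody, antigen))
  paratope <- if (methods::is(loops, "ParatopeMap")) loops
              else loadLoopDefinitions(loops, pose)
  w <- config@weights
  p <- config@perturb
  kT <- config@kT
  stats <- list(lowResCycles = 0L, highResCycles = 0L,
                tried = integer(), accepted = integer(), trajectory = character())
  note <- function(x) stats$trajectory <<- c(stats$trajectory, x)

  # Steps 1-2: starting position, then glancing contact
  dockTree <- buildDockingFoldTree(pose)
  pose <- if (config@mode == "local") {
    localPerturbStart(pose, dockTree, p$initTransSigma, p$initTiltSigma)
  } else {
    globalRandomizeStart(pose, dockTree, paratope, p$globalSmallRot)
  }
  note("init")
  pose <- slideIntoContact(pose, dockTree)
  note("slide")
  stats$startPose <- pose

  # Steps 3-5: centroid stage, antibody rigid-body Monte Carlo (+ swaps)
  poseC <- toCentroid(pose)
  dockTreeC <- buildDockingFoldTree(poseC)
  loopTreeC <- buildLoopFoldTree(poseC, paratope, allowVlVh = FALSE)
  ensembleC <- if (!is.null(ensemble)) lapply(ensemble, toCentroid)
  member <- 1L
  stC <- poseStatic(poseC, loopTreeC)
  eC <- scoreFast(poseC@xyz, stC, w)$total
  for (cyc in seq_len(config@lowResCycles)) {
    trial <- rigidBodyPerturb(poseC, dockTreeC, "abag",
                              p$lowResTrans, p$lowResRot)
    eT <- scoreFast(trial@xyz, stC, w)$total
    if (metropolisAccept(eT - eC, kT)) {
      poseC <- trial; eC <- eT
    }
    if (!is.null(ensembleC)) {
      sw <- conformerSwap(poseC, ensembleC, dockTreeC, w, kT)
      m <- attr(sw, "member")
      if (!is.na(m)) member <- m
      attr(sw, "member") <- NULL
      poseC <- sw
      eC <- scoreFast(poseC@xyz, stC, w)$total
    }
    stats$lowResCycles <- stats$lowResCycles + 1L
    if (isTRUE(config@options$loopRelaxEachCycle)) {
      for (ln in c("H2", "H3"))
        poseC <- loopRelax(poseC, loopTreeC, ln, w, p$smallMaxLow, p$nSmall,
                           p$nShear, p$ccdTol, p$ccdMaxSweeps,
                           minimize = config@options$minMaxEval > 0,
                           minMaxEval = config@options$minMaxEval)
    }
  }
  note("lowres")

  # Step 6: centroid CDR H2 & H3 relaxation (light-heavy jump frozen,
  # side chains stay pseudo-atoms)
  if (!isTRUE(config@options$loopRelaxEachCycle)) {
    for (ln in c("H2", "H3"))
      poseC <- loopRelax(poseC, loopTreeC, ln, w, p$smallMaxLow, p$nSmall,
                         p$nShear, p$ccdTol, p$ccdMaxSweeps,
                         minimize = config@options$minMaxEval > 0,
                         minMaxEval = config@options$minMaxEval)
  }
  note("looprelax_lowres")

  # Step 7: back to full atoms; side chains from the starting antibody
  # model (current ensemble member) and the antigen input
  donorAb <- if (!is.null(ensemble)) ensemble[[member]] else antibody
  pose <- toFullatom(poseC, donors = list(donorAb, antigen))
  note("fullatom")

  dockTree <- buildDockingFoldTree(pose)
  loopTree <- buildLoopFoldTree(pose, paratope, allowVlVh = FALSE)
  rs <- poseResidues(pose)
  lp <- paratope@loops
  cdrUids <- unlist(lapply(seq_len(nrow(lp)), function(i)
    rs$resUid[rs$chain == lp$chain[i] & rs$resno %in% (lp$start[i]:lp$stop[i])]))

  # Step 8: pack both interfaces and the CDR neighborhoods
  doPack <- !identical(config@options$pack, FALSE)
  if (doPack) {
    sel8 <- unique(c(
      interfaceResidues(pose, c("light", "heavy"), "antigen", 10)$resUid,
      interfaceResidues(pose, "light", "heavy", 10)$resUid,
      neighborResidues(pose, cdrUids, 8)))
    pose <- packSidechains(pose, sel8, w, loopTree)
  }
  note("pack")

  # Steps 9-12: high-resolution Monte Carlo over the five-move set
  st <- poseStatic(pose, loopTree)
  eCur <- scoreFast(pose@xyz, st, w)
  best <- list(pose = pose, e = eCur)
  stats$interfaceTrace <- numeric(config@highResCycles)
  moveNames <- config@moveSet$name
  stats$tried <- stats$accepted <-
    stats::setNames(integer(length(moveNames)), moveNames)
  minEval <- config@options$minMaxEval
  for (cyc in seq_len(config@highResCycles)) {
    mv <- selectMove(config@moveSet)
    trial <- pose
    if (mv == "dock_rb") {
      trial <- rigidBodyPerturb(trial, dockTree, "abag", p$dockTrans, p$dockRot)
    } else if (mv == "vlvh_rb") {
      trial <- rigidBodyPerturb(trial, dockTree, "vlvh", p$vlvhTrans, p$vlvhRot)
    } else if (mv == "cdr_min") {
      if (minEval > 0)
        trial <- minimizeDof(trial, loopTree, moveMap(backboneFree = cdrUids),
                             w, cbTree = loopTree, maxEval = minEval)
    } else if (mv == "h3_relax") {
      trial <- loopRelax(trial, loopTree, "H3", w, p$smallMaxHigh, p$nSmall,
                         p$nShear, p$ccdTol, p$ccdMaxSweeps,
                         minimize = minEval > 0, minMaxEval = minEval)
    } else if (mv == "h2_relax") {
      trial <- loopRelax(trial, loopTree, "H2", w, p$smallMaxHigh, p$nSmall,
                         p$nShear, p$ccdTol, p$ccdMaxSweeps,
                         minimize = minEval > 0, minMaxEval = minEval)
    }
    # Step 10: pack the side chains relevant to the move
    if (doPack)
      trial <- packSidechains(trial, packSelection(trial, paratope, mv), w,
                              loopTree)
    # Step 11: minimize the selected region (H2/H3 relaxations are already
    # minimized)
    if (minEval > 0) {
      if (mv %in% c("dock_rb", "vlvh_rb")) {
        jm <- if (mv == "dock_rb") "abag" else "vlvh"
        trial <- minimizeDof(trial, dockTree, moveMap(jumpsFree = jm), w,
                             cbTree = loopTree, maxEval = minEval)
      } else if (mv == "cdr_min") {
        trial <- minimizeDof(trial, loopTree, moveMap(backboneFree = cdrUids),
                             w, cbTree = loopTree, maxEval = minEval)
      }
    }
    eT <- scoreFast(trial@xyz, st, w)
    stats$tried[mv] <- stats$tried[mv] + 1L
    if (metropolisAccept(eT$total - eCur$total, kT)) {
      pose <- trial; eCur <- eT
      stats$accepted[mv] <- stats$accepted[mv] + 1L
      if (eCur$interface < best$e$interface) best <- list(pose = pose, e = eCur)
    }
    stats$highResCycles <- stats$highResCycles + 1L
    stats$interfaceTrace[cyc] <- unname(eCur$interface)
  }
  note("highres")

  bestReport <- methods::new("EnergyReport", total = best$e$total,
                             terms = best$e$terms,
                             interfaceEnergy = unname(best$e$interface))
  methods::new("Decoy", pose = pose, bestPose = best$pose,
               energy = bestReport, stats = stats, seed = seed)
}

#' Run a batch docking simulation
#'
#' Generates `nDecoys` independent trajectories; decoy i uses seed
#' `config@seed + i`, so runs are reproducible and embarrassingly parallel
#' in principle. A failing trajectory is logged and skipped; the remaining
#' decoys are kept.
#'
#' @param antibody antibody pose or ensemble (see [runDecoy()]).
#' @param antigen antigen [Pose-class].
#' @param loops loop definitions (see [runDecoy()]).
#' @param config a [ProtocolConfig-class].
#' @return a [DecoySet-class] with the per-decoy score table.
#' @export
runSimulation <- function(antibody, antigen, loops, config = protocolConfig()) {
  decoys <- list()
  rows <- list()
  for (i in seq_len(config@nDecoys)) {
    seed <- config@seed + i
    d <- tryCatch(runDecoy(antibody, antigen, loops, config, seed = seed),
                  error = function(e) {
                    warning(sprintf("decoy %d failed: %s", i, conditionMessage(e)))
                    NULL
                  })
    if (is.null(d)) next
    decoys[[length(decoys) + 1]] <- d
    tm <- energyTerms(d@energy)
    rows[[length(rows) + 1]] <- data.frame(
      decoy = i, seed = seed, total = energyTotal(d@energy),
      interface_energy = interfaceEnergy(d@energy),
      t(tm), check.names = FALSE)
  }
  methods::new("DecoySet", decoys = decoys,
               table = if (length(rows)) do.call(rbind, rows) else data.frame())
}
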