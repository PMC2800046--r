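# S4 classes for the docking data model.

setOldClass("data.frame")

#' Pose: a molecular system for docking
#'
#' A `Pose` holds an antibody Fv (light + heavy chains) and an antigen as an
#' ordered atom table plus an n x 3 coordinate matrix. Resolution is either
#' `"fullatom"` (all heavy atoms, optional hydrogens) or `"centroid"` (four
#' backbone atoms plus one side-chain pseudo-atom per residue). The
#' `partition` maps chain identifiers to docking roles (`"light"`, `"heavy"`,
#' `"antigen"`).
#'
#' @slot atoms data.frame with one row per atom: `chain`, `resno`, `insert`,
#'   `resid` (3-letter residue name), `elety` (atom name), `element`,
#'   `occ`, plus derived columns `isBackbone`, `isHydrogen`, `vdw`, `charge`,
#'   `group` (1 light / 2 heavy / 3 antigen), `chainIdx`, `resUid` (global
#'   1-based residue counter), `bbComplete`.
#' @slot xyz numeric matrix (n x 3), Angstrom.
#' @slot resolution `"fullatom"` or `"centroid"`.
#' @slot partition named character vector, chain id -> role.
#' @export
setClass("Pose", representation(
  atoms = "data.frame",
  xyz = "matrix",
  resolution = "character",
  partition = "character"
))

setValidity("Pose", function(object) {
  msg <- character()
  if (nrow(object@atoms) != nrow(object@xyz))
    msg <- c(msg, "atom table and coordinate matrix disagree in length")
  if (ncol(object@xyz) != 3) msg <- c(msg, "xyz must have 3 columns")
  if (nrow(object@xyz) && !all(is.finite(object@xyz)))
    msg <- c(msg, "coordinates must be finite")
  if (!object@resolution %in% c("fullatom", "centroid"))
    msg <- c(msg, "resolution must be 'fullatom' or 'centroid'")
  if (!all(object@partition %in% c("light", "heavy", "antigen")))
    msg <- c(msg, "partition roles must be light/heavy/antigen")
  if (nrow(object@atoms)) {
    if (any(object@atoms$vdw <= 0)) msg <- c(msg, "vdw radii must be > 0")
    bb <- object@atoms$isBackbone & !object@atoms$elety %in% c("N", "CA", "C", "O")
    if (any(bb)) msg <- c(msg, "backbone flag only valid for N/CA/C/O")
    for (ch in unique(object@atoms$chain)) {
      rn <- object@atoms$resno[object@atoms$chain == ch]
      if (is.unsorted(rn)) {
        msg <- c(msg, sprintf("residue numbers not increasing in chain %s", ch))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Paratope bookkeeping for an antibody Fv
#'
#' Records the six CDR loop definitions, the framework residue sets of the
#' light and heavy chains, and the paratope (union of all CDR residues).
#'
#' @slot loops data.frame with columns `name` (L1..L3, H1..H3), `chain`
#'   (chain id), `role` (light/heavy), `start`, `stop`, `cutpoint`
#'   (residue numbers, inclusive; cutpoint is where the loop fold-tree cut
#'   sits).
#' @slot frameworkLight,frameworkHeavy integer residue numbers outside the
#'   CDRs.
#' @slot paratope data.frame (`chain`, `resno`) of all CDR residues.
#' @export
setClass("ParatopeMap", representation(
  loops = "data.frame",
  frameworkLight = "integer",
  frameworkHeavy = "integer",
  paratope = "data.frame"
))

setValidity("ParatopeMap", function(object) {
  msg <- character()
  lp <- object@loops
  if (!all(c("L1", "L2", "L3", "H1", "H2", "H3") %in% lp$name))
    msg <- c(msg, "all six CDR loops (L1-L3, H1-H3) must be present")
  if (any(lp$start >= lp$stop)) msg <- c(msg, "loop start must be < stop")
  if (any(lp$cutpoint < lp$start | lp$cutpoint >= lp$stop))
    msg <- c(msg, "cutpoint must lie in [start, stop)")
  for (ch in unique(lp$chain)) {
    r <- unlist(lapply(which(lp$chain == ch), function(i) lp$start[i]:lp$stop[i]))
    if (anyDuplicated(r)) msg <- c(msg, sprintf("loops overlap in chain %s", ch))
  }
  if (length(msg)) msg else TRUE
})

#' Kinematic fold tree
#'
#' Describes how structural perturbations propagate: `jumps` are 6-DOF
#' rigid-body connections (each with the downstream atom index set and a
#' flexible flag); `cutpoints` kinematically sever the chain inside CDR loops
#' so torsion changes stay local to the loop.
#'
#' Two kinds are built: the docking tree (`kind = "dock"`, flexible
#' light-heavy and antibody-antigen jumps, no cutpoints) and the loop tree
#' (`kind = "loop"`, fixed stem jumps, cut at the middle of each loop,
#' light-heavy jump optionally frozen).
#'
#' @slot kind `"dock"` or `"loop"`.
#' @slot jumps named list; each element has `down` (downstream atom indices),
#'   `flexible` (logical).
#' @slot cutpoints data.frame (`chain`, `resno`, `resUid`), possibly empty.
#' @slot loops data.frame of loop definitions with residue uids resolved
#'   (`uidStart`, `uidStop`, `uidCut`), empty for the docking tree.
#' @export
setClass("FoldTree", representation(
  kind = "character",
  jumps = "list",
  cutpoints = "data.frame",
  loops = "data.frame"
))

#' Move map: degrees of freedom open to a move or minimization
#'
#' @slot backboneFree integer residue uids whose phi/psi may change.
#' @slot jumpsFree character names of flexible jumps.
#' @slot sidechainFree integer residue uids whose chi angles may change.
#' @export
setClass("MoveMap", representation(
  backboneFree = "integer",
  jumpsFree = "character",
  sidechainFree = "integer"
))

#' Score weights and parameters
#'
#' Weights for the transparent docking score: soft-sphere repulsion, a
#' Gaussian contact well, Coulomb electrostatics with distance-dependent
#' dielectric, a quadratic chainbreak penalty at loop cutpoints, and the two
#' interchain terms (antibody-antigen and light-heavy cross-pair energies).
#'
#' @slot weights named numeric over `vdw_repulsive`, `contact_attractive`,
#'   `electrostatic`, `chainbreak`, `interchain_ab_ag`, `interchain_vl_vh`.
#' @slot sigma width of the contact well (Angstrom).
#' @slot cutoff pair interaction cutoff (Angstrom).
#' @export
setClass("ScoreWeights", representation(
  weights = "numeric",
  sigma = "numeric",
  cutoff = "numeric"
))

setValidity("ScoreWeights", function(object) {
  need <- c("vdw_repulsive", "contact_attractive", "electrostatic",
            "chainbreak", "interchain_ab_ag", "interchain_vl_vh")
  msg <- character()
  if (!all(need %in% names(object@weights)))
    msg <- c(msg, paste("weights must include:", paste(need, collapse = ", ")))
  if (!all(is.finite(object@weights))) msg <- c(msg, "weights must be finite")
  if (is.finite(object@weights["chainbreak"]) && object@weights["chainbreak"] <= 0)
    msg <- c(msg, "chainbreak weight must be > 0")
  if (length(msg)) msg else TRUE
})

#' Decomposed energy report
#'
#' @slot total weighted total score.
#' @slot terms named per-term values (unweighted raw sums for the base and
#'   chainbreak terms; weight-combined cross-pair energies for the two
#'   interchain terms).
#' @slot interfaceEnergy the antibody-antigen intermolecular component used
#'   for decoy ranking.
#' @export
setClass("EnergyReport", representation(
  total = "numeric",
  terms = "numeric",
  interfaceEnergy = "numeric"
))

#' Protocol configuration
#'
#' @slot mode `"local"` or `"global"` starting-position generation.
#' @slot nDecoys number of independent trajectories (defaults: 1000 local,
#'   5000 global).
#' @slot lowResCycles,highResCycles Monte Carlo cycles per stage (default 50
#'   each).
#' @slot kT Metropolis temperature in score units (default 0.8).
#' @slot moveSet data.frame of the high-resolution move set (`name`,
#'   `weight`).
#' @slot perturb named list of perturbation magnitudes (see
#'   [defaultPerturbParams()]).
#' @slot weights [ScoreWeights-class] used throughout.
#' @slot seed base random seed; decoy i uses `seed + i`.
#' @slot options named list of extra switches (`loopRelaxEachCycle`,
#'   `packCycles`, ...).
#' @export
setClass("ProtocolConfig", representation(
  mode = "character",
  nDecoys = "numeric",
  lowResCycles = "numeric",
  highResCycles = "numeric",
  kT = "numeric",
  moveSet = "data.frame",
  perturb = "list",
  weights = "ScoreWeights",
  seed = "numeric",
  options = "list"
))

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("local", "global")) msg <- c(msg, "mode must be local or global")
  if (object@kT <= 0) msg <- c(msg, "kT must be > 0")
  if (object@lowResCycles <= 0 || object@highResCycles <= 0)
    msg <- c(msg, "cycle counts must be > 0")
  if (length(msg)) msg else TRUE
})

#' One docking trajectory result
#'
#' @slot pose the final (last accepted) pose of the trajectory.
#' @slot bestPose the lowest-interface-energy snapshot observed during the
#'   run; this is the decoy the protocol reports.
#' @slot energy [EnergyReport-class] of `bestPose`.
#' @slot stats trajectory counters: cycles executed, moves tried/accepted by
#'   type, the post-initialization starting pose.
#' @slot seed the seed that generated this decoy.
#' @export
setClass("Decoy", representation(
  pose = "Pose",
  bestPose = "Pose",
  energy = "EnergyReport",
  stats = "list",
  seed = "numeric"
))

#' A set of decoys with their score table
#'
#' @slot decoys list of [Decoy-class] objects.
#' @slot table data.frame, one row per decoy: id, seed, per-term scores,
#'   total and interface energy.
#' @export
setClass("DecoySet", representation(
  decoys = "list",
  table = "data.frame"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "Pose", function(object) {
  rs <- poseResidues(object)
  cat(sprintf("Pose: %d atoms, %d residues, %d chains [%s]\n",
              nrow(object@atoms), nrow(rs), length(object@partition),
              object@resolution))
  for (ch in names(object@partition)) {
    n <- sum(rs$chain == ch)
    cat(sprintf("  chain %s (%s): %d residues\n", ch, object@partition[ch], n))
  }
  invisible(object)
})

setMethod("show", "ParatopeMap", function(object) {
  cat("ParatopeMap: six CDR loops\n")
  lp <- object@loops
  for (i in seq_len(nrow(lp)))
    cat(sprintf("  %s chain %s %d-%d (cut %d)\n", lp$name[i], lp$chain[i],
                lp$start[i], lp$stop[i], lp$cutpoint[i]))
  cat(sprintf("  paratope: %d residues\n", nrow(object@paratope)))
  invisible(object)
})

setMethod("show", "FoldTree", function(object) {
  cat(sprintf("FoldTree (%s): %d jumps (%d flexible), %d cutpoints\n",
              object@kind, length(object@jumps),
              sum(vapply(object@jumps, function(j) isTRUE(j$flexible), TRUE)),
              nrow(object@cutpoints)))
  invisible(object)
})

setMethod("show", "EnergyReport", function(object) {
  cat(sprintf("EnergyReport: total = %.3f, interface = %.3f\n",
              object@total, object@interfaceEnergy))
  print(round(object@terms, 4))
  invisible(object)
})

setMethod("show", "Decoy", function(object) {
  cat(sprintf("Decoy (seed %d): best interface energy %.3f, total %.3f\n",
              object@seed, object@energy@interfaceEnergy, object@energy@total))
  invisible(object)
})

setMethod("show", "DecoySet", function(object) {
  cat(sprintf("DecoySet: %d decoys\n", length(object@decoys)))
  if (nrow(object@table)) {
    best <- object@table[which.min(object@table$interface_energy), ]
    cat(sprintf("  lowest interface energy: %.3f (decoy %d)\n",
                best$interface_energy, best$decoy))
  }
  invisible(object)
})

# ---- simple accessors -------------------------------------------------------

#' @describeIn Pose-class number of atoms.
#' @param pose a [Pose-class].
#' @export
nAtoms <- function(pose) nrow(pose@atoms)

#' Atom coordinates of a pose
#' @param pose a [Pose-class].
#' @return n x 3 numeric matrix.
#' @export
poseCoords <- function(pose) pose@xyz

#' Atom table of a pose
#' @param pose a [Pose-class].
#' @export
poseAtoms <- function(pose) pose@atoms

#' Resolution flag of a pose
#' @param pose a [Pose-class].
#' @export
poseResolution <- function(pose) pose@resolution

#' Chain-to-role partition of a pose
#' @param pose a [Pose-class].
#' @export
posePartition <- function(pose) pose@partition

#' Total score of an energy report
#' @param x an [EnergyReport-class].
#' @export
energyTotal <- function(x) x@total

#' Interface (antibody-antigen cross) energy of a report
#' @param x an [EnergyReport-class].
#' @export
interfaceEnergy <- function(x) x@interfaceEnergy

#' Per-term decomposition of an energy report
#' @param x an [EnergyReport-class].
#' @export
energyTerms <- function(x) x@terms

#' Loop definitions of a paratope map
#' @param x a [ParatopeMap-class].
#' @export
paratopeLoops <- function(x) x@loops

#' Paratope residues (chain, resno) of a paratope map
#' @param x a [ParatopeMap-class].
#' @export
paratopeResidues <- function(x) x@paratope

#' Decoy list of a DecoySet
#' @param x a [DecoySet-class].
#' @export
decoyList <- function(x) x@decoys

#' Score table of a DecoySet
#' @param x a [DecoySet-class].
#' @export
decoyTable <- function(x) x@table

#' Best (lowest-interface-energy) pose of a decoy
#' @param x a [Decoy-class].
#' @export
bestPose <- function(x) x@bestPose

#' Trajectory statistics of a decoy
#' @param x a [Decoy-class].
#' @export
decoyStats <- function(x) x@stats
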