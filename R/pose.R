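# Pose construction, residue bookkeeping and representation switching.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Fixed per-element van der Waals radii (Angstrom); the side-chain
# pseudo-atom of the centroid representation uses 2.0.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, X = 2.0)

# Formal charges on charged side-chain tips (full-atom electrostatics).
CHARGED_ATOMS <- list(
  LYS = c(NZ = 1), ARG = c(CZ = 1),
  ASP = c(CG = -1), GLU = c(CD = -1)
)

elementFromName <- function(elety) {
  e <- sub("^[0-9]+", "", elety)
  first <- toupper(substr(e, 1, 1))
  ifelse(elety == "CEN", "X",
         ifelse(first %in% c("C", "N", "O", "S", "H"), first, "C"))
}

atomCharge <- function(resid, elety) {
  q <- numeric(length(resid))
  for (rn in names(CHARGED_ATOMS)) {
    tips <- CHARGED_ATOMS[[rn]]
    for (at in names(tips)) q[resid == rn & elety == at] <- tips[[at]]
  }
  q
}

#' Construct a Pose from an atom table
#'
#' Fills in all derived per-atom columns (element, vdW radius, backbone and
#' hydrogen flags, formal charge, partner group, global residue uid) and
#' validates the object. Atoms must be grouped by residue, residues by chain,
#' chains in the order of `partition`.
#'
#' @param atoms data.frame with at least `chain`, `resno`, `insert`, `resid`,
#'   `elety` (and optionally `element`, `occ`, `bbComplete`).
#' @param xyz n x 3 coordinate matrix.
#' @param resolution `"fullatom"` or `"centroid"`.
#' @param partition named character vector chain id -> role
#'   (light/heavy/antigen).
#' @return a [Pose-class].
#' @export
newPose <- function(atoms, xyz, resolution = "fullatom", partition) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element) || any(!nzchar(atoms$element)))
    atoms$element <- elementFromName(atoms$elety)
  atoms$isHydrogen <- atoms$element == "H"
  atoms$isBackbone <- atoms$elety %in% BACKBONE_ATOMS
  atoms$vdw <- unname(VDW_RADII[atoms$element])
  atoms$vdw[is.na(atoms$vdw)] <- 1.7
  atoms$charge <- atomCharge(atoms$resid, atoms$elety)

  roles <- c(light = 1L, heavy = 2L, antigen = 3L)
  if (is.null(names(partition))) stop("partition must be a named chain -> role map")
  missing <- setdiff(unique(atoms$chain), names(partition))
  if (length(missing))
    stop("chains without a partition role: ", paste(missing, collapse = ", "))
  atoms$group <- unname(roles[partition[atoms$chain]])
  atoms$chainIdx <- match(atoms$chain, names(partition))

  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$resUid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))

  if (is.null(atoms$bbComplete)) {
    bb <- tapply(atoms$elety, atoms$resUid,
                 function(e) all(BACKBONE_ATOMS %in% e))
    atoms$bbComplete <- as.logical(bb[as.character(atoms$resUid)])
  }
  rownames(atoms) <- NULL
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- NULL
  first <- which(!duplicated(atoms$resUid))
  last <- c(first[-1] - 1L, nrow(atoms))
  attr(atoms, "resTable") <- data.frame(
    resUid = atoms$resUid[first], chain = atoms$chain[first],
    resno = atoms$resno[first], insert = atoms$insert[first],
    resid = atoms$resid[first], group = atoms$group[first],
    first = first, last = last, bbComplete = atoms$bbComplete[first],
    stringsAsFactors = FALSE)
  methods::new("Pose", atoms = atoms, xyz = xyz,
               resolution = resolution, partition = partition)
}

#' Residue table of a pose
#'
#' One row per residue with its global uid, identity and the atom index range
#' it occupies.
#'
#' @param pose a [Pose-class].
#' @return data.frame with `resUid`, `chain`, `resno`, `insert`, `resid`,
#'   `group`, `first`, `last`, `bbComplete`.
#' @export
poseResidues <- function(pose) {
  a <- pose@atoms
  cached <- attr(a, "resTable")
  if (!is.null(cached)) return(cached)
  if (!nrow(a)) {
    return(data.frame(resUid = integer(), chain = character(),
                      resno = integer(), insert = character(),
                      resid = character(), group = integer(),
                      first = integer(), last = integer(),
                      bbComplete = logical()))
  }
  first <- which(!duplicated(a$resUid))
  last <- c(first[-1] - 1L, nrow(a))
  data.frame(resUid = a$resUid[first], chain = a$chain[first],
             resno = a$resno[first], insert = a$insert[first],
             resid = a$resid[first], group = a$group[first],
             first = first, last = last, bbComplete = a$bbComplete[first],
             stringsAsFactors = FALSE)
}

# Atom indices of a set of roles ("light","heavy","antigen").
groupAtomIdx <- function(pose, roles) {
  codes <- c(light = 1L, heavy = 2L, antigen = 3L)[roles]
  which(pose@atoms$group %in% codes)
}

# Atom index of a named atom in a residue (by chain + resno [+ insert]).
atomIdx <- function(pose, chain, resno, elety, insert = "") {
  a <- pose@atoms
  i <- which(a$chain == chain & a$resno == resno & a$insert == insert &
               a$elety == elety)
  if (length(i) != 1)
    stop(sprintf("atom %s not found uniquely in %s%d%s", elety, chain, resno, insert))
  i
}

# Center of mass (unweighted centroid) of a set of atom indices.
centerOfMass <- function(pose, idx) colMeans(pose@xyz[idx, , drop = FALSE])

#' Extract chains of a pose
#'
#' @param pose a [Pose-class].
#' @param roles roles to keep (e.g. `c("light", "heavy")`).
#' @return a [Pose-class] with the remaining chains.
#' @export
subsetPose <- function(pose, roles) {
  idx <- groupAtomIdx(pose, roles)
  if (!length(idx)) stop("no atoms for roles: ", paste(roles, collapse = ", "))
  part <- pose@partition[pose@partition %in% roles]
  keep <- c("chain", "resno", "insert", "resid", "elety", "element", "occ",
            "bbComplete")
  newPose(pose@atoms[idx, keep], pose@xyz[idx, , drop = FALSE],
          pose@resolution, part)
}

#' Combine poses into one system
#'
#' Concatenates the chains of several poses (e.g. an antibody Fv pose and an
#' antigen pose) into a single [Pose-class]; chain ids must be distinct and
#' resolutions must agree.
#'
#' @param poses list of [Pose-class] objects.
#' @return a [Pose-class].
#' @export
combinePoses <- function(poses) {
  stopifnot(length(poses) >= 1)
  res <- unique(vapply(poses, function(p) p@resolution, ""))
  if (length(res) != 1) stop("poses must share one resolution")
  part <- do.call(c, lapply(poses, function(p) p@partition))
  if (anyDuplicated(names(part))) stop("duplicate chain ids across poses")
  keep <- c("chain", "resno", "insert", "resid", "elety", "element", "occ",
            "bbComplete")
  atoms <- do.call(rbind, lapply(poses, function(p) p@atoms[, keep]))
  xyz <- do.call(rbind, lapply(poses, function(p) p@xyz))
  newPose(atoms, xyz, res, part)
}

#' Switch a pose to the centroid representation
#'
#' Keeps the four backbone atoms of every residue and replaces the side chain
#' by a single pseudo-atom (`CEN`, vdW radius 2.0) at the geometric center of
#' the side-chain heavy atoms; for glycine (or any residue without side-chain
#' heavy atoms) the pseudo-atom coincides with the alpha carbon. No side-chain
#' packing is possible in this representation.
#'
#' @param pose a full-atom [Pose-class].
#' @return a centroid [Pose-class].
#' @export
toCentroid <- function(pose) {
  if (pose@resolution == "centroid") {
    warning("pose is already centroid; returning unchanged")
    return(pose)
  }
  a <- pose@atoms
  rs <- poseResidues(pose)
  rows <- vector("list", nrow(rs))
  coords <- vector("list", nrow(rs))
  for (i in seq_len(nrow(rs))) {
    span <- rs$first[i]:rs$last[i]
    sub <- a[span, ]
    bb <- match(BACKBONE_ATOMS, sub$elety)
    present <- !is.na(bb)
    bbIdx <- span[bb[present]]
    sc <- span[!sub$elety %in% BACKBONE_ATOMS & !sub$isHydrogen]
    cen <- if (length(sc)) {
      colMeans(pose@xyz[sc, , drop = FALSE])
    } else {
      pose@xyz[span[match("CA", sub$elety)], ]
    }
    rows[[i]] <- data.frame(
      chain = rs$chain[i], resno = rs$resno[i], insert = rs$insert[i],
      resid = rs$resid[i],
      elety = c(BACKBONE_ATOMS[present], "CEN"),
      element = c(a$element[bbIdx], "X"),
      occ = 1, bbComplete = rs$bbComplete[i], stringsAsFactors = FALSE)
    coords[[i]] <- rbind(pose@xyz[bbIdx, , drop = FALSE], cen)
  }
  newPose(do.call(rbind, rows), do.call(rbind, coords), "centroid",
          pose@partition)
}

#' Rebuild full-atom detail from a centroid pose
#'
#' Side chains are grafted residue-by-residue from donor poses (typically the
#' starting antibody model and the unbound antigen): the donor backbone
#' (N/CA/C) is superposed onto the current backbone and its side-chain atoms
#' are carried along, so an unmoved backbone recovers the donor exactly.
#' Residues without a donor get idealized side chains from internal templates
#' at default chi angles.
#'
#' @param pose a centroid [Pose-class].
#' @param donors a [Pose-class] or list of poses supplying side-chain
#'   coordinates (matched by chain, residue number and insertion code).
#' @return a full-atom [Pose-class].
#' @export
toFullatom <- function(pose, donors = NULL) {
  if (pose@resolution != "centroid") stop("pose must be centroid")
  if (!is.null(donors) && methods::is(donors, "Pose")) donors <- list(donors)
  donorRes <- lapply(donors, poseResidues)
  rs <- poseResidues(pose)
  rows <- vector("list", nrow(rs))
  coords <- vector("list", nrow(rs))
  for (i in seq_len(nrow(rs))) {
    span <- rs$first[i]:rs$last[i]
    sub <- pose@atoms[span, ]
    bbNames <- intersect(BACKBONE_ATOMS, sub$elety)
    bbIdx <- span[match(bbNames, sub$elety)]
    bbXyz <- pose@xyz[bbIdx, , drop = FALSE]
    N <- pose@xyz[span[match("N", sub$elety)], ]
    CA <- pose@xyz[span[match("CA", sub$elety)], ]
    C <- pose@xyz[span[match("C", sub$elety)], ]

    scNames <- character(); scXyz <- NULL
    donorHit <- FALSE
    for (d in seq_along(donors)) {
      dr <- donorRes[[d]]
      j <- which(dr$chain == rs$chain[i] & dr$resno == rs$resno[i] &
                   dr$insert == rs$insert[i])
      if (length(j) == 1) {
        if (dr$resid[j] != rs$resid[i])
          stop(sprintf("donor residue name mismatch at %s%d: %s vs %s",
                       rs$chain[i], rs$resno[i], dr$resid[j], rs$resid[i]))
        don <- donors[[d]]
        dspan <- dr$first[j]:dr$last[j]
        dsub <- don@atoms[dspan, ]
        dbb <- dspan[match(c("N", "CA", "C"), dsub$elety)]
        if (any(is.na(dbb))) next
        fit <- kabsch(don@xyz[dbb, , drop = FALSE], rbind(N, CA, C))
        sc <- dspan[!dsub$elety %in% BACKBONE_ATOMS & !dsub$isHydrogen]
        scNames <- don@atoms$elety[sc]
        if (length(sc))
          scXyz <- applyFit(don@xyz[sc, , drop = FALSE], fit)
        donorHit <- TRUE
        break
      }
    }
    if (!donorHit) {
      built <- buildSidechain(rs$resid[i], N, CA, C)
      scNames <- rownames(built)
      scXyz <- built
    }
    rows[[i]] <- data.frame(
      chain = rs$chain[i], resno = rs$resno[i], insert = rs$insert[i],
      resid = rs$resid[i], elety = c(bbNames, scNames),
      element = elementFromName(c(bbNames, scNames)),
      occ = 1, bbComplete = rs$bbComplete[i], stringsAsFactors = FALSE)
    coords[[i]] <- rbind(bbXyz, scXyz)
  }
  newPose(do.call(rbind, rows), do.call(rbind, coords), "fullatom",
          pose@partition)
}
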