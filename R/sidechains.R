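# Idealized side-chain templates, chi-angle bookkeeping and rebuild.
#
# Templates are internal-coordinate tables: each side-chain atom is placed by
# placeAtom() from three previously placed atoms with a fixed bond length and
# angle; the torsion is either fixed or (chi index + offset).  The supported
# alphabet covers the fixture residues and common grafting cases; residues
# outside it simply carry whatever side-chain atoms their donor provides.

scRow <- function(atom, r1, r2, r3, bond, angle, chi, tor) {
  data.frame(atom = atom, r1 = r1, r2 = r2, r3 = r3, bond = bond,
             angle = angle, chi = chi, tor = tor, stringsAsFactors = FALSE)
}

# CB is placed by the improper torsion N-C-CA-CB = +123.2 deg, which fixes
# the L-chirality at the alpha carbon.
cbRow <- function(bond = 1.53) scRow("CB", "N", "C", "CA", bond, 111.1, 0, 123.2)

SC_TEMPLATES <- list(
  GLY = scRow(character(), character(), character(), character(),
              numeric(), numeric(), integer(), numeric())[0, ],
  ALA = cbRow(1.521),
  SER = rbind(cbRow(),
              scRow("OG", "N", "CA", "CB", 1.417, 110.8, 1, 0)),
  VAL = rbind(cbRow(1.546),
              scRow("CG1", "N", "CA", "CB", 1.521, 110.5, 1, 0),
              scRow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, 122.3)),
  LEU = rbind(cbRow(),
              scRow("CG", "N", "CA", "CB", 1.53, 116.3, 1, 0),
              scRow("CD1", "CA", "CB", "CG", 1.521, 110.7, 2, 0),
              scRow("CD2", "CA", "CB", "CG", 1.521, 110.7, 2, 122.6)),
  LYS = rbind(cbRow(),
              scRow("CG", "N", "CA", "CB", 1.52, 111.3, 1, 0),
              scRow("CD", "CA", "CB", "CG", 1.52, 111.3, 2, 0),
              scRow("CE", "CB", "CG", "CD", 1.52, 111.3, 3, 0),
              scRow("NZ", "CG", "CD", "CE", 1.489, 110.5, 4, 0)),
  ASP = rbind(cbRow(),
              scRow("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              scRow("OD1", "CA", "CB", "CG", 1.25, 118.4, 2, 0),
              scRow("OD2", "CA", "CB", "CG", 1.25, 118.4, 2, 180)),
  GLU = rbind(cbRow(),
              scRow("CG", "N", "CA", "CB", 1.52, 114.2, 1, 0),
              scRow("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              scRow("OE1", "CB", "CG", "CD", 1.25, 118.4, 3, 0),
              scRow("OE2", "CB", "CG", "CD", 1.25, 118.4, 3, 180))
)

# chi-angle atom quadruples per residue type.
CHI_DEFS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1"))
)

DEFAULT_CHIS <- c(-65, 180, 180, 180)

#' Build an idealized side chain onto a backbone frame
#'
#' @param resname 3-letter residue code (must be in the template alphabet).
#' @param N,CA,C backbone coordinates of the residue.
#' @param chis chi angles in degrees (recycled from defaults).
#' @return matrix of side-chain heavy-atom coordinates with atom-name
#'   rownames (0 rows for glycine).
#' @export
buildSidechain <- function(resname, N, CA, C, chis = DEFAULT_CHIS) {
  tpl <- SC_TEMPLATES[[resname]]
  if (is.null(tpl))
    stop("no side-chain template for residue type ", resname)
  known <- list(N = N, CA = CA, C = C)
  out <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(tpl))) {
    tor <- if (tpl$chi[i] > 0) chis[tpl$chi[i]] + tpl$tor[i] else tpl$tor[i]
    p <- placeAtom(known[[tpl$r1[i]]], known[[tpl$r2[i]]], known[[tpl$r3[i]]],
                   tpl$bond[i], tpl$angle[i], tor)
    known[[tpl$atom[i]]] <- p
    out <- rbind(out, p)
  }
  rownames(out) <- tpl$atom
  out
}

# Number of chi angles a residue type supports (0 if none / unknown type).
nChi <- function(resname) length(CHI_DEFS[[resname]])

# Measure chi k of a residue (by uid); NA if atoms missing.
measureChi <- function(pose, resUid, k) {
  q <- chiQuad(pose, resUid, k)
  if (is.null(q)) return(NA_real_)
  dihedral4(pose@xyz[q[1], ], pose@xyz[q[2], ], pose@xyz[q[3], ],
            pose@xyz[q[4], ])
}

chiQuad <- function(pose, resUid, k) {
  a <- pose@atoms
  span <- which(a$resUid == resUid)
  resname <- a$resid[span[1]]
  defs <- CHI_DEFS[[resname]]
  if (is.null(defs) || k > length(defs)) return(NULL)
  idx <- span[match(defs[[k]], a$elety[span])]
  if (any(is.na(idx))) return(NULL)
  idx
}

# Set chi k of a residue to an absolute value (degrees); rotates the atoms
# distal to the chi axis.  Returns the pose (unchanged if undefined).
setChi <- function(pose, resUid, k, value) {
  q <- chiQuad(pose, resUid, k)
  if (is.null(q)) return(pose)
  a <- pose@atoms
  span <- which(a$resUid == resUid)
  resname <- a$resid[span[1]]
  tpl <- SC_TEMPLATES[[resname]]
  if (is.null(tpl)) return(pose)
  movingNames <- tpl$atom[tpl$chi >= k]
  mov <- span[a$elety[span] %in% movingNames]
  if (!length(mov)) return(pose)
  cur <- dihedral4(pose@xyz[q[1], ], pose@xyz[q[2], ], pose@xyz[q[3], ],
                   pose@xyz[q[4], ])
  delta <- value - cur
  axisPoint <- pose@xyz[q[2], ]
  axisDir <- pose@xyz[q[3], ] - axisPoint
  pose@xyz[mov, ] <- rotateAbout(pose@xyz[mov, , drop = FALSE],
                                 axisPoint, axisDir, delta)
  pose
}
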