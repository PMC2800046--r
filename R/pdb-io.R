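# PDB input/output. Parsing and record formatting are delegated to bio3d;
# this layer applies the docking-specific policies: chain selection by
# partition role, altloc collapse to highest occupancy, exclusion of HETATM
# and water records, preservation of insertion codes, and flagging of
# residues with incomplete backbones.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Read a PDB file into a Pose
#'
#' Reads ATOM records (HETATM, waters and non-protein residues are dropped),
#' collapses alternate locations to the highest-occupancy copy, and assigns
#' the named chains to docking roles. Residues missing any of the four
#' backbone atoms are kept but flagged (`bbComplete = FALSE`) and excluded
#' from metric atom sets; a warning lists them.
#'
#' @param path PDB file.
#' @param partition named character vector chain id -> role, e.g.
#'   `c(L = "light", H = "heavy", A = "antigen")`.
#' @return a full-atom [Pose-class].
#' @export
readPdb <- function(path, partition) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !at$resid %in% c("HOH", "WAT", "DOD"), ]
  at <- at[at$resid %in% STANDARD_AA, ]
  missing <- setdiff(names(partition), unique(at$chain))
  if (length(missing))
    stop("chains named in partition but absent from file: ",
         paste(missing, collapse = ", "))
  at <- at[at$chain %in% names(partition), ]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc collapse: keep the highest-occupancy copy of each atom
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$o)
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(match(at$chain, names(partition)), at$resno,
                   at$insert, at$eleno), ]
  } else {
    at <- at[order(match(at$chain, names(partition)), at$resno,
                   at$insert, at$eleno), ]
  }

  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, elety = at$elety,
                      element = elementFromName(at$elety), occ = at$o,
                      stringsAsFactors = FALSE)
  pose <- newPose(atoms, cbind(at$x, at$y, at$z), "fullatom", partition)
  rs <- poseResidues(pose)
  bad <- rs[!rs$bbComplete, ]
  if (nrow(bad))
    warning("residues with incomplete backbone excluded from metric atom sets: ",
            paste(sprintf("%s%d%s", bad$chain, bad$resno, bad$insert),
                  collapse = ", "))
  pose
}

#' Write a Pose as a PDB file
#'
#' Standard ATOM records, chain ids, residue numbering and insertion codes
#' preserved; coordinates formatted to 3 decimals.
#'
#' @param pose a [Pose-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePdb <- function(pose, path) {
  if (!nAtoms(pose)) stop("cannot write an empty pose")
  a <- pose@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(pose@xyz)),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}
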