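# CDR loop bookkeeping and interface residue identification.

#' Load and validate CDR loop definitions
#'
#' Builds the [ParatopeMap-class] for a pose from a configuration naming the
#' six CDR loops (L1-L3 on the light chain, H1-H3 on the heavy chain) with
#' inclusive residue ranges. CDR boundaries are user-supplied (Chothia-style
#' ranges are the usual choice); no numbering scheme is hard-coded. The loop
#' cutpoint -- where the loop fold tree severs the chain -- defaults to the
#' middle of the loop, `start + floor((stop - start)/2)`.
#'
#' @param config path to a YAML file with a `loops:` block, or an equivalent
#'   list: each entry has `name`, `chain` (`"light"`/`"heavy"` or a chain
#'   id), `start`, `stop` and optionally `cutpoint`.
#' @param pose the [Pose-class] the ranges refer to.
#' @return a validated [ParatopeMap-class].
#' @export
loadLoopDefinitions <- function(config, pose) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  loops <- if (!is.null(config$loops)) config$loops else config
  need <- c("L1", "L2", "L3", "H1", "H2", "H3")
  nm <- vapply(loops, function(l) as.character(l$name), "")
  absent <- setdiff(need, nm)
  if (length(absent))
    stop("loop definitions missing: ", paste(absent, collapse = ", "))

  roleChain <- function(x) {
    if (x %in% c("light", "heavy")) {
      ch <- names(pose@partition)[pose@partition == x]
      if (length(ch) != 1) stop("pose has no unique ", x, " chain")
      ch
    } else x
  }
  rs <- poseResidues(pose)
  rows <- lapply(loops, function(l) {
    ch <- roleChain(as.character(l$chain))
    start <- as.integer(l$start); stop_ <- as.integer(l$stop)
    if (start >= stop_)
      stop(sprintf("loop %s: start must be < stop", l$name))
    have <- rs$resno[rs$chain == ch]
    rng <- start:stop_
    if (!all(rng %in% have))
      stop(sprintf("loop %s: residues %s out of range for chain %s", l$name,
                   paste(setdiff(rng, have), collapse = ","), ch))
    cut <- if (!is.null(l$cutpoint)) as.integer(l$cutpoint)
           else start + (stop_ - start) %/% 2
    if (cut < start || cut >= stop_)
      stop(sprintf("loop %s: cutpoint %d outside [start, stop)", l$name, cut))
    data.frame(name = as.character(l$name), chain = ch,
               role = unname(pose@partition[ch]), start = start,
               stop = stop_, cutpoint = cut, stringsAsFactors = FALSE)
  })
  lp <- do.call(rbind, rows)
  lp <- lp[match(need, lp$name), ]
  h3len <- lp$stop[lp$name == "H3"] - lp$start[lp$name == "H3"] + 1
  if (h3len < 3 || h3len > 20)
    stop("H3 loop length ", h3len, " outside the supported range (3-20)")
  if (h3len < 7 || h3len > 11)
    warning("H3 loop length ", h3len, " outside the typical 7-11 range")

  lch <- names(pose@partition)[pose@partition == "light"]
  hch <- names(pose@partition)[pose@partition == "heavy"]
  inLoops <- function(ch) {
    sel <- lp$chain == ch
    unique(unlist(mapply(seq, lp$start[sel], lp$stop[sel], SIMPLIFY = FALSE)))
  }
  fwL <- setdiff(rs$resno[rs$chain == lch], inLoops(lch))
  fwH <- setdiff(rs$resno[rs$chain == hch], inLoops(hch))
  para <- do.call(rbind, lapply(seq_len(nrow(lp)), function(i)
    data.frame(chain = lp$chain[i], resno = lp$start[i]:lp$stop[i],
               stringsAsFactors = FALSE)))
  methods::new("ParatopeMap", loops = lp, frameworkLight = as.integer(fwL),
               frameworkHeavy = as.integer(fwH), paratope = para)
}

#' Interface residues between two docking partners
#'
#' A residue belongs to the interface when any of its non-hydrogen atoms lies
#' within `cutoff` of a non-hydrogen atom of the other partner (the classic
#' 10-Angstrom interface definition). Symmetric in the two groups and
#' monotone in the cutoff.
#'
#' @param pose a [Pose-class].
#' @param groupA,groupB role sets, e.g. `c("light","heavy")` vs `"antigen"`.
#' @param cutoff distance threshold in Angstrom (default 10).
#' @return data.frame of interface residues (`resUid`, `chain`, `resno`,
#'   `side` = "A" or "B").
#' @export
interfaceResidues <- function(pose, groupA = c("light", "heavy"),
                              groupB = "antigen", cutoff = 10) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ia <- groupAtomIdx(pose, groupA)
  ib <- groupAtomIdx(pose, groupB)
  if (!length(ia) || !length(ib)) stop("empty partner group")
  a <- pose@atoms
  heavyA <- ia[!a$isHydrogen[ia]]
  heavyB <- ib[!a$isHydrogen[ib]]
  uidA <- unique(a$resUid[heavyA])
  uidB <- unique(a$resUid[heavyB])
  pairs <- expand.grid(uidA = uidA, uidB = uidB)
  d <- residuePairMinDistCpp(pose@xyz, !a$isHydrogen, a$resUid,
                             as.integer(pairs$uidA), as.integer(pairs$uidB))
  hit <- pairs[d <= cutoff, ]
  rs <- poseResidues(pose)
  mk <- function(uids, side) {
    if (!length(uids)) {
      return(data.frame(resUid = integer(), chain = character(),
                        resno = integer(), side = character(),
                        stringsAsFactors = FALSE))
    }
    i <- match(uids, rs$resUid)
    data.frame(resUid = uids, chain = rs$chain[i], resno = rs$resno[i],
               side = side, stringsAsFactors = FALSE)
  }
  rbind(mk(sort(unique(hit$uidA)), "A"), mk(sort(unique(hit$uidB)), "B"))
}

# Residues within `cutoff` of any residue in `uids`, measured between
# C-beta atoms (C-alpha for glycine / centroid poses).  Used for the 8 A
# side-chain neighborhood of the CDR loops.
neighborResidues <- function(pose, uids, cutoff = 8) {
  a <- pose@atoms
  rs <- poseResidues(pose)
  repAtom <- function(i) {
    span <- rs$first[i]:rs$last[i]
    j <- span[match("CB", a$elety[span])]
    if (is.na(j)) j <- span[match("CA", a$elety[span])]
    j
  }
  reps <- vapply(seq_len(nrow(rs)), repAtom, 1L)
  ok <- !is.na(reps)
  X <- pose@xyz[reps[ok], , drop = FALSE]
  sel <- rs$resUid[ok] %in% uids
  if (!any(sel)) return(integer())
  d2 <- outer(rowSums(X^2), rowSums(X[sel, , drop = FALSE]^2), "+") -
    2 * X %*% t(X[sel, , drop = FALSE])
  near <- rowSums(d2 <= cutoff^2) > 0
  sort(unique(c(uids, rs$resUid[ok][near])))
}
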