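# Docking-quality metrics: ligand rmsd, interface rmsd, fraction of native
# contacts, CAPRI-style ratings, funnel detection, perturbation tables and
# structural-diversity statistics.

# Matched backbone atom indices (N/CA/C/O) for residues shared by model and
# native, optionally restricted to roles and/or residue keys.
matchedBackbone <- function(model, native, roles = NULL, keys = NULL) {
  rsM <- poseResidues(model); rsN <- poseResidues(native)
  if (!is.null(roles)) {
    codes <- c(light = 1L, heavy = 2L, antigen = 3L)[roles]
    rsM <- rsM[rsM$group %in% codes, ]
    rsN <- rsN[rsN$group %in% codes, ]
  }
  keyM <- paste(rsM$chain, rsM$resno, rsM$insert)
  keyN <- paste(rsN$chain, rsN$resno, rsN$insert)
  common <- intersect(keyM, keyN)
  if (!is.null(keys)) common <- intersect(common, keys)
  rsM <- rsM[match(common, keyM), ]
  rsN <- rsN[match(common, keyN), ]
  ok <- rsM$bbComplete & rsN$bbComplete
  rsM <- rsM[ok, ]; rsN <- rsN[ok, ]
  if (!nrow(rsM)) stop("no residue correspondence between model and native")
  idx <- function(pose, rs) {
    unlist(lapply(seq_len(nrow(rs)), function(i) {
      span <- rs$first[i]:rs$last[i]
      span[match(BACKBONE_ATOMS, pose@atoms$elety[span])]
    }))
  }
  list(model = idx(model, rsM), native = idx(native, rsN))
}

#' Ligand rmsd
#'
#' Superposes the model's antibody backbone (N/CA/C/O) onto the native
#' antibody by least squares, then reports the rmsd of the antigen backbone
#' atoms without a second superposition. Measures how far the predicted
#' antigen placement is from the native one.
#'
#' @param model,native [Pose-class] objects sharing residue identity.
#' @return rmsd in Angstrom.
#' @export
ligandRmsd <- function(model, native) {
  ab <- matchedBackbone(model, native, roles = c("light", "heavy"))
  ag <- matchedBackbone(model, native, roles = "antigen")
  fit <- kabsch(model@xyz[ab$model, , drop = FALSE],
                native@xyz[ab$native, , drop = FALSE])
  rmsdCoords(applyFit(model@xyz[ag$model, , drop = FALSE], fit),
             native@xyz[ag$native, , drop = FALSE])
}

#' Interface rmsd
#'
#' The interface residue set is computed on the native complex (all residues
#' with a non-hydrogen atom within `cutoff` of the other partner); the model
#' is superposed onto the native over those residues' backbone atoms and the
#' rmsd is reported over the same atoms.
#'
#' @param model,native [Pose-class] objects sharing residue identity.
#' @param cutoff native interface cutoff in Angstrom (default 10).
#' @return rmsd in Angstrom.
#' @export
interfaceRmsd <- function(model, native, cutoff = 10) {
  ir <- interfaceResidues(native, c("light", "heavy"), "antigen", cutoff)
  if (!nrow(ir)) stop("native complex has an empty interface")
  rsN <- poseResidues(native)
  i <- match(ir$resUid, rsN$resUid)
  keys <- paste(rsN$chain[i], rsN$resno[i], rsN$insert[i])
  mb <- matchedBackbone(model, native, keys = keys)
  fit <- kabsch(model@xyz[mb$model, , drop = FALSE],
                native@xyz[mb$native, , drop = FALSE])
  rmsdCoords(applyFit(model@xyz[mb$model, , drop = FALSE], fit),
             native@xyz[mb$native, , drop = FALSE])
}

# Cross-partner residue pairs with heavy-atom contact <= cutoff.
contactPairs <- function(pose, cutoff = 5) {
  a <- pose@atoms
  uidAb <- unique(a$resUid[a$group %in% c(1L, 2L) & !a$isHydrogen])
  uidAg <- unique(a$resUid[a$group == 3L & !a$isHydrogen])
  pairs <- expand.grid(ab = uidAb, ag = uidAg)
  d <- residuePairMinDistCpp(pose@xyz, !a$isHydrogen, a$resUid,
                             as.integer(pairs$ab), as.integer(pairs$ag))
  pairs[d <= cutoff, ]
}

#' Fraction of native contacts
#'
#' Native residue-residue contacts are cross-partner pairs with any
#' non-hydrogen atoms within `cutoff` (5 Angstrom); the value is the
#' fraction of those pairs still in contact in the model.
#'
#' @param model,native [Pose-class] objects sharing residue identity.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(model, native, cutoff = 5) {
  natPairs <- contactPairs(native, cutoff)
  if (!nrow(natPairs)) stop("native complex has no cross-partner contacts")
  keyOf <- function(pose, uid) {
    rs <- poseResidues(pose)
    i <- match(uid, rs$resUid)
    paste(rs$chain[i], rs$resno[i], rs$insert[i])
  }
  natKeys <- paste(keyOf(native, natPairs$ab), keyOf(native, natPairs$ag))
  rsM <- poseResidues(model)
  mKey <- paste(rsM$chain, rsM$resno, rsM$insert)
  uidM <- function(keys) rsM$resUid[match(keys, mKey)]
  ab <- uidM(keyOf(native, natPairs$ab))
  ag <- uidM(keyOf(native, natPairs$ag))
  ok <- !is.na(ab) & !is.na(ag)
  if (!any(ok)) return(0)
  a <- model@atoms
  d <- residuePairMinDistCpp(model@xyz, !a$isHydrogen, a$resUid,
                             as.integer(ab[ok]), as.integer(ag[ok]))
  sum(d <= cutoff) / nrow(natPairs)
}

CAPRI_LEVELS <- c("incorrect", "acceptable", "medium", "high")

#' CAPRI-style quality rating
#'
#' Combines ligand rmsd (L), interface rmsd (I) and the fraction of native
#' contacts into the standard four-level rating:
#' incorrect if fnat < 0.1 or (L > 10 and I > 4); else high if fnat >= 0.5
#' and (L <= 1 or I <= 1); else medium if (fnat >= 0.3 and (L <= 5 or
#' I <= 2)) or (fnat >= 0.5 and L > 1 and I > 1); else acceptable if
#' fnat >= 0.3 or (fnat >= 0.1 and (L <= 10 or I <= 4)); else incorrect.
#' Monotone: raising fnat at fixed rmsds never lowers the rating.
#'
#' @param l_rms ligand rmsd (Angstrom).
#' @param i_rms interface rmsd (Angstrom).
#' @param fnat_val fraction of native contacts in `[0, 1]`.
#' @return character vector of ratings (vectorized over the inputs).
#' @export
capriRate <- function(l_rms, i_rms, fnat_val) {
  n <- max(length(l_rms), length(i_rms), length(fnat_val))
  L <- rep_len(l_rms, n); I <- rep_len(i_rms, n); f <- rep_len(fnat_val, n)
  stopifnot(all(is.finite(L)), all(is.finite(I)),
            all(f >= 0 & f <= 1))
  out <- character(n)
  for (k in seq_len(n)) {
    out[k] <- if (f[k] < 0.1 || (L[k] > 10 && I[k] > 4)) {
      "incorrect"
    } else if (f[k] >= 0.5 && (L[k] <= 1 || I[k] <= 1)) {
      "high"
    } else if ((f[k] >= 0.3 && (L[k] <= 5 || I[k] <= 2)) ||
               (f[k] >= 0.5 && L[k] > 1 && I[k] > 1)) {
      "medium"
    } else if (f[k] >= 0.3 || (f[k] >= 0.1 && (L[k] <= 10 || I[k] <= 4))) {
      "acceptable"
    } else {
      "incorrect"
    }
  }
  out
}

#' Compute the metric report for a set of decoys
#'
#' @param models list of [Pose-class] decoys (or a [DecoySet-class], whose
#'   best poses are used).
#' @param native the native complex [Pose-class].
#' @return data.frame with `ligand_rmsd`, `interface_rmsd`, `fnat`, `rating`.
#' @export
evaluateDecoys <- function(models, native) {
  if (methods::is(models, "DecoySet")) models <- lapply(models@decoys, bestPose)
  rows <- lapply(models, function(m) {
    l <- ligandRmsd(m, native)
    i <- interfaceRmsd(m, native)
    f <- fnat(m, native)
    data.frame(ligand_rmsd = l, interface_rmsd = i, fnat = f,
               rating = capriRate(l, i, f), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect a docking energy funnel
#'
#' A funnel exists when at least five of the ten lowest-interface-energy
#' decoys are of medium-or-better quality. With `strictMedium = TRUE` only
#' decoys rated exactly "medium" are counted (the narrower reading of the
#' definition); the default also counts "high".
#'
#' @param ratings character vector of CAPRI ratings, one per decoy.
#' @param energies interface energies, same length.
#' @param nTop,nNeeded funnel definition parameters (10 and 5).
#' @param strictMedium count only "medium" decoys?
#' @return logical flag.
#' @export
detectFunnel <- function(ratings, energies, nTop = 10, nNeeded = 5,
                         strictMedium = FALSE) {
  stopifnot(length(ratings) == length(energies))
  if (length(ratings) < nTop)
    stop("funnel detection needs at least ", nTop, " decoys")
  top <- ratings[order(energies)][seq_len(nTop)]
  good <- if (strictMedium) top == "medium" else top %in% c("medium", "high")
  sum(good) >= nNeeded
}

#' Rank decoys by energy
#'
#' Stable ascending sort by interface energy (default) or total score; ties
#' keep decoy order.
#'
#' @param set a [DecoySet-class].
#' @param by `"interface_energy"` or `"total"`.
#' @param k how many to return (all if larger than the set, with a warning).
#' @return the score table rows of the top `k` decoys, in rank order.
#' @export
rankDecoys <- function(set, by = c("interface_energy", "total"), k = 10) {
  by <- match.arg(by)
  tab <- set@table
  if (!nrow(tab)) stop("empty decoy set")
  if (k > nrow(tab)) {
    warning("k exceeds the number of decoys; returning all")
    k <- nrow(tab)
  }
  tab[order(tab[[by]], tab$decoy)[seq_len(k)], ]
}

#' Per-decoy perturbation table
#'
#' One row per decoy with its energies and docking metrics, plus the
#' rescored native complex as a reference row (the data behind an
#' interface-score versus ligand-rmsd perturbation plot).
#'
#' @param set a [DecoySet-class].
#' @param native the native complex [Pose-class].
#' @param weights a [ScoreWeights-class] for rescoring the native.
#' @return data.frame.
#' @export
perturbationTable <- function(set, native, weights = scoreWeights()) {
  met <- evaluateDecoys(set, native)
  tab <- cbind(set@table[, c("decoy", "total", "interface_energy")], met)
  natE <- scorePose(native, weights)
  natRow <- data.frame(decoy = 0L, total = energyTotal(natE),
                       interface_energy = interfaceEnergy(natE),
                       ligand_rmsd = 0, interface_rmsd = 0, fnat = 1,
                       rating = "high", stringsAsFactors = FALSE)
  rbind(natRow, tab)
}

#' Structural diversity of low-energy decoys
#'
#' For each CDR: superpose the corresponding framework chain of each decoy
#' onto the start structure and report the rmsd over that CDR's backbone;
#' for the light-heavy orientation: superpose the light framework and
#' report the rmsd over the heavy framework backbone; for the paratope:
#' superpose and query the paratope backbone. Means and standard deviations
#' over the decoys.
#'
#' @param decoys list of [Pose-class] objects sharing the start's layout.
#' @param start the reference [Pose-class] (e.g. the starting antibody).
#' @param paratope a [ParatopeMap-class].
#' @return data.frame with `segment`, `mean_rmsd`, `sd_rmsd`.
#' @export
diversityStats <- function(decoys, start, paratope) {
  rsS <- poseResidues(start)
  keysOf <- function(chain, resnos)
    paste(chain, resnos, "")
  lch <- names(start@partition)[start@partition == "light"]
  hch <- names(start@partition)[start@partition == "heavy"]
  segRmsd <- function(decoy, fitKeys, queryKeys) {
    fitIdx <- matchedBackbone(decoy, start, keys = fitKeys)
    qIdx <- matchedBackbone(decoy, start, keys = queryKeys)
    fit <- kabsch(decoy@xyz[fitIdx$model, , drop = FALSE],
                  start@xyz[fitIdx$native, , drop = FALSE])
    rmsdCoords(applyFit(decoy@xyz[qIdx$model, , drop = FALSE], fit),
               start@xyz[qIdx$native, , drop = FALSE])
  }
  lp <- paratope@loops
  segs <- list()
  for (i in seq_len(nrow(lp))) {
    fw <- if (lp$role[i] == "light") paratope@frameworkLight
          else paratope@frameworkHeavy
    segs[[lp$name[i]]] <- list(fit = keysOf(lp$chain[i], fw),
                               query = keysOf(lp$chain[i],
                                              lp$start[i]:lp$stop[i]))
  }
  segs[["VL-VH"]] <- list(fit = keysOf(lch, paratope@frameworkLight),
                          query = keysOf(hch, paratope@frameworkHeavy))
  pKeys <- paste(paratope@paratope$chain, paratope@paratope$resno, "")
  segs[["paratope"]] <- list(fit = pKeys, query = pKeys)
  rows <- lapply(names(segs), function(nm) {
    vals <- vapply(decoys, segRmsd, 1, fitKeys = segs[[nm]]$fit,
                   queryKeys = segs[[nm]]$query)
    data.frame(segment = nm, mean_rmsd = mean(vals),
               sd_rmsd = stats::sd(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
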