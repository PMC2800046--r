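# Shared fixtures (built once per test run) and independent brute-force
# oracles. Oracles deliberately avoid the package's own Kabsch/metric code
# paths: superpositions go through bio3d, everything else is plain R.

.cache <- new.env(parent = emptyenv())

cachedNative <- function() {
  if (is.null(.cache$native)) .cache$native <- makeToyComplex(fixtureSpec())
  .cache$native
}

cachedParatope <- function() {
  if (is.null(.cache$para))
    .cache$para <- fixtureParatope(cachedNative(), fixtureSpec())
  .cache$para
}

cachedAntigen <- function() {
  if (is.null(.cache$ag)) .cache$ag <- subsetPose(cachedNative(), "antigen")
  .cache$ag
}

cachedAntibody <- function() {
  if (is.null(.cache$ab))
    .cache$ab <- subsetPose(cachedNative(), c("light", "heavy"))
  .cache$ab
}

cachedMimic <- function() {
  if (is.null(.cache$mimic))
    .cache$mimic <- suppressWarnings(
      makeHomologyMimic(cachedNative(), fixtureSpec()))
  .cache$mimic
}

cachedLoopTree <- function() {
  if (is.null(.cache$ltree))
    .cache$ltree <- buildLoopFoldTree(cachedNative(), cachedParatope())
  .cache$ltree
}

# backbone atom xyz-vector indices (for bio3d) of a selection
xyzInds <- function(pose, atomIdx) {
  sort(c(3 * (atomIdx - 1) + 1, 3 * (atomIdx - 1) + 2, 3 * (atomIdx - 1) + 3))
}

bbIdxOfRoles <- function(pose, roles) {
  a <- poseAtoms(pose)
  codes <- c(light = 1L, heavy = 2L, antigen = 3L)[roles]
  which(a$group %in% codes & a$isBackbone)
}

# ligand rmsd through bio3d: superpose antibody backbone, measure antigen
# backbone (model and native must share the atom layout, as fixtures do)
bruteLigandRmsd <- function(model, native) {
  ab <- bbIdxOfRoles(native, c("light", "heavy"))
  ag <- bbIdxOfRoles(native, "antigen")
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(poseCoords(native))),
                           mobile = as.numeric(t(poseCoords(model))),
                           fixed.inds = xyzInds(native, ab),
                           mobile.inds = xyzInds(model, ab))
  plainRmsd(fitted, as.numeric(t(poseCoords(native))),
            xyzInds(model, ag), xyzInds(native, ag))
}

# rmsd computed directly from xyz vectors (full precision)
plainRmsd <- function(a, b, aInds, bInds) {
  da <- matrix(a[aInds], ncol = 3, byrow = TRUE)
  db <- matrix(b[bInds], ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((da - db)^2)))
}

# interface rmsd through bio3d, native 10 A interface by brute-force scan
bruteInterfaceRmsd <- function(model, native, cutoff = 10) {
  uids <- bruteInterfaceUids(native, cutoff)
  a <- poseAtoms(native)
  idx <- which(a$resUid %in% uids & a$isBackbone)
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(poseCoords(native))),
                           mobile = as.numeric(t(poseCoords(model))),
                           fixed.inds = xyzInds(native, idx),
                           mobile.inds = xyzInds(model, idx))
  plainRmsd(fitted, as.numeric(t(poseCoords(native))),
            xyzInds(model, idx), xyzInds(native, idx))
}

# all-pairs interface residue scan (heavy atoms only), plain R
bruteInterfaceUids <- function(pose, cutoff = 10) {
  a <- poseAtoms(pose)
  xyz <- poseCoords(pose)
  ab <- which(a$group %in% c(1L, 2L) & !a$isHydrogen)
  ag <- which(a$group == 3L & !a$isHydrogen)
  hits <- integer()
  for (i in ab) {
    d <- sqrt(colSums((t(xyz[ag, , drop = FALSE]) - xyz[i, ])^2))
    if (any(d <= cutoff)) hits <- c(hits, a$resUid[i], a$resUid[ag[d <= cutoff]])
  }
  sort(unique(hits))
}

# brute-force residue-residue contact pairs at `cutoff` (heavy atoms)
bruteContacts <- function(pose, cutoff = 5) {
  a <- poseAtoms(pose)
  xyz <- poseCoords(pose)
  abU <- unique(a$resUid[a$group %in% c(1L, 2L)])
  agU <- unique(a$resUid[a$group == 3L])
  out <- list()
  for (i in abU) {
    ii <- which(a$resUid == i & !a$isHydrogen)
    for (j in agU) {
      jj <- which(a$resUid == j & !a$isHydrogen)
      dmin <- min(sqrt(outer(rowSums(xyz[ii, , drop = FALSE]^2),
                             rowSums(xyz[jj, , drop = FALSE]^2), "+") -
                         2 * xyz[ii, , drop = FALSE] %*%
                         t(xyz[jj, , drop = FALSE])))
      if (dmin <= cutoff) out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}

bruteFnat <- function(model, native, cutoff = 5) {
  nat <- bruteContacts(native, cutoff)
  if (!length(nat)) stop("no native contacts")
  mod <- bruteContacts(model, cutoff)
  key <- function(p) paste(p[1], p[2])
  mean(vapply(nat, key, "") %in% vapply(mod, key, ""))
}

# rigid global motion applied to a whole pose
rigidMove <- function(pose, axis = c(1, 2, 3), angle = 25,
                      shift = c(3, -4, 5)) {
  xyz <- poseCoords(pose)
  R <- AbAgDock:::rotationMatrix(axis, angle)
  pose@xyz <- sweep(xyz %*% t(R), 2, shift, FUN = "+")
  pose
}

# a tiny three-chain pose of single-atom "residues" for geometric edge cases
miniPose <- function(lightAt = c(0, 0, 0), heavyAt = c(0, 0, 2),
                     antigenAt = c(20, 0, 1)) {
  atoms <- data.frame(
    chain = c("L", "H", "A"), resno = 1L, insert = "",
    resid = "GLY", elety = "CA", element = "C", occ = 1,
    bbComplete = FALSE, stringsAsFactors = FALSE)
  newPose(atoms, rbind(lightAt, heavyAt, antigenAt), "fullatom",
          c(L = "light", H = "heavy", A = "antigen"))
}
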