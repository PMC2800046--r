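---
title: "Flexible-paratope antibody-antigen docking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible-paratope antibody-antigen docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AbAgDock)
```

## The problem

Antibody-antigen complex structures are often predicted by docking an
antibody Fv model against an antigen. When the antibody is a homology model,
its six complementarity determining region (CDR) loops and the relative
orientation of the light (VL) and heavy (VH) variable domains carry errors
of 1-3 Angstrom, enough to frustrate rigid-backbone docking. AbAgDock
implements a multi-body Monte Carlo docking protocol that treats those
error-prone degrees of freedom as explicitly flexible: the antibody-antigen
rigid-body placement, the VL-VH orientation, and the six CDR loop backbones
are all optimized simultaneously while a decoy is generated.

## Kinematic model

Structural changes propagate through two fold trees, kinematic spanning
trees over rigid backbone segments:

* the **docking tree** has two flexible 6-DOF jumps -- light-to-heavy and
  antibody-to-antigen. A jump transform is a rotation about the downstream
  body's center of mass plus a translation, an exact isometry of that body.
  Center-of-mass anchoring is this package's choice; any fixed anchor gives
  the same reachable set of placements.
* the **loop tree** freezes the jumps (the VL-VH jump optionally), joins the
  stem residues flanking each CDR with a fixed jump and severs the chain at
  the loop middle (`start + floor((stop-start)/2)`). Torsion changes build
  the N-terminal half of the loop forward from the start stem and the
  C-terminal half backward from the stop stem, so a loop move can never
  displace an atom outside its loop.

The price of a cutpoint is a broken chain; closure pressure comes from a
quadratic chainbreak penalty on the deviation between the first backbone
nitrogen after the cut and its ideal position continued from the residue
before the cut with standard peptide geometry (C-N 1.329 A, CA-C-N 116.2
degrees, the psi dihedral measured toward the actual nitrogen). The
deviation therefore captures bond and angle mismatch; torsion continuity
across the cut is enforced by the three-anchor CCD targets rather than by
this scalar.

Cyclic coordinate descent (CCD) closes an open loop: each phi/psi in the
loop receives, in turn, the analytic rotation minimizing the summed squared
distance between three anchor pairs across the cut (the real N/CA of the
post-cut residue and the C of the pre-cut residue, against their
ideal-geometry "overlap" images built from the opposite half). Each update
is monotone in that objective by construction; iteration stops when the
chainbreak deviation reaches 0.15 A (default) or after 100 sweeps.

## Representations

Full-atom poses carry all heavy atoms (hydrogens are optional on input and
ignored by every distance criterion). The coarse representation keeps the
four backbone atoms and replaces each side chain by one pseudo-atom at the
side-chain heavy-atom centroid (alpha carbon for glycine), with a 2.0 A
radius. Switching back to full atoms grafts side-chain coordinates from
donor structures -- the starting antibody model and the (unbound) antigen --
by superposing the donor backbone per residue; residues without a donor get
idealized side chains from internal templates. An unmoved backbone recovers
its donor exactly, so the switch is lossless for rigid motions.

## Scoring

Protocols of this family are normally driven by a mature macromolecular
force field that is not reproducible from first principles, so the package defines a
transparent analog that preserves the qualitative landscape features the
protocol needs -- clash relief, contact reward, loop-closure pressure, a
mild electrostatic preference:

* soft-sphere repulsion per heavy-atom pair, `max(0, (rsum - d)/rsum)^2`
  with fixed per-element radii (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2,
  pseudo-atom 2.0 A);
* a Gaussian contact well `-exp(-(d - rsum)^2 / (2 sigma^2))`, sigma 1.5 A;
* Coulomb electrostatics with distance-dependent dielectric (eps = 4d) on
  charged side-chain tips, clamped below 2 A so it cannot overwhelm the
  bounded repulsion;
* the chainbreak penalty, weight 10, over the six CDR cutpoints.

Pairs within one residue or between backbone-adjacent residues are excluded;
the interaction cutoff is 12 A. Intra-partner pairs feed the base terms;
light-heavy and antibody-antigen cross pairs are accumulated separately as
the two interchain terms, so the weighted total decomposes exactly and the
**interface energy** -- the antibody-antigen cross component used to rank
decoys -- equals `score(complex) - score(partners separated)` identically.

The default repulsion weight is 100 against 0.5 for the contact well. The
ratio is the load-bearing choice: the contact well, summed over a growing
number of cross pairs, otherwise rewards burying the antigen ever deeper
into the antibody -- a quadratic soft sphere at unit weight only pushes back
noticeably at overlaps beyond ~1.5 A, and rigid-body minimization happily
paid ~0.2 per clashing pair to gain whole shells of contacts. At 100:0.5,
interpenetration beyond roughly a quarter Angstrom costs more than any
contact it gains, which moves the minima to surface-complementary
placements. Pair sums are computed densely in compiled code; at the
sub-100-residue systems this package targets a dense pass is faster and
simpler than neighbor-list bookkeeping.

## The protocol

One decoy is generated as follows (counts are the shipped defaults):

1. **Start**: in local mode the antigen is spun uniformly 0-360 degrees
   about the axis of partner centers, tilted off-axis by a Gaussian draw
   (sigma 8 degrees) and translated along it (sigma 8 A). In global mode the
   antigen orientation is drawn uniformly over rotations and the antibody is
   rotated so its paratope (the union of the six CDRs) points at the
   antigen, plus a 10-degree wobble.
2. **Slide into contact** along the centers axis until the closest
   antibody-antigen atom pair is within 1 A of van der Waals contact
   (bisection on the minimal gap, approached from outside).
3. **Low-resolution stage** (centroid): 50 Monte Carlo cycles of
   antibody-antigen rigid-body perturbation (0.7 A / 5 degrees), each with
   an ensemble conformer swap when an antibody ensemble is supplied -- a
   random member's antibody is superposed onto the current placement and
   accepted by Metropolis, emulating conformer selection.
4. **Centroid CDR relaxation**: H2 and H3 are each perturbed by 5 small and
   5 shear moves (6-degree cap), re-closed by CCD and minimized, with the
   VL-VH jump frozen. By default this runs once after the 50 cycles,
   matching the numbered protocol; `loopRelaxEachCycle` moves it inside the
   loop for users who read the flowchart that way.
5. **Resolution switch and packing**: side chains return from the donors;
   both interfaces (10 A rule) and the CDR neighborhoods (8 A between beta
   carbons) are repacked by a greedy chi-grid search (30-degree scan,
   10-degree refinement, random residue order, one sweep).
6. **High-resolution stage**: 50 cycles of a weighted move set --
   antibody-antigen rigid perturbation (40%), VL-VH rigid perturbation
   (40%), backbone minimization of all CDRs (10%), H3 relaxation (5%), H2
   relaxation (5%); high-resolution rigid-body magnitudes are 0.1 A / 3
   degrees and small/shear caps 3 degrees. After each move the relevant side
   chains are repacked and the selected degree of freedom is minimized (the
   H2/H3 relaxations already minimize internally); the cycle is accepted or
   rejected by the Metropolis criterion at kT = 0.8.
7. **Output**: the lowest-interface-energy snapshot observed along the
   accepted trajectory (tracked after every cycle, the finest granularity
   consistent with "observed during the simulation").

Minimization is derivative-free coordinate descent over one isolated DOF set
at a time -- one jump's six rigid-body coordinates, or one loop's torsions,
or all-CDR torsions -- with adaptive step halving, a same-direction line
search, and a hard evaluation budget (default 80 objective calls per
invocation). Isolating the degrees of freedom follows the observation that
simultaneous minimization over all degrees of freedom lets the stiff
rigid-body coordinates dominate while the loop torsions barely move, and
costs about three times more.

A simulation is `nDecoys` independent trajectories (1000 local / 5000 global
by default), decoy *i* seeded with `seed + i` so runs are reproducible and
trivially parallel. Batch tables are ranked by interface energy with stable
ties; ranking by total score is available because on some targets
(poorly packed interfaces) the total discriminates better.

## Evaluation stack

* **Ligand rmsd**: superpose the model's antibody backbone (N, CA, C, O) on
  the native antibody by least squares, then measure the antigen backbone
  rmsd without re-fitting.
* **Interface rmsd**: the interface residue set (any heavy atom within 10 A
  of the other partner) is computed on the native complex only; the model is
  superposed on the native over those backbone atoms and measured on them.
* **fnat**: the fraction of native cross-partner residue contacts (5 A
  heavy-atom criterion) recovered by the model.
* **CAPRI-style rating**: the standard four-level table; it reproduces the
  two anchor cases used to validate it -- 8.9/4.2/39% is acceptable,
  6.6/3.5/55% is medium -- and is monotone in fnat.
* **Funnel**: at least five medium-or-better decoys among the ten lowest
  interface-energy decoys. The narrower literal reading (count only
  "medium") is available via `strictMedium`; the default counts "high" as
  well, since a better-quality decoy should never demote a funnel.
* **Diversity statistics**: per-CDR rmsd from the start after superposing
  the owning chain's framework, VL-VH orientation rmsd (superpose light
  framework, measure heavy framework) and paratope rmsd, with means and
  standard deviations over the ten lowest-energy decoys.

Superpositions use a closed-form least-squares rotation with determinant
correction, checked in the test suite against an independent
implementation.

## Synthetic fixtures

`makeToyComplex()` builds a deterministic toy system: two idealized helical
chains (20 and 24 residues) standing in for the light and heavy domains,
splayed into a V whose cup opens toward the six designated CDR stretches
(H3 is 8 residues, inside the 7-11 range typical of benchmark sets), and a
10-residue helical antigen laid across the cup, slid into glancing contact
and then seated by rigid-body minimization of both jumps -- so the native
complex occupies an energy minimum of its own landscape, as a crystal
structure would, with at least five native residue contacts at the 5 A
criterion (fourteen under the defaults). Residues are mostly alanine/glycine with a
few serine/leucine/lysine/glutamate so packing and electrostatics are
exercised. `makeHomologyMimic()` emulates homology-model error: each CDR's
torsions are perturbed and CCD-reclosed, with the magnitude calibrated by
bisection until the loop's backbone rmsd to native is within 20% of the
requested error (default 2 A -- the scale reported for real antibody
homology models), and the VL-VH orientation is jittered (0.5 A / 3
degrees); an ensemble is independent draws. Short loops (3-4 residues)
cannot always reach 2 A and are returned best-effort with a warning.
`makeDecoyCloud()` gives rigid-antigen decoys with analytically known
displacements for metric validation.

What these fixtures do *not* model: real secondary-structure packing,
a sequence-accurate paratope, solvation, interfacial waters (a known
failure mode of implicit-solvation docking), or crystal-contact artifacts.
A passing suite therefore demonstrates correctness of the kinematics,
scoring bookkeeping, sampling distributions and metric definitions -- not
benchmark-grade docking accuracy on real complexes.

## Numerical choices and degenerate inputs

* Torsions live in (-180, 180]; setting one is an exact rotation of the
  moving half, so bond lengths/angles are conserved to machine precision.
* Slide-into-contact brackets the 1 A gap with unit steps before bisecting
  (tolerance 0.005 A) because exponential stepping can jump across the
  narrow contact window; it fails loudly if no contact exists along the
  centers axis or the partner centers coincide.
* The altloc policy keeps the highest-occupancy copy; waters, HETATM and
  non-protein residues are dropped; residues missing a backbone atom are
  flagged and excluded from metric atom sets with a warning.
* Ties in decoy ranking are broken by decoy index (stable sort).
* Problem sizes in the shipped tests: the 54-residue toy complex, 100-decoy
  metric clouds, a 200-decoy local docking simulation, 100,000-draw
  sampling checks. These sizes give stable statistics for every criterion
  while keeping a full run at desk scale.

## Known limitations

The energy model is a transparent analog, not a calibrated force field:
absolute energies are meaningless across systems and no solvation or
orientation-dependent hydrogen bonding is present. The side-chain packer is
a greedy grid search without a rotamer library or unbound-rotamer memory.
Fold trees cover exactly the two topologies the protocol needs; there is no
general n-body machinery, no symmetric docking and no flexibility for
non-CDR loops. Homology-model generation for real antibodies is out of
scope -- inputs are PDB files the user supplies.
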