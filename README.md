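# AbAgDock

Flexible-paratope Monte Carlo docking of antibody–antigen complexes in R.

## What it does and for whom

When an antibody Fv must be docked against its antigen starting from a
homology model, the errors concentrated in the six complementarity
determining region (CDR) loops and in the relative orientation of the
light/heavy variable domains (V<sub>L</sub>–V<sub>H</sub>) frustrate
rigid-backbone docking. AbAgDock is for structural bioinformaticians who
need a docking protocol that treats exactly those degrees of freedom as
flexible: every decoy simultaneously samples

* the antibody–antigen rigid-body placement (6-DOF jump),
* the V<sub>L</sub>–V<sub>H</sub> orientation (6-DOF jump), and
* the backbones of CDRs L1–L3 and H1–H3 (φ/ψ torsions behind loop
  fold-trees with cutpoints, re-closed by cyclic coordinate descent).

A decoy is generated by a two-resolution Monte Carlo minimization
trajectory: random start (local perturbation or global paratope-directed
randomization), slide into glancing contact (1 Å of van der Waals contact),
50 coarse-grained rigid-body cycles (side chains as single pseudo-atoms,
optional ensemble conformer swapping), centroid relaxation of CDRs H2/H3,
return to full atoms with side-chain grafting and interface packing, then 50
cycles drawing from a weighted move set —

| move | probability |
|---|---|
| antibody–antigen rigid-body perturbation | 40% |
| V<sub>L</sub>–V<sub>H</sub> rigid-body perturbation | 40% |
| backbone minimization of all CDRs | 10% |
| CDR H3 relaxation (small/shear/CCD + minimization) | 5% |
| CDR H2 relaxation | 5% |

— each followed by targeted side-chain packing, isolated-DOF minimization
and Metropolis acceptance at kT = 0.8. The decoy reported is the
lowest-*interface-energy* snapshot observed, where the interface energy is
the antibody–antigen intermolecular component of the score, and a batch of
decoys (1000 local / 5000 global by default) is ranked by it.

The evaluation stack implements the standard docking quality measures:
ligand rmsd L<sub>rms</sub> (antigen backbone after antibody superposition),
interface rmsd I<sub>rms</sub> (backbone of the native 10 Å interface),
f<sub>nat</sub> (fraction of native residue contacts at 5 Å), CAPRI-style
high/medium/acceptable/incorrect ratings, energy-funnel detection (≥ 5
medium-or-better among the 10 lowest-energy decoys) and per-segment
structural-diversity statistics.

A programmatic fixture module generates toy antibody-like complexes,
homology-model mimics with calibrated CDR error, ensembles and decoy clouds,
so the whole package is testable offline at desk scale. The scoring function
is a transparent analog (soft-sphere repulsion, Gaussian contact well,
damped Coulomb, chainbreak penalty) — see the methods vignette
(`vignettes/flexible-docking-methods.Rmd`) for the model, its parameters and
its limitations.

## Worked example

Dock a homology-model mimic of a toy antibody against its antigen and
evaluate the decoys against the native:

```r
library(AbAgDock)

spec   <- fixtureSpec()                 # 54-residue toy complex, 8-residue H3
native <- makeToyComplex(spec)
native
#> Pose: 294 atoms, 54 residues, 3 chains [fullatom]
#>   chain L (light): 20 residues
#>   chain H (heavy): 24 residues
#>   chain A (antigen): 10 residues

mimic <- makeHomologyMimic(native, spec)    # ~2 A CDR error + VL-VH jitter
cfg   <- protocolConfig(mode = "local", nDecoys = 20, seed = 7)
set   <- runSimulation(mimic$antibody, subsetPose(native, "antigen"),
                       fixtureParatope(native, spec), cfg)
set
#> DecoySet: 20 decoys
#>   lowest interface energy: -132.533 (decoy 5)

rankDecoys(set, "interface_energy", k = 3)[, c("decoy", "total", "interface_energy")]
#>  decoy     total interface_energy
#>      5 -874.5956       -132.53253
#>     16 -836.5895        -92.02758
#>     11 -832.1782        -85.85577

met <- evaluateDecoys(set, native)
head(met, 3)
#>  ligand_rmsd interface_rmsd      fnat     rating
#>     7.311161       3.230821 0.2857143 acceptable
#>     8.474891       3.822708 0.4285714 acceptable
#>     9.809089       3.220483 0.4285714 acceptable
```

Each row is one decoy: its antigen-placement error in Å (`ligand_rmsd`),
the backbone error over the native interface (`interface_rmsd`), the
fraction of native residue contacts it recovers (`fnat`), and the
CAPRI-style label combining the three. This 20-decoy run yields 7 medium
and 11 acceptable decoys but no energy funnel
(`detectFunnel(met$rating, decoyTable(set)$interface_energy)` is `FALSE` —
fewer than five medium-or-better among the ten lowest energies); the
shipped defaults run 1000 trajectories.

A thin command-line front end (`inst/cli/abagdock.R`) exposes
`dock`, `evaluate` and `make-fixture` subcommands over the same functions
for shell pipelines, with chain roles and CDR ranges supplied as YAML.

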