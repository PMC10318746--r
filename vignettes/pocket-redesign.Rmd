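---
title: "Methods: binding-pocket ligand replacement and redesign"
author: "PocketSwap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-pocket ligand replacement and redesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PocketSwap)
```

PocketSwap swaps the ligand of a solute-binding protein for a
stereoisomer and redesigns the pocket around it, scoring the result with
a thermodynamic cycle. This vignette documents the models behind each
stage, the parameters that matter, the numerical choices, and what the
synthetic fixtures do and do not demonstrate.

## The biological problem

The *A. vitis* ABC-transporter solute-binding protein clamps the
hexitol allitol between two domains. Sorbitol, the sugar alcohol whose
intracellular accumulation underlies sorbitol-dehydrogenase-deficiency
pathologies (cataract, retinopathy, peripheral neuropathy), is the C3
epimer of allitol: identical constitution, one inverted stereocenter.
The workflow asks whether small pocket redesigns make the protein a
better sorbitol binder — a candidate "molecular sponge".

## Alditol geometry and stereo descriptors

`buildAlditol()` constructs an n-carbon polyol in the extended
(all-anti) backbone conformation with tetrahedral centers and standard
bond lengths (C–C 1.54 Å, C–O 1.43 Å, C–H 1.09 Å, O–H 0.96 Å). The
extended conformer is arbitrary but irrelevant downstream: docking
re-aligns the backbone rigidly and refines every hydroxyl torsion
against the crystal pose.

Configuration is encoded as R/S descriptors for the internal carbons,
assigned from 3D coordinates by the signed volume of the ranked
substituent directions. Priorities use a fixed ranking appropriate to
uniform polyol chains:

> OH > chain toward the farther terminus > chain toward the nearer
> terminus > H.

For linear polyols this coincides with constitutional CIP ranking — at
every internal carbon the longer chain branch presents (O, C, H) where
the shorter presents (O, H, H) at its terminus, so the comparison is
decided before any stereo-dependent CIP rule is reached. Ties can only
occur at the exact midpoint of an odd-length backbone and are broken
toward the higher-numbered side (documented, deterministic; hexitols
have no such tie). Because the ranking is identical in both epimers,
inverting one center flips exactly one label: allitol is (2S,3S,4R,5R)
in the package's C1-first numbering and sorbitol (D-glucitol) is
(2S,3R,4R,5R) — the difference sits at C3, the epimeric center.
Hydrogens are generated on build but dropped when matching against
heavy-atom crystal ligands; the descriptor computation needs no
hydrogens (the H direction is implied by the other three substituents).

Bond perception declares two atoms bonded when their separation is at
most the sum of covalent radii plus a tolerance (default 0.45 Å; the
comparison is closed so that ideal-geometry bonds lying exactly at the
radius sum are stable at zero tolerance). The backbone is the longest
simple carbon path, oriented by C1..Cn atom names when present,
otherwise by lowest serial.

## Docking by backbone superposition

Placement is the deliberately simple two-move recipe:

1. **Kabsch superposition** of the six backbone carbons (closed-form
   SVD least squares). The determinant sign fix forbids reflections — a
   reflected fit would silently invert the ligand's stereochemistry,
   which is the one thing the workflow must preserve. Both the direct
   (C1–C1) and reversed (C1–C6) correspondences are scored and the
   lower-RMSD orientation kept, since alditol numbering direction is a
   convention. Degenerate inputs (fewer than three pairs, collinear
   points) are rejected.
2. **Hydroxyl torsion refinement** by cyclic coordinate descent over
   the backbone C–C torsions, minimizing the summed squared deviation
   of hydroxyl oxygens from their reference counterparts. Each
   one-torsion subproblem has the closed form
   A + B·cos θ + C·sin θ, so the per-torsion optimum
   is analytic (θ\* = atan2(−C, −B)); a half-degree grid check can be
   enabled as a safeguard. The oxygen on the epimeric carbon (default
   C3) is excluded from the objective — its hydroxyl points the other
   way by construction and must not be forced onto the reference.

The two moves alternate (torsion moves perturb the rigid alignment)
until the backbone RMSD changes by less than 1e-4 Å between rounds,
with a cap of 50 rounds; the torsion stage stops when a sweep improves
the objective by less than 1e-6 Å² or after 100 sweeps. These
tolerances are engineering choices: the procedure they automate was
originally interactive and had no convergence criterion. Rigid moves
and bond rotations cannot change chirality, so stereo descriptors are
invariant under the whole pipeline (tested).

`swapLigand()` then removes the old heteroatom residue and inserts the
placed ligand's heavy atoms with fresh serials, the old chain id and
residue number; protein atoms are untouched.

## Polar contacts

Crystal inputs carry no hydrogens, so hydrogen bonds are approximated
by their community-standard heavy-atom proxy. A `ContactCriteria`
object holds the knobs:

| parameter | default | meaning |
|---|---|---|
| `neighborCutoff` | 4.0 Å | pocket-residue selection radius |
| `polarDistanceMin` | 2.4 Å | minimum donor–acceptor separation |
| `polarDistanceMax` | 3.5 Å | maximum donor–acceptor separation |
| `angleMin` | 90° | heavy-atom antecedent angle at both partners |
| `includeBackbone` | TRUE | consider backbone N/O (flagged in output) |

Donor/acceptor typing is a fixed per-residue table (side-chain N/O of
HIS, ARG, ASP, GLU, GLN, ASN, LYS, TYR, SER, THR, TRP; S of CYS and
MET) plus ligand oxygens. The antecedent-angle criterion — every bonded
heavy neighbour of each polar atom must sit at ≥ 90° from the partner —
rejects geometries in which no plausible proton could bridge the pair.
The comparison carries a 1e-6-degree tolerance so that ideal-geometry
fixtures whose antecedent angles are exactly 90° count stably under
floating-point rigid motions. The exact thresholds are calibration
knobs, not constants of nature: published polar-bond counts came from a
visualization tool's defaults, so the criteria are exposed in the API
and reports state the criteria they were computed under.

`contactReport()` tabulates per-residue counts across up to three
states (before design, after design, after relax) with a totals row and
separately lists pocket residues with zero contacts — the "potential
for polar bonds" set that the design stage targets by default.

## The reduced energy model

The packing, minimization and cycle stages need an energy function.
External scorefunction values are opaque (their absolute scale is not
reproducible and is consumed only as ΔΔG inputs), so the package
defines its own reduced, fully specified heavy-atom model, shipped as a
versioned text parameter file (`inst/extdata/reduced_ff_v1.txt`):

* **Lennard-Jones**: 4ε[(σ/r)¹² − (σ/r)⁶] with Lorentz–Berthelot
  mixing over seven atom types; 10 Å cutoff with CHARMM-style switching
  from 8 Å. The r⁻¹² term carries a separate scale factor so the relax
  protocol can ramp repulsion from soft to full.
* **Coulomb**: k·qᵢqⱼ/(D·r²) with distance-dependent dielectric
  ε(r) = 4r — a standard vacuum-free screening choice for
  hydrogen-free models. Template charges per residue atom absorb the
  implicit hydrogens, so neutral side chains sum to 0 and
  ASP/GLU/LYS/ARG to ±1.
* **Hydrogen bonds**: a square well of −1.0 reduced unit per geometric
  polar contact, reusing the contact criteria above. Hydrogen-bonded
  pairs are *dropped from the Coulomb sum*: with the bridging proton
  absent, the bare donor–acceptor charge product (two partial negative
  oxygens) would register repulsion for an interaction that is
  attractive; the well replaces it. This coupling is what transmits the
  "more polar bonds" design pressure into the optimizer.
* **Torsions**: k(1 + cos 3φ), k = 0.2, over side-chain and ligand C–C
  bonds (backbone atoms excluded), favouring staggered rotamers.
* **Exclusions**: 1-2 and 1-3 pairs excluded, 1-4 pairs scaled by 0.5,
  with bonded topology perceived from covalent distances (peptide and
  disulfide bonds included automatically).

Energies are dimensionless ("reduced units"); only differences within
the model are meaningful. The implementation is checked against a
brute-force double-loop oracle on random fixtures, against the closed
form −ε at the LJ minimum, and for rigid-motion invariance.

## Fixed-backbone design

`DesignSpec` mirrors the resfile idiom: NATRO (untouched), NATAA
(native identity, repackable), ALLAA (any identity) per residue, with a
default for unlisted residues, and a plain-text resfile reader/writer.
Side chains are rebuilt from idealized internal-coordinate templates on
the fixed backbone (N, Cα, C kept; Cβ placed at the L-configuration
improper dihedral of +122.5°, matching crystal-structure geometry);
ring closure for five-membered rings and the proline ring is
approximate, and proline as a *target* identity is allowed but flagged.
The rotamer library samples χ at {−60°, 60°, 180°} per rotatable bond
(aromatic/amide χ₂ at ±90°, proline at its two pucker values), full
cartesian product, uniform weights — coarse, desk-scale, and swappable.

`packResidues()` runs Metropolis simulated annealing over (identity,
rotamer) assignments: geometric cooling (default kT 100 → 0.3 over 50
steps per designable residue), one residue rebuilt per step, ΔE from
the full reduced-model score, acceptance by the Metropolis criterion,
best-ever configuration returned, fully deterministic given the seed
(the global RNG stream is saved and restored). Equal-energy proposals
resolve by first-seen order under the seeded stream, so reruns are
bit-identical. `repeatOptimize()` is the fixed-temperature preset (kT =
1, n = 20 independent sweeps, best kept). `minimizeTorsions()` descends
cyclically over χ (or backbone) torsions with a numeric gradient and a
shrinking line search that only ever accepts energy-lowering rotations;
`relaxComplex()` cycles soft-to-full repulsion ramps of NATAA repacking
plus minimization and reports the best full-repulsion structure.

The thermodynamic cycle is bookkeeping on five state energies, with two
contracts worth stating: the free-ligand energy may be *unknown* (it
cancels in ΔΔG and is never silently zeroed), and the wild-type
energies entering ΔΔG are the pre-minimization ones — minimizing the
unbound protein first would bias the cycle toward the unbound state, so
the pipeline driver enforces that pairing.

## What the synthetic fixtures emulate

`makePocket()` builds a hexitol and plants template residues around it
by constraint satisfaction: the residue's terminal reference atom is
placed on a sphere of the target radius around a chosen ligand oxygen,
body pointing outward, with a deterministic spin/tilt grid resolving
overlaps — never by minimization, so ground truth stays analytic.
Planted polar identities inside the hydrogen-bond window create
contacts by construction; fillers stay outside the 4 Å pocket; an
optional clash plants an overlapping side chain; `makeDimer()` emulates
a crystallographic homodimer; `makeStereoPair()` builds epimer pairs.
Every ground-truth record is re-verified by the corresponding analysis
operation before the fixture is returned, keeping generator and
analyzers mutually consistent.

The designable site deserves honesty: a backbone is placed so that a
serine χ₁ = −60° rotamer gains a polar contact to a ligand hydroxyl
(O3 for a sorbitol fixture; O5 — an epimer-conserved oxygen — when the
fixture carries allitol destined for a ligand swap), then the site is
mutated to valine. The site also defines a small-residue design
alphabet (ALA/VAL/CYS/SER/THR) as part of its ground truth, and
generation verifies by full enumeration that the minimum-energy
assignment over that alphabet gains the contact. The restriction is
load-bearing: in an open vacuum pocket, dispersion always rewards the
bulkiest side chain, so over all twenty identities the optimum need not
be the contact-gaining one. The fixture therefore demonstrates that the
optimizer *finds* a planted polar-gain optimum — not that polar gain
dominates design in real, solvated, tightly packed pockets.

More generally: fixtures are isolated residues floating around a
ligand. They exercise the geometry, bookkeeping and optimization
machinery exactly, but they have no peptide connectivity between
pocket residues, no protein core, no solvent, and no crystallographic
noise. Passing tests validate the machinery, not the biology.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script run at desk scale: pockets
of 4–6 residues plus a 12-heavy-atom ligand (≈ 60 atoms), annealing
runs of 40–150 steps, relax with 1 cycle of 3 ramp stages, Metropolis
frequency checks at 10⁵ trials, and transform-oracle sampling at 10⁴
candidates. Key tolerances: Kabsch recovery asserted at 1e-8; docking
convergence 1e-4 Å; torsion-refinement convergence 1e-6 Å²; minimizer
sweep tolerance 1e-4 with step halving down to 1e-5 rad; energy
breakdown internally consistent to 1e-9. Degenerate inputs fail loudly
rather than silently: empty structures, absent chains or het codes,
collinear superposition inputs, unknown residue types (warning + skip
in contact typing; error with the offending atom listed in energy
typing), non-finite starting energies, and infeasible fixture
plantings.

## Open choices made here

* Which monomer of a dimer to keep is not determined by the workflow;
  the first chain is the default and a flag selects another.
* The original sculpting procedure's starting sorbitol conformer is
  unknown; it is irrelevant after backbone alignment, so the builder's
  extended conformer is used.
* Whether backbone minimization should also move side chains is
  ambiguous in the source procedure; both are exposed
  (`chiTorsions()` selections are caller-controlled).
* The 18-residue all-pocket design set of the original experiment is
  recomputed from geometry (`residuesWithin` at 4 Å) rather than taken
  as a list.

## Limitations

No solvation, no entropy, no explicit hydrogens, no backbone
flexibility during design, idealized ring geometry, a coarse rotamer
library, and an energy scale that is internally consistent but not
comparable to any published scorefunction. The package reproduces a
*procedure* — swap, count polar bonds, redesign, evaluate a ΔΔG cycle —
with every step specified and testable; it does not predict binding
affinities.
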