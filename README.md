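# PocketSwap

In-silico redesign of a protein binding pocket around a stereoisomer of
its natural ligand.

The motivating system is the *Agrobacterium vitis* ABC-transporter
solute-binding protein (SBP), a periplasmic "Venus flytrap" receptor
that binds the hexitol **allitol**. **Sorbitol** (D-glucitol) — the sugar
alcohol that accumulates in tissues with sorbitol-dehydrogenase
deficiency and drives cataract formation and peripheral neuropathy — is
the **C3 epimer** of allitol: same formula C6H14O6, same six-carbon
chain with one hydroxyl per carbon, inverted configuration at exactly
one stereocenter. A pocket evolved for allitol is therefore one hydroxyl
flip away from a sorbitol scavenger, and the engineering question is
whether a few pocket mutations make sorbitol binding *more* favorable.

PocketSwap implements that workflow end to end:

1. **Structure handling** — parse PDB files, extract one monomer of a
   crystallographic dimer, pull the bound ligand out of the complex
   (`readPdb`, `extractMonomer`, `extractLigand`, `writePdb`).
2. **Ligand building** — construct ideal-geometry linear alditols with
   explicit R/S stereo descriptors per internal carbon
   (`buildAlditol`, `stereoDescriptors`, `buildSorbitol`).
3. **Backbone-guided docking** — place the new ligand by least-squares
   (Kabsch) superposition of the six-carbon backbones, refine the
   hydroxyl torsions against the crystal pose (all but the epimeric C3
   hydroxyl), iterate to convergence, then swap the ligands
   (`dockByBackbone`, `swapLigand`).
4. **Contact analysis** — select pocket residues within 4 Å of the
   ligand and detect polar contacts (heavy-atom hydrogen-bond proxies:
   N/O/S donor–acceptor pairs at 2.4–3.5 Å with antecedent angles
   ≥ 90°) (`residuesWithin`, `polarContacts`, `contactReport`).
5. **Reduced energy model** — a self-contained heavy-atom score in
   reduced units: Lennard-Jones + screened Coulomb with a switched 10 Å
   cutoff, a −1 square-well per geometric hydrogen bond, and a 3-fold
   side-chain torsion penalty (`scoreEnergy`, `scoreParts`).
6. **Pocket design** — fixed-backbone mutation/repacking by Metropolis
   simulated annealing over a rotamer library under resfile-style
   NATRO/NATAA/ALLAA modes, plus torsion-space minimization and a
   repack-and-minimize relax protocol (`packResidues`,
   `minimizeTorsions`, `relaxComplex`, `repeatOptimize`).
7. **Thermodynamic cycle** — the binding bookkeeping

   ```
   dG_bind  = G_C  - (G_P  + G_L)
   dG*_bind = G_C* - (G_P* + G_L)
   ddG_bind = G_C* - G_P* - G_C + G_P        (G_L cancels)
   ```

   with `ddG_bind < 0` meaning the redesigned pocket binds the ligand
   more favorably (`ddgBind`, `isFavorable`, `cycleReport`).
8. **Synthetic fixtures** — pockets generated around a built alditol
   with residues planted at exact donor–acceptor distances, so contact
   counts and design behaviour are known by construction
   (`makePocket`, `makeDimer`, `makeStereoPair`).
9. **Pipeline driver** — `runPipeline()` chains the stages and writes
   every intermediate structure under its lineage nickname (`protein`,
   `allitol`, `sorbitol`, `proall`, `prosor`, `minprosor`, `finprosor`,
   `fastprosor`) plus a JSON manifest. A thin shell wrapper with
   subcommands lives in `inst/cli/pocketswap`.

## Worked example

Build a synthetic allitol pocket, dock sorbitol into it, and inspect the
contacts and energies:

```r
library(PocketSwap)

spec <- new("FixtureSpec", seed = 1L, nPocketResidues = 5L,
            plantedContacts = data.frame(resName = c("HIS", "ARG", "GLN"),
                                         distance = c(2.9, 3.0, 3.1)),
            designableSite = TRUE, ligandName = "X9X")
pocket <- makePocket(spec)
pocket$model
#> PdbStructure: 56 atoms, 1 chain(s), 6 residues
#>   heteroatom residues: X9X

srb <- buildSorbitol()
molecularFormula(srb)
#>  C  H  O
#>  6 14  6
descriptors(stereoDescriptors(srb))    # allitol is S S R R: C3 epimer
#>   2   3   4   5
#> "S" "R" "R" "R"

placed <- dockByBackbone(dropHydrogens(srb),
                         extractLigand(pocket$model, "X9X"))
attr(placed, "rmsd")                   # backbone fit, Angstrom
#> 3.17e-16

prosor <- swapLigand(pocket$model, "X9X", placed)
sor <- extractLigand(prosor, "SOR")
rep <- contactReport(polarContacts(prosor, sor),
                     pocketResidues = residuesWithin(prosor, sor, 4.0))
rep$table
#>   chainId resSeq resName before delta
#> 1       A     10     HIS      1     0
#> 2       A     20     ARG      1     0
#> 3       A     30     GLN      1     0
#> 4       A     40     VAL      0     0
#> 5             NA   TOTAL      3     0
rep$potential                          # the redesign targets
#>   chainId resSeq resName
#> 1       A     40     VAL

round(scoreParts(prosor, "SOR"), 3)    # reduced units
#>     GC     GP     GL
#> 95.221 89.665 10.881
```

The three planted polar residues each make exactly one hydrogen-bond
proxy to the docked ligand; the valine at residue 40 sits inside the
4 Å pocket with no polar contact — the "potential for polar bonds"
site that `packResidues()` can redesign (on this fixture it selects a
serine rotamer that gains a contact and lowers the complex energy).

The published state energies for the selectively mutated SBP complex
flow through the same cycle arithmetic:

```r
ddg <- ddgBind(GC = -140.67, GP = -171.51,
               GCstar = -224.80, GPstar = -228.27)
ddg
#> [1] -27.37
isFavorable(ddg)
#> [1] "favorable"
```

## Scope notes

Absolute energies from external scorefunctions are not reproduced; the
package defines its own reduced energy model and treats published
absolute scores purely as inputs to the ΔΔG arithmetic (`cycleReport`
marks them as `supplied`). Docking is the backbone-superposition recipe,
not a pose search; design is fixed-backbone. See the methods vignette
(`vignettes/pocket-redesign.Rmd`) for the model, its assumptions, and
its limitations.
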