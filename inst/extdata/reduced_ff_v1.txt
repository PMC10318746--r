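# PocketSwap reduced force field, version 1
#
# Heavy-atom (hydrogen-free) score in reduced energy units:
#   E = LJ + Coulomb + Hbond + Torsion
# LJ: 4*eps*((sigma/r)^12 - (sigma/r)^6), Lorentz-Berthelot mixing,
#     cutoff with CHARMM-style switching between switchStart and cutoff.
# Coulomb: coulombConstant * qi * qj / (dielectricSlope * r^2)
#     (distance-dependent dielectric eps(r) = dielectricSlope * r).
# Hbond: hbondEnergy per geometric polar contact (donor/acceptor heavy
#     atoms inside the polar distance window with antecedent angle >= 90).
#     Hydrogen-bonded pairs are dropped from the Coulomb sum: the well
#     replaces the bare donor-acceptor charge product, which would
#     register as repulsion with the bridging proton absent.
# Torsion: torsionK * (1 + cos(3*phi)) per side-chain / ligand C-C bond.
#
# Record kinds:
#   PARAM  <key> <value>
#   TYPE   <type> <sigma Angstrom> <epsilon reduced>
#   CHARGE <resName|*> <atomName> <type> <charge e>
# A '*' residue name is the backbone template shared by all amino acids.
# Implicit-hydrogen charges are absorbed into the bonded heavy atom, so
# neutral side chains sum to zero and charged ones to +/-1.

PARAM dielectricSlope 4.0
PARAM coulombConstant 332.0
PARAM hbondEnergy -1.0
PARAM torsionK 0.2
PARAM cutoff 10.0
PARAM switchStart 8.0
PARAM scale14 0.5

TYPE C3 3.80 0.10
TYPE C2 3.75 0.10
TYPE NP 3.25 0.17
TYPE NC 3.25 0.17
TYPE OH 3.00 0.17
TYPE OC 2.96 0.21
TYPE S  3.55 0.25

# backbone (all amino acids)
CHARGE * N   NP -0.30
CHARGE * CA  C3  0.25
CHARGE * C   C2  0.50
CHARGE * O   OC -0.45
CHARGE * OXT OC -0.45

CHARGE ALA CB  C3  0.00

CHARGE ARG CB  C3  0.00
CHARGE ARG CG  C3  0.00
CHARGE ARG CD  C3  0.00
CHARGE ARG NE  NP  0.12
CHARGE ARG CZ  C2  0.40
CHARGE ARG NH1 NC  0.24
CHARGE ARG NH2 NC  0.24

CHARGE ASN CB  C3  0.30
CHARGE ASN CG  C2  0.55
CHARGE ASN OD1 OC -0.55
CHARGE ASN ND2 NP -0.30

CHARGE ASP CB  C3  0.00
CHARGE ASP CG  C2  0.36
CHARGE ASP OD1 OC -0.68
CHARGE ASP OD2 OC -0.68

CHARGE CYS CB  C3  0.15
CHARGE CYS SG  S  -0.15

CHARGE GLN CB  C3  0.00
CHARGE GLN CG  C3  0.30
CHARGE GLN CD  C2  0.55
CHARGE GLN OE1 OC -0.55
CHARGE GLN NE2 NP -0.30

CHARGE GLU CB  C3  0.00
CHARGE GLU CG  C3  0.00
CHARGE GLU CD  C2  0.36
CHARGE GLU OE1 OC -0.68
CHARGE GLU OE2 OC -0.68

# GLY has no side chain

CHARGE HIS CB  C3  0.00
CHARGE HIS CG  C2  0.20
CHARGE HIS ND1 NP -0.30
CHARGE HIS CD2 C2  0.15
CHARGE HIS CE1 C2  0.25
CHARGE HIS NE2 NP -0.30

CHARGE ILE CB  C3  0.00
CHARGE ILE CG1 C3  0.00
CHARGE ILE CG2 C3  0.00
CHARGE ILE CD1 C3  0.00

CHARGE LEU CB  C3  0.00
CHARGE LEU CG  C3  0.00
CHARGE LEU CD1 C3  0.00
CHARGE LEU CD2 C3  0.00

CHARGE LYS CB  C3  0.00
CHARGE LYS CG  C3  0.00
CHARGE LYS CD  C3  0.00
CHARGE LYS CE  C3  0.25
CHARGE LYS NZ  NC  0.75

CHARGE MET CB  C3  0.05
CHARGE MET CG  C3  0.05
CHARGE MET SD  S  -0.15
CHARGE MET CE  C3  0.05

CHARGE PHE CB  C3  0.00
CHARGE PHE CG  C2  0.00
CHARGE PHE CD1 C2  0.00
CHARGE PHE CD2 C2  0.00
CHARGE PHE CE1 C2  0.00
CHARGE PHE CE2 C2  0.00
CHARGE PHE CZ  C2  0.00

CHARGE PRO CB  C3  0.00
CHARGE PRO CG  C3  0.00
CHARGE PRO CD  C3  0.05

CHARGE SER CB  C3  0.30
CHARGE SER OG  OH -0.30

CHARGE THR CB  C3  0.30
CHARGE THR OG1 OH -0.30
CHARGE THR CG2 C3  0.00

CHARGE TRP CB  C3  0.00
CHARGE TRP CG  C2  0.00
CHARGE TRP CD1 C2  0.15
CHARGE TRP NE1 NP -0.30
CHARGE TRP CD2 C2  0.00
CHARGE TRP CE2 C2  0.15
CHARGE TRP CE3 C2  0.00
CHARGE TRP CZ2 C2  0.00
CHARGE TRP CZ3 C2  0.00
CHARGE TRP CH2 C2  0.00

CHARGE TYR CB  C3  0.00
CHARGE TYR CG  C2  0.00
CHARGE TYR CD1 C2  0.00
CHARGE TYR CD2 C2  0.00
CHARGE TYR CE1 C2  0.00
CHARGE TYR CE2 C2  0.00
CHARGE TYR CZ  C2  0.30
CHARGE TYR OH  OH -0.30

CHARGE VAL CB  C3  0.00
CHARGE VAL CG1 C3  0.00
CHARGE VAL CG2 C3  0.00

# linear alditol ligand templates (het codes SOR, X9X, generic LIG):
# each backbone carbon +0.30 paired with its hydroxyl oxygen -0.30
CHARGE SOR C1 C3 0.30
CHARGE SOR C2 C3 0.30
CHARGE SOR C3 C3 0.30
CHARGE SOR C4 C3 0.30
CHARGE SOR C5 C3 0.30
CHARGE SOR C6 C3 0.30
CHARGE SOR O1 OH -0.30
CHARGE SOR O2 OH -0.30
CHARGE SOR O3 OH -0.30
CHARGE SOR O4 OH -0.30
CHARGE SOR O5 OH -0.30
CHARGE SOR O6 OH -0.30
CHARGE X9X C1 C3 0.30
CHARGE X9X C2 C3 0.30
CHARGE X9X C3 C3 0.30
CHARGE X9X C4 C3 0.30
CHARGE X9X C5 C3 0.30
CHARGE X9X C6 C3 0.30
CHARGE X9X O1 OH -0.30
CHARGE X9X O2 OH -0.30
CHARGE X9X O3 OH -0.30
CHARGE X9X O4 OH -0.30
CHARGE X9X O5 OH -0.30
CHARGE X9X O6 OH -0.30
CHARGE LIG C1 C3 0.30
CHARGE LIG C2 C3 0.30
CHARGE LIG C3 C3 0.30
CHARGE LIG C4 C3 0.30
CHARGE LIG C5 C3 0.30
CHARGE LIG C6 C3 0.30
CHARGE LIG O1 OH -0.30
CHARGE LIG O2 OH -0.30
CHARGE LIG O3 OH -0.30
CHARGE LIG O4 OH -0.30
CHARGE LIG O5 OH -0.30
CHARGE LIG O6 OH -0.30
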