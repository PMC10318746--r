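#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "altLoc", "resName", "chainId", "resSeq",
                "x", "y", "z", "occupancy", "bFactor", "element", "recordKind")

.emptyAtomTable <- function() {
  data.frame(serial = integer(0), name = character(0), altLoc = character(0),
             resName = character(0), chainId = character(0), resSeq = integer(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occupancy = numeric(0), bFactor = numeric(0),
             element = character(0), recordKind = character(0),
             stringsAsFactors = FALSE)
}

.validAtomTable <- function(df) {
  msgs <- character(0)
  miss <- setdiff(.ATOM_COLS, names(df))
  if (length(miss))
    msgs <- c(msgs, paste0("atom table missing columns: ",
                           paste(miss, collapse = ", ")))
  if (!length(msgs) && nrow(df)) {
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
      msgs <- c(msgs, "atom coordinates must be finite")
    occ <- df$occupancy[!is.na(df$occupancy)]
    if (length(occ) && (any(occ < 0) || any(occ > 1)))
      msgs <- c(msgs, "occupancy must lie in [0, 1]")
    if (!all(df$recordKind %in% c("ATOM", "HETATM")))
      msgs <- c(msgs, "recordKind must be ATOM or HETATM")
  }
  msgs
}

#' Hierarchical protein structure model
#'
#' An ordered table of ATOM/HETATM records parsed from a PDB file, with
#' chains and residues derived by grouping on (chainId, resSeq, resName).
#' One row per atom; coordinates in Angstrom.
#'
#' @slot atoms data.frame with one row per atom and columns
#'   serial, name, altLoc, resName, chainId, resSeq, x, y, z,
#'   occupancy, bFactor, element, recordKind.
#' @seealso [readPdb()], [writePdb()], [extractMonomer()], [extractLigand()]
#' @export
setClass("PdbStructure", representation(atoms = "data.frame"),
         prototype(atoms = .emptyAtomTable()),
         validity = function(object) {
           msgs <- .validAtomTable(object@atoms)
           if (length(msgs)) msgs else TRUE
         })

#' Small-molecule ligand with bond graph and stereo descriptors
#'
#' Atoms plus a perceived covalent bond graph. For linear alditols the
#' carbon backbone is identified (ordered C1..Cn), each backbone carbon is
#' mapped to its hydroxyl oxygen, and R/S descriptors are assigned to the
#' internal carbons.
#'
#' @slot atoms data.frame in the same layout as [PdbStructure-class].
#' @slot bonds two-column integer matrix of atom row indices (i < j).
#' @slot backbone integer vector of atom row indices, ordered C1..Cn.
#' @slot hydroxylMap named integer vector mapping backbone position
#'   ("1".."n") to the row index of the attached oxygen.
#' @slot stereo named character vector of R/S descriptors for the internal
#'   backbone carbons ("2".."n-1").
#' @export
setClass("Ligand", representation(atoms = "data.frame", bonds = "matrix",
                                  backbone = "integer", hydroxylMap = "integer",
                                  stereo = "character"),
         prototype(atoms = .emptyAtomTable(),
                   bonds = matrix(integer(0), ncol = 2),
                   backbone = integer(0), hydroxylMap = integer(0),
                   stereo = character(0)),
         validity = function(object) {
           msgs <- .validAtomTable(object@atoms)
           b <- object@bonds
           if (ncol(b) != 2) msgs <- c(msgs, "bonds must have two columns")
           else if (nrow(b) && (max(b) > nrow(object@atoms) || min(b) < 1))
             msgs <- c(msgs, "bond indices out of range")
           if (length(msgs)) msgs else TRUE
         })

#' Stereochemical configuration of a linear alditol
#'
#' Ordered R/S assignments for the internal carbons (C2..C5 of a hexitol).
#'
#' @slot descriptors character vector of "R"/"S", one per internal carbon.
#' @export
setClass("StereoConfig", representation(descriptors = "character"),
         validity = function(object) {
           if (!all(object@descriptors %in% c("R", "S")))
             return("descriptors must be 'R' or 'S'")
           TRUE
         })

#' Proper rigid-body transform
#'
#' Applied to row-vector coordinates as `x %*% rotation + translation`.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#' @export
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"),
         prototype(rotation = diag(3), translation = c(0, 0, 0)),
         validity = function(object) {
           if (!all(dim(object@rotation) == c(3, 3)))
             return("rotation must be 3x3")
           if (abs(det(object@rotation) - 1) > 1e-8)
             return("rotation must be proper (det = +1)")
           if (max(abs(crossprod(object@rotation) - diag(3))) > 1e-8)
             return("rotation must be orthonormal")
           if (length(object@translation) != 3)
             return("translation must have length 3")
           TRUE
         })

#' Geometric criteria for pocket selection and polar contacts
#'
#' Heavy-atom hydrogen-bond proxy: donor/acceptor N, O (and CYS S) pairs
#' with separation inside a distance window and, in the absence of
#' hydrogens, an antecedent angle requirement (X-D...A with X the bonded
#' heavy-atom antecedent of each polar atom).
#'
#' @slot neighborCutoff Angstrom; pocket residue selection radius.
#' @slot polarDistanceMax Angstrom; maximum donor-acceptor separation.
#' @slot polarDistanceMin Angstrom; minimum donor-acceptor separation.
#' @slot angleMin degrees; minimum heavy-atom antecedent angle.
#' @slot includeBackbone logical; also consider backbone N/O atoms.
#' @export
setClass("ContactCriteria",
         representation(neighborCutoff = "numeric", polarDistanceMax = "numeric",
                        polarDistanceMin = "numeric", angleMin = "numeric",
                        includeBackbone = "logical"),
         prototype(neighborCutoff = 4.0, polarDistanceMax = 3.5,
                   polarDistanceMin = 2.4, angleMin = 90, includeBackbone = TRUE),
         validity = function(object) {
           if (!(object@polarDistanceMin > 0 &&
                 object@polarDistanceMin < object@polarDistanceMax))
             return("require 0 < polarDistanceMin < polarDistanceMax")
           if (!is.finite(object@neighborCutoff) || object@neighborCutoff < 0)
             return("neighborCutoff must be finite and >= 0")
           TRUE
         })

#' Energy decomposition in reduced units
#'
#' @slot lj,coulomb,hbond,torsion,total numeric, reduced energy units;
#'   total equals the component sum.
#' @export
setClass("EnergyBreakdown",
         representation(lj = "numeric", coulomb = "numeric", hbond = "numeric",
                        torsion = "numeric", total = "numeric"),
         prototype(lj = 0, coulomb = 0, hbond = 0, torsion = 0, total = 0),
         validity = function(object) {
           s <- object@lj + object@coulomb + object@hbond + object@torsion
           if (is.finite(s) && abs(s - object@total) > 1e-9)
             return("total must equal the sum of components")
           TRUE
         })

#' Reduced force-field parameter set
#'
#' Heavy-atom Lennard-Jones types, per-residue template partial charges, a
#' distance-dependent dielectric, and a square-well geometric hydrogen-bond
#' term. Loaded from the plain-text parameter file shipped with the package
#' (see [defaultForceField()]).
#'
#' @slot types data.frame: type, sigma (Angstrom), epsilon (reduced).
#' @slot charges data.frame: resName, atomName, type, charge.
#' @slot dielectricSlope numeric D in eps(r) = D * r.
#' @slot coulombConstant numeric prefactor, reduced units.
#' @slot hbondEnergy numeric well depth per geometric polar contact (<= 0).
#' @slot torsionK numeric 3-fold torsion barrier height.
#' @slot cutoff,switchStart numeric Angstrom; nonbonded cutoff and start of
#'   the switching region.
#' @slot scale14 numeric multiplier on 1-4 nonbonded interactions.
#' @slot ljRepulsiveScale numeric multiplier on the r^-12 repulsion (used
#'   by the relax protocol's ramp).
#' @slot version character tag of the parameter file.
#' @export
setClass("ForceFieldParams",
         representation(types = "data.frame", charges = "data.frame",
                        dielectricSlope = "numeric", coulombConstant = "numeric",
                        hbondEnergy = "numeric", torsionK = "numeric",
                        cutoff = "numeric", switchStart = "numeric",
                        scale14 = "numeric", ljRepulsiveScale = "numeric",
                        version = "character"),
         validity = function(object) {
           if (nrow(object@types) &&
               (any(object@types$sigma <= 0) || any(object@types$epsilon <= 0)))
             return("sigma and epsilon must be positive")
           if (object@switchStart >= object@cutoff)
             return("switchStart must be below cutoff")
           TRUE
         })

#' Per-residue design modes (the resfile analogue)
#'
#' Modes: NATRO (native rotamer, untouched), NATAA (native amino acid,
#' repackable), ALLAA (any amino acid, repackable).
#'
#' @slot residues data.frame: chainId, resSeq, mode.
#' @slot defaultMode mode applied to unlisted residues.
#' @export
setClass("DesignSpec",
         representation(residues = "data.frame", defaultMode = "character"),
         prototype(residues = data.frame(chainId = character(0),
                                         resSeq = integer(0),
                                         mode = character(0),
                                         stringsAsFactors = FALSE),
                   defaultMode = "NATRO"),
         validity = function(object) {
           ok <- c("NATRO", "NATAA", "ALLAA")
           if (!(object@defaultMode %in% ok))
             return("defaultMode must be NATRO, NATAA or ALLAA")
           if (nrow(object@residues) && !all(object@residues$mode %in% ok))
             return("modes must be NATRO, NATAA or ALLAA")
           TRUE
         })

#' Simulated-annealing schedule for rotamer packing
#'
#' Geometric cooling from kTStart to kTEnd over nSteps Metropolis steps.
#'
#' @slot kTStart,kTEnd numeric reduced temperatures, kTStart >= kTEnd > 0.
#' @slot nSteps integer >= 1.
#' @slot seed integer random seed.
#' @export
setClass("AnnealingSchedule",
         representation(kTStart = "numeric", kTEnd = "numeric",
                        nSteps = "integer", seed = "integer"),
         prototype(kTStart = 100, kTEnd = 0.3, nSteps = 250L, seed = 1L),
         validity = function(object) {
           if (!(object@kTStart >= object@kTEnd && object@kTEnd > 0))
             return("require kTStart >= kTEnd > 0")
           if (object@nSteps < 1L) return("nSteps must be >= 1")
           TRUE
         })

#' Side-chain rotamer library
#'
#' Per amino acid, a list of chi-angle tuples (degrees in (-180, 180])
#' with prior weights.
#'
#' @slot rotamers named list; each element a list with `chi` (numeric
#'   matrix, one row per rotamer) and `weight` (numeric vector).
#' @export
setClass("RotamerLibrary", representation(rotamers = "list"),
         validity = function(object) {
           for (aa in names(object@rotamers)) {
             r <- object@rotamers[[aa]]
             if (!nrow(r$chi)) return(paste0("amino acid ", aa, " has no rotamers"))
             if (nrow(r$chi) && any(r$chi <= -180 | r$chi > 180))
               return("chi angles must lie in (-180, 180]")
           }
           TRUE
         })

#' Binding thermodynamic cycle
#'
#' State energies of the wild-type complex (GC), wild-type apo protein
#' (GP), free ligand (GL, may be NA: it cancels in ddG), mutant complex
#' (GCstar) and mutant apo protein (GPstar), all in reduced units.
#'
#' @slot GC,GP,GL,GCstar,GPstar numeric; GL may be NA_real_.
#' @export
setClass("ThermodynamicCycle",
         representation(GC = "numeric", GP = "numeric", GL = "numeric",
                        GCstar = "numeric", GPstar = "numeric"),
         prototype(GC = NA_real_, GP = NA_real_, GL = NA_real_,
                   GCstar = NA_real_, GPstar = NA_real_),
         validity = function(object) {
           for (s in c("GC", "GP", "GCstar", "GPstar")) {
             v <- slot(object, s)
             if (!is.na(v) && !is.finite(v))
               return(paste0(s, " must be finite or NA"))
           }
           TRUE
         })

#' Specification for a synthetic pocket fixture
#'
#' Describes a pocket to generate around a built alditol: residues planted
#' at exact nearest-atom distances (polar identities create polar contacts
#' by construction), an optional steric clash, an optional designable site
#' that can gain a polar contact through mutation, and optional
#' dimerization.
#'
#' @slot seed integer; all generator randomness derives from it.
#' @slot nPocketResidues integer; total residues (fillers added if needed).
#' @slot plantedContacts data.frame: resName, distance (Angstrom, the
#'   nearest-heavy-atom distance to the ligand).
#' @slot plantedClash logical; plant one side chain overlapping the ligand.
#' @slot designableSite logical; plant a site that gains a contact only
#'   under mutation.
#' @slot dimerize logical; duplicate the assembly as a second chain.
#' @slot ligandName three-letter het code of the built ligand.
#' @export
setClass("FixtureSpec",
         representation(seed = "integer", nPocketResidues = "integer",
                        plantedContacts = "data.frame", plantedClash = "logical",
                        designableSite = "logical", dimerize = "logical",
                        ligandName = "character"),
         prototype(seed = 1L, nPocketResidues = 0L,
                   plantedContacts = data.frame(resName = character(0),
                                                distance = numeric(0),
                                                stringsAsFactors = FALSE),
                   plantedClash = FALSE, designableSite = FALSE,
                   dimerize = FALSE, ligandName = "SOR"),
         validity = function(object) {
           d <- object@plantedContacts$distance
           if (length(d) && (any(d < 2.4) || any(d > 10)))
             return("planted distances must lie in [2.4, 10] Angstrom")
           TRUE
         })
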