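# PDB structure input/output and monomer/ligand extraction.

.WATER_CODES <- c("HOH", "WAT", "DOD")

.elementFromName <- function(name, resName) {
  # PDB convention: the element is the leading alphabetic part of the atom
  # name once digits are stripped; two-letter elements only for a small set.
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  if (two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &&
      nchar(nm) == 2 && !(resName %in% .AA3))
    return(two)
  first <- regmatches(nm, regexpr("[A-Z]", nm))
  if (length(first)) first else "X"
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.newStructure <- function(atoms) {
  rownames(atoms) <- NULL
  new("PdbStructure", atoms = atoms)
}

#' Read a PDB file into a structure model
#'
#' Parses fixed-column ATOM/HETATM records (first MODEL only). Waters are
#' dropped by default and alternate locations other than blank or 'A' are
#' discarded, the common single-conformer convention.
#'
#' @param path path to a PDB file.
#' @param keepWaters keep HOH/WAT residues? Default FALSE.
#' @param keepAltLocs keep all alternate-location indicators? Default FALSE
#'   (keep blank or 'A' only).
#' @return a [PdbStructure-class].
#' @examples
#' pocket <- makePocket(new("FixtureSpec", seed = 1L,
#'                          plantedContacts = data.frame(resName = "SER",
#'                                                       distance = 2.9)))
#' f <- tempfile(fileext = ".pdb")
#' writePdb(pocket$model, f)
#' readPdb(f)
#' @export
readPdb <- function(path, keepWaters = FALSE, keepAltLocs = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) stop("no ATOM or HETATM records in ", path)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altLoc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    resName = trimws(a$resid),
    chainId = ifelse(is.na(a$chain) | a$chain == "", "", a$chain),
    resSeq = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, pmin(1, pmax(0, a$o))),
    bFactor = ifelse(is.na(a$b), 0, a$b),
    element = ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
                     mapply(.elementFromName, a$elety, a$resid),
                     toupper(trimws(a$elesy))),
    recordKind = a$type,
    stringsAsFactors = FALSE)
  if (!keepAltLocs) atoms <- atoms[atoms$altLoc %in% c("", "A"), , drop = FALSE]
  if (!keepWaters) atoms <- atoms[!(atoms$resName %in% .WATER_CODES), , drop = FALSE]
  if (!nrow(atoms)) stop("no coordinate records left after filtering in ", path)
  .newStructure(atoms)
}

#' Write a structure model to a PDB file
#'
#' Emits fixed-column v3.3 ATOM/HETATM records so that a
#' `readPdb(writePdb(x))` round trip reproduces the atom table (coordinates
#' to the format's 3-decimal precision).
#'
#' @param model a [PdbStructure-class]; must contain at least one atom.
#' @param path output file path.
#' @return invisibly, the path written.
#' @export
writePdb <- function(model, path) {
  stopifnot(is(model, "PdbStructure"))
  a <- model@atoms
  if (!nrow(a)) stop("refusing to write an empty structure")
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     type = a$recordKind, eleno = a$serial, elety = a$name,
                     resid = a$resName, chain = a$chainId, resno = a$resSeq,
                     xyz = as.vector(t(.xyzMatrix(a))),
                     o = a$occupancy, b = a$bFactor, elesy = a$element)
    TRUE
  }, error = function(e) stop("cannot write PDB file '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Extract one monomer from a multi-chain structure
#'
#' Keeps the protein atoms of one chain together with heteroatom residues
#' assigned to it. Heteroatoms carrying the chain's id belong to it;
#' orphan heteroatoms (blank chain id) are assigned to the nearest protein
#' chain by minimum heavy-atom distance.
#'
#' @param model a [PdbStructure-class].
#' @param keepChain chain identifier to retain.
#' @return a [PdbStructure-class] restricted to that monomer.
#' @export
extractMonomer <- function(model, keepChain) {
  stopifnot(is(model, "PdbStructure"))
  a <- model@atoms
  if (!(keepChain %in% a$chainId))
    stop("chain '", keepChain, "' not present in the model")
  het <- a$recordKind == "HETATM"
  keep <- a$chainId == keepChain
  orphan <- het & a$chainId == ""
  if (any(orphan)) {
    prot <- a[a$recordKind == "ATOM", , drop = FALSE]
    pxyz <- .xyzMatrix(prot)
    ridx <- which(orphan)
    # indistinguishable copies (same code and number, blank chain) are
    # separated by record contiguity
    newBlock <- c(TRUE, diff(ridx) > 1 |
                    a$resSeq[ridx[-1]] != a$resSeq[ridx[-length(ridx)]] |
                    a$resName[ridx[-1]] != a$resName[ridx[-length(ridx)]])
    block <- cumsum(newBlock)
    for (b in unique(block)) {
      idx <- ridx[block == b]
      d <- .crossDist(.xyzMatrix(a[idx, , drop = FALSE]), pxyz)
      nearest <- prot$chainId[arrayInd(which.min(d), dim(d))[2]]
      if (nearest == keepChain) keep[idx] <- TRUE
    }
  }
  out <- a[keep, , drop = FALSE]
  if (!nrow(out)) stop("chain '", keepChain, "' selected no atoms")
  .newStructure(out)
}

.hetResidueIndex <- function(a, hetCode, chain = NULL) {
  sel <- a$recordKind == "HETATM" & a$resName == hetCode
  if (!is.null(chain)) sel <- sel & a$chainId == chain
  if (!any(sel)) stop("heteroatom residue '", hetCode, "' not found",
                      if (!is.null(chain)) paste0(" in chain ", chain))
  key <- paste(a$chainId, a$resSeq, sep = "\r")[sel]
  if (length(unique(key)) > 1)
    stop("multiple copies of '", hetCode,
         "' present; select one with the chain argument")
  which(sel)
}

#' Extract a heteroatom ligand as a Ligand object
#'
#' Pulls one HETATM residue out of the model (the source model is left
#' unchanged), perceives its covalent bond graph from interatomic
#' distances, and, for linear polyols, assigns the carbon backbone,
#' hydroxyl map and stereo descriptors. If several copies of the het code
#' are present, `chain` must disambiguate.
#'
#' @param model a [PdbStructure-class].
#' @param hetCode three-letter heteroatom residue code (e.g. "X9X", "SOR").
#' @param chain optional chain id selecting one copy.
#' @return a [Ligand-class].
#' @seealso [removeLigand()] for the complementary ligand-free structure.
#' @export
extractLigand <- function(model, hetCode, chain = NULL) {
  stopifnot(is(model, "PdbStructure"))
  idx <- .hetResidueIndex(model@atoms, hetCode, chain)
  asLigand(.newStructure(model@atoms[idx, , drop = FALSE]))
}

#' Remove a heteroatom ligand from a structure
#'
#' Companion of [extractLigand()]: the extracted ligand and the structure
#' returned here partition the original atoms.
#'
#' @inheritParams extractLigand
#' @return a [PdbStructure-class] without the ligand.
#' @export
removeLigand <- function(model, hetCode, chain = NULL) {
  stopifnot(is(model, "PdbStructure"))
  idx <- .hetResidueIndex(model@atoms, hetCode, chain)
  .newStructure(model@atoms[-idx, , drop = FALSE])
}
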