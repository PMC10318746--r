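#' Atom table accessor
#'
#' Returns the underlying atom table (one row per atom).
#'
#' @param x a [PdbStructure-class] or [Ligand-class].
#' @return data.frame of atom records.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "PdbStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Ligand", function(x) x@atoms)

#' Number of atoms
#' @param x a [PdbStructure-class] or [Ligand-class].
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "PdbStructure", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Ligand", function(x) nrow(x@atoms))

#' Chain identifiers present in a structure
#' @param x a [PdbStructure-class].
#' @return character vector of chain ids (protein chains first).
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname chainIds
#' @export
setMethod("chainIds", "PdbStructure", function(x) {
  a <- x@atoms
  unique(c(unique(a$chainId[a$recordKind == "ATOM"]), unique(a$chainId)))
})

#' Residue-level summary of a structure
#'
#' One row per (chainId, resSeq, resName) group in order of appearance,
#' with the atom count of each residue. The grouping partitions the atom
#' table.
#'
#' @param x a [PdbStructure-class].
#' @return data.frame with chainId, resSeq, resName, recordKind, nAtoms.
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname residueTable
#' @export
setMethod("residueTable", "PdbStructure", function(x) {
  a <- x@atoms
  if (!nrow(a)) {
    return(data.frame(chainId = character(0), resSeq = integer(0),
                      resName = character(0), recordKind = character(0),
                      nAtoms = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(a$chainId, a$resSeq, a$resName, sep = "\r")
  first <- !duplicated(key)
  data.frame(chainId = a$chainId[first], resSeq = a$resSeq[first],
             resName = a$resName[first], recordKind = a$recordKind[first],
             nAtoms = as.integer(table(key)[unique(key)]),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' Stereo descriptors accessor
#' @param x a [Ligand-class] or [StereoConfig-class].
#' @return named character vector of R/S descriptors.
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @rdname descriptors
#' @export
setMethod("descriptors", "StereoConfig", function(x) x@descriptors)

#' @rdname descriptors
#' @export
setMethod("descriptors", "Ligand", function(x) x@stereo)

setMethod("show", "PdbStructure", function(object) {
  rt <- residueTable(object)
  cat("PdbStructure:", nrow(object@atoms), "atoms,",
      length(unique(rt$chainId)), "chain(s),", nrow(rt), "residues\n")
  het <- rt[rt$recordKind == "HETATM", , drop = FALSE]
  if (nrow(het))
    cat("  heteroatom residues:",
        paste(unique(het$resName), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "Ligand", function(object) {
  f <- molecularFormula(object)
  cat("Ligand:", nrow(object@atoms), "atoms,", nrow(object@bonds), "bonds",
      if (length(f)) paste0("[", paste0(names(f), f, collapse = ""), "]"), "\n")
  if (length(object@stereo))
    cat("  stereo (C", paste(names(object@stereo), collapse = ", C"), "): ",
        paste(object@stereo, collapse = ", "), "\n", sep = "")
  invisible(object)
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown (reduced units): total %.4f\n", object@total))
  cat(sprintf("  lj %.4f | coulomb %.4f | hbond %.4f | torsion %.4f\n",
              object@lj, object@coulomb, object@hbond, object@torsion))
  invisible(object)
})

setMethod("show", "ThermodynamicCycle", function(object) {
  cat("ThermodynamicCycle (reduced units)\n")
  cat(sprintf("  GC %s  GP %s  GL %s  GC* %s  GP* %s\n",
              format(object@GC), format(object@GP),
              if (is.na(object@GL)) "unknown" else format(object@GL),
              format(object@GCstar), format(object@GPstar)))
  ok <- !is.na(object@GC) && !is.na(object@GP) &&
    !is.na(object@GCstar) && !is.na(object@GPstar)
  if (ok) {
    dd <- ddgBind(object)
    cat(sprintf("  ddG_bind = %.4f (%s)\n", dd, isFavorable(dd)))
  }
  invisible(object)
})
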