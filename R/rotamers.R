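# Idealized side-chain templates and the coarse rotamer library used by
# fixed-backbone design. Side chains are rebuilt from internal
# coordinates on the existing backbone (N, CA, C); ring geometry is
# idealized. Chi angles follow the usual convention (chi1 = N-CA-CB-G).

# Template rows: atom name, the three reference atoms (parent p1, p2,
# p3), bond length (A), bond angle (deg, at p1) and either a fixed
# dihedral (chi = 0) or an offset added to rotatable angle chi_k.
.tpl <- function(...) {
  args <- c(...)
  if (!length(args)) {
    return(data.frame(name = character(0), p1 = character(0),
                      p2 = character(0), p3 = character(0),
                      bond = numeric(0), angle = numeric(0),
                      dih = numeric(0), chi = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- matrix(args, ncol = 7, byrow = TRUE)
  data.frame(name = m[, 1], p1 = m[, 2], p2 = m[, 3], p3 = m[, 4],
             bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
             dih = as.numeric(sub("^chi[0-9]\\+?", "", sub("^chi[0-9]$", "0", m[, 7]))),
             chi = ifelse(grepl("^chi", m[, 7]),
                          as.integer(substr(m[, 7], 4, 4)), 0L),
             stringsAsFactors = FALSE)
}

.SIDECHAIN_TEMPLATES <- list(
  GLY = .tpl(),
  ALA = .tpl(),
  SER = .tpl("OG", "CB", "CA", "N", 1.42, 110.5, "chi1"),
  CYS = .tpl("SG", "CB", "CA", "N", 1.81, 114.0, "chi1"),
  THR = .tpl("OG1", "CB", "CA", "N", 1.43, 109.6, "chi1",
             "CG2", "CB", "CA", "N", 1.52, 110.5, "chi1+120"),
  VAL = .tpl("CG1", "CB", "CA", "N", 1.52, 110.5, "chi1",
             "CG2", "CB", "CA", "N", 1.52, 110.5, "chi1+-120"),
  LEU = .tpl("CG", "CB", "CA", "N", 1.53, 116.3, "chi1",
             "CD1", "CG", "CB", "CA", 1.52, 110.7, "chi2",
             "CD2", "CG", "CB", "CA", 1.52, 110.7, "chi2+-120"),
  ILE = .tpl("CG1", "CB", "CA", "N", 1.53, 110.4, "chi1",
             "CG2", "CB", "CA", "N", 1.52, 110.5, "chi1+120",
             "CD1", "CG1", "CB", "CA", 1.52, 113.8, "chi2"),
  MET = .tpl("CG", "CB", "CA", "N", 1.52, 114.0, "chi1",
             "SD", "CG", "CB", "CA", 1.80, 112.7, "chi2",
             "CE", "SD", "CG", "CB", 1.79, 100.9, "chi3"),
  PRO = .tpl("CG", "CB", "CA", "N", 1.49, 104.5, "chi1",
             "CD", "CG", "CB", "CA", 1.50, 105.5, "35"),
  PHE = .tpl("CG", "CB", "CA", "N", 1.50, 113.8, "chi1",
             "CD1", "CG", "CB", "CA", 1.39, 120.8, "chi2",
             "CD2", "CG", "CB", "CA", 1.39, 120.8, "chi2+180",
             "CE1", "CD1", "CG", "CB", 1.39, 121.0, "180",
             "CE2", "CD2", "CG", "CB", 1.39, 121.0, "180",
             "CZ", "CE1", "CD1", "CG", 1.39, 120.0, "0"),
  TYR = .tpl("CG", "CB", "CA", "N", 1.50, 113.8, "chi1",
             "CD1", "CG", "CB", "CA", 1.39, 120.8, "chi2",
             "CD2", "CG", "CB", "CA", 1.39, 120.8, "chi2+180",
             "CE1", "CD1", "CG", "CB", 1.39, 121.0, "180",
             "CE2", "CD2", "CG", "CB", 1.39, 121.0, "180",
             "CZ", "CE1", "CD1", "CG", 1.39, 120.0, "0",
             "OH", "CZ", "CE1", "CD1", 1.38, 120.0, "180"),
  TRP = .tpl("CG", "CB", "CA", "N", 1.50, 113.6, "chi1",
             "CD1", "CG", "CB", "CA", 1.37, 126.9, "chi2",
             "CD2", "CG", "CB", "CA", 1.43, 126.6, "chi2+180",
             "NE1", "CD1", "CG", "CB", 1.38, 110.2, "180",
             "CE2", "CD2", "CG", "CB", 1.41, 107.2, "180",
             "CE3", "CD2", "CG", "CB", 1.40, 133.9, "0",
             "CZ2", "CE2", "CD2", "CG", 1.40, 122.4, "180",
             "CZ3", "CE3", "CD2", "CG", 1.39, 118.6, "180",
             "CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, "0"),
  HIS = .tpl("CG", "CB", "CA", "N", 1.49, 113.8, "chi1",
             "ND1", "CG", "CB", "CA", 1.38, 122.7, "chi2",
             "CD2", "CG", "CB", "CA", 1.36, 131.0, "chi2+180",
             "CE1", "ND1", "CG", "CB", 1.32, 109.2, "180",
             "NE2", "CD2", "CG", "CB", 1.37, 107.2, "180"),
  ASP = .tpl("CG", "CB", "CA", "N", 1.52, 113.0, "chi1",
             "OD1", "CG", "CB", "CA", 1.25, 119.0, "chi2",
             "OD2", "CG", "CB", "CA", 1.25, 118.4, "chi2+180"),
  ASN = .tpl("CG", "CB", "CA", "N", 1.52, 112.7, "chi1",
             "OD1", "CG", "CB", "CA", 1.23, 120.8, "chi2",
             "ND2", "CG", "CB", "CA", 1.33, 116.5, "chi2+180"),
  GLU = .tpl("CG", "CB", "CA", "N", 1.52, 114.0, "chi1",
             "CD", "CG", "CB", "CA", 1.52, 112.6, "chi2",
             "OE1", "CD", "CG", "CB", 1.25, 118.0, "chi3",
             "OE2", "CD", "CG", "CB", 1.25, 118.0, "chi3+180"),
  GLN = .tpl("CG", "CB", "CA", "N", 1.52, 114.0, "chi1",
             "CD", "CG", "CB", "CA", 1.52, 112.6, "chi2",
             "OE1", "CD", "CG", "CB", 1.23, 120.8, "chi3",
             "NE2", "CD", "CG", "CB", 1.33, 116.5, "chi3+180"),
  LYS = .tpl("CG", "CB", "CA", "N", 1.52, 114.0, "chi1",
             "CD", "CG", "CB", "CA", 1.52, 111.3, "chi2",
             "CE", "CD", "CG", "CB", 1.52, 111.7, "chi3",
             "NZ", "CE", "CD", "CG", 1.49, 112.0, "chi4"),
  ARG = .tpl("CG", "CB", "CA", "N", 1.52, 114.0, "chi1",
             "CD", "CG", "CB", "CA", 1.52, 111.3, "chi2",
             "NE", "CD", "CG", "CB", 1.46, 112.0, "chi3",
             "CZ", "NE", "CD", "CG", 1.33, 124.2, "chi4",
             "NH1", "CZ", "NE", "CD", 1.33, 120.0, "0",
             "NH2", "CZ", "NE", "CD", 1.33, 120.0, "180"))

.nChi <- function(aa) {
  t <- .SIDECHAIN_TEMPLATES[[aa]]
  if (is.null(t) || !nrow(t)) 0L else max(t$chi)
}

#' Amino acids supported by the design machinery
#' @return character vector of three-letter codes.
#' @export
designableAminoAcids <- function() names(.SIDECHAIN_TEMPLATES)

#' Coarse built-in rotamer library
#'
#' Chi angles sampled at -60, 60 and 180 degrees per rotatable chi
#' (aromatic/planar chi2 at -90/90; proline restricted to its ring
#' pucker), full cartesian product, uniform prior weights. Swappable: any
#' [RotamerLibrary-class] with the same layout can be passed to the
#' design functions.
#'
#' @return a [RotamerLibrary-class].
#' @export
defaultRotamerLibrary <- function() {
  base <- c(-60, 60, 180)
  special <- list(PHE = list(2, c(-90, 90)), TYR = list(2, c(-90, 90)),
                  TRP = list(2, c(-90, 90)), HIS = list(2, c(-90, 90)),
                  ASP = list(2, c(-90, 90)), ASN = list(2, c(-90, 90)))
  rot <- list()
  for (aa in names(.SIDECHAIN_TEMPLATES)) {
    k <- .nChi(aa)
    if (k == 0L) {
      chi <- matrix(numeric(0), nrow = 1, ncol = 0)
    } else if (aa == "PRO") {
      chi <- matrix(c(-25, 25), ncol = 1)
    } else {
      vals <- rep(list(base), k)
      sp <- special[[aa]]
      if (!is.null(sp)) vals[[sp[[1]]]] <- sp[[2]]
      chi <- as.matrix(expand.grid(vals, KEEP.OUT.ATTRS = FALSE))
      dimnames(chi) <- NULL
    }
    rot[[aa]] <- list(chi = chi, weight = rep(1 / nrow(chi), nrow(chi)))
  }
  new("RotamerLibrary", rotamers = rot)
}

.residueRows <- function(atomTable, chain, resSeq) {
  which(atomTable$chainId == chain & atomTable$resSeq == resSeq &
          atomTable$recordKind == "ATOM")
}

.atomPos <- function(atomTable, rows, name) {
  i <- rows[atomTable$name[rows] == name]
  if (!length(i)) stop("atom ", name, " missing from residue")
  c(atomTable$x[i[1]], atomTable$y[i[1]], atomTable$z[i[1]])
}

# Build side-chain heavy atoms for amino acid `aa` on a backbone frame.
# Returns a named list of positions (CB first unless GLY).
.buildSideChain <- function(aa, posN, posCA, posC, chi) {
  tmpl <- .SIDECHAIN_TEMPLATES[[aa]]
  if (is.null(tmpl)) stop("no side-chain template for ", aa)
  out <- list()
  if (aa != "GLY")
    out$CB <- .placeInternal(posCA, posN, posC, 1.53, 110.4, 122.5)
  if (nrow(tmpl)) {
    pos <- c(list(N = posN, CA = posCA, C = posC), out)
    for (r in seq_len(nrow(tmpl))) {
      row <- tmpl[r, ]
      d <- if (row$chi > 0L) chi[row$chi] + row$dih else row$dih
      p <- .placeInternal(pos[[row$p1]], pos[[row$p2]], pos[[row$p3]],
                          row$bond, row$angle, d)
      pos[[row$name]] <- p
      out[[row$name]] <- p
    }
  }
  out
}

#' Current chi angles of a residue
#'
#' Measured from the coordinates using the template's chi-defining
#' quadruples; NA where atoms are missing.
#'
#' @param model a [PdbStructure-class].
#' @param chain,resSeq residue selector.
#' @return numeric vector of chi angles, degrees (length = number of
#'   rotatable chis of the residue type).
#' @export
residueChi <- function(model, chain, resSeq) {
  a <- model@atoms
  rows <- .residueRows(a, chain, resSeq)
  if (!length(rows)) stop("residue ", chain, "/", resSeq, " not found")
  aa <- a$resName[rows[1]]
  tmpl <- .SIDECHAIN_TEMPLATES[[aa]]
  k <- .nChi(aa)
  if (k == 0L) return(numeric(0))
  chis <- rep(NA_real_, k)
  for (ci in seq_len(k)) {
    row <- tmpl[tmpl$chi == ci & tmpl$dih == 0, ][1, ]
    ok <- tryCatch({
      p4 <- .atomPos(a, rows, row$name); p3 <- .atomPos(a, rows, row$p1)
      p2 <- .atomPos(a, rows, row$p2); p1 <- .atomPos(a, rows, row$p3)
      chis[ci] <- .dihedralDeg(p1, p2, p3, p4)
      TRUE
    }, error = function(e) FALSE)
  }
  chis
}

#' Mutate or repack one residue on a fixed backbone
#'
#' Replaces the residue's side chain with amino acid `newAA` built at chi
#' angles `chi`, keeping the backbone atoms (N, CA, C, O) at their input
#' coordinates, the standard fixed-backbone design move. Serial numbers
#' are renumbered. Proline is permitted as a target identity but flagged
#' with a warning, since its backbone ring constraint is only
#' approximated by the template.
#'
#' @param model a [PdbStructure-class].
#' @param chain,resSeq residue selector.
#' @param newAA three-letter code of the new identity.
#' @param chi numeric chi angles, degrees; default the first rotamer of
#'   [defaultRotamerLibrary()].
#' @param warnProline warn when mutating to PRO? Default TRUE.
#' @return a [PdbStructure-class] with the residue rebuilt.
#' @export
mutateResidue <- function(model, chain, resSeq, newAA, chi = NULL,
                          warnProline = TRUE) {
  stopifnot(is(model, "PdbStructure"))
  if (!(newAA %in% names(.SIDECHAIN_TEMPLATES)))
    stop("unsupported amino acid: ", newAA)
  if (newAA == "PRO" && warnProline)
    warning("mutation to PRO: backbone ring constraint only approximated")
  a <- model@atoms
  rows <- .residueRows(a, chain, resSeq)
  if (!length(rows)) stop("residue ", chain, "/", resSeq, " not found")
  if (is.null(chi)) {
    k <- .nChi(newAA)
    chi <- if (k) defaultRotamerLibrary()@rotamers[[newAA]]$chi[1, ] else numeric(0)
  }
  posN <- .atomPos(a, rows, "N"); posCA <- .atomPos(a, rows, "CA")
  posC <- .atomPos(a, rows, "C")
  side <- .buildSideChain(newAA, posN, posCA, posC, chi)
  keep <- rows[a$name[rows] %in% .BACKBONE_ATOMS]
  drop <- setdiff(rows, keep)
  bb <- a[keep, , drop = FALSE]
  bb$resName <- newAA
  newRows <- do.call(rbind, lapply(names(side), function(nm) {
    .mkAtom(0L, nm, .elementFromName(nm, newAA), side[[nm]], newAA,
            chainId = chain, resSeq = resSeq, recordKind = "ATOM")
  }))
  if (!is.null(newRows)) {
    newRows$occupancy <- 1; newRows$bFactor <- 0
  }
  res <- rbind(bb, newRows)
  before <- a[seq_len(nrow(a)) < min(rows) & !(seq_len(nrow(a)) %in% rows), ,
              drop = FALSE]
  after <- a[seq_len(nrow(a)) > max(rows) & !(seq_len(nrow(a)) %in% rows), ,
             drop = FALSE]
  out <- rbind(before, res, after)
  out$serial <- seq_len(nrow(out))
  .newStructure(out)
}
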