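# Pocket residue selection and polar-contact (hydrogen-bond proxy)
# detection. Crystal structures carry no hydrogens, so contacts are
# defined on donor/acceptor heavy atoms: N, O (and CYS/MET S as weak
# donors) separated by 2.4-3.5 Angstrom with an antecedent-angle check
# (the heavy-atom neighbour of each polar atom must sit at >= 90 degrees
# from the partner, a standing proxy for plausible hydrogen placement).

# Side-chain polar atoms per residue type. Backbone N/O are handled
# separately and flagged.
.SIDECHAIN_POLAR <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  HIS = c("ND1", "NE2"), LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  TRP = "NE1", MET = "SD")

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.isPolarProteinAtom <- function(atomTable, includeBackbone = TRUE) {
  nm <- atomTable$name
  rn <- atomTable$resName
  side <- mapply(function(n, r) {
    p <- .SIDECHAIN_POLAR[[r]]
    !is.null(p) && n %in% p
  }, nm, rn, USE.NAMES = FALSE)
  back <- nm %in% c("N", "O", "OXT") & rn %in% .AA3
  if (includeBackbone) side | back else side
}

#' Protein residues within a cutoff of the ligand
#'
#' A residue is included when any of its heavy atoms lies within `cutoff`
#' Angstrom of any ligand heavy atom. The selection is monotone in the
#' cutoff and equals the brute-force all-pairs distance filter.
#'
#' @param model a [PdbStructure-class] (protein ATOM records are used).
#' @param ligand a [Ligand-class] placed in the model frame.
#' @param cutoff Angstrom (the paper-style pocket definition uses 4.0).
#' @return data.frame with chainId, resSeq, resName and minDist, sorted
#'   by residue number.
#' @export
residuesWithin <- function(model, ligand, cutoff = 4.0) {
  stopifnot(is(model, "PdbStructure"), is(ligand, "Ligand"))
  lxyz <- .xyzMatrix(ligand@atoms[toupper(ligand@atoms$element) != "H", ,
                                  drop = FALSE])
  if (!nrow(lxyz)) stop("ligand has no heavy atoms")
  a <- model@atoms
  prot <- a[a$recordKind == "ATOM" & toupper(a$element) != "H", , drop = FALSE]
  if (!nrow(prot)) {
    return(data.frame(chainId = character(0), resSeq = integer(0),
                      resName = character(0), minDist = numeric(0),
                      stringsAsFactors = FALSE))
  }
  d <- .crossDist(.xyzMatrix(prot), lxyz)
  minPerAtom <- apply(d, 1, min)
  key <- paste(prot$chainId, prot$resSeq, prot$resName, sep = "\r")
  minPerRes <- tapply(minPerAtom, key, min)
  first <- !duplicated(key)
  out <- data.frame(chainId = prot$chainId[first], resSeq = prot$resSeq[first],
                    resName = prot$resName[first],
                    minDist = as.numeric(minPerRes[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[out$minDist <= cutoff, , drop = FALSE]
  out <- out[order(out$chainId, out$resSeq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyContactTable <- function() {
  data.frame(chainId = character(0), resSeq = integer(0),
             resName = character(0), proteinAtom = character(0),
             partnerAtom = character(0), partnerResSeq = integer(0),
             distance = numeric(0), backbone = logical(0),
             kind = character(0), stringsAsFactors = FALSE)
}

# Antecedent heavy atoms (bonded neighbours) of atom `i` in a coordinate
# table, found by covalent-distance perception against nearby atoms.
.antecedents <- function(xyz, elements, i) {
  rad <- .COVALENT_RADII[toupper(elements)]
  rad[is.na(rad)] <- 0.77
  d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  which(d < rad + rad[i] + 0.45 & d > 0.4 & seq_along(d) != i)
}

.angleOK <- function(xyz, elements, i, partnerPos, angleMin) {
  ante <- .antecedents(xyz, elements, i)
  ante <- ante[toupper(elements[ante]) != "H"]
  if (!length(ante)) return(TRUE)  # isolated polar atom: no constraint
  # small tolerance keeps exact-boundary geometries (e.g. ideal-geometry
  # 90-degree antecedents) stable under floating-point rigid motions
  all(vapply(ante, function(k) {
    .angleDeg(xyz[k, ], xyz[i, ], partnerPos) >= angleMin - 1e-6
  }, logical(1)))
}

#' Detect protein-ligand polar contacts
#'
#' One contact per donor/acceptor heavy-atom pair (protein polar atom x
#' ligand oxygen) meeting the distance window and the heavy-atom
#' antecedent angle criterion of `criteria`. Residues whose type has no
#' entry in the donor/acceptor table contribute nothing (a warning is
#' raised for unknown residue types carrying N/O side-chain atoms).
#'
#' @param model a [PdbStructure-class].
#' @param ligand a [Ligand-class] placed in the model frame.
#' @param criteria a [ContactCriteria-class].
#' @return data.frame of contacts: chainId, resSeq, resName, proteinAtom,
#'   partnerAtom, partnerResSeq, distance, backbone, kind.
#' @export
polarContacts <- function(model, ligand, criteria = new("ContactCriteria")) {
  stopifnot(is(model, "PdbStructure"), is(ligand, "Ligand"),
            is(criteria, "ContactCriteria"))
  a <- model@atoms
  prot <- a[a$recordKind == "ATOM" & toupper(a$element) != "H", , drop = FALSE]
  lat <- ligand@atoms[toupper(ligand@atoms$element) != "H", , drop = FALSE]
  if (!nrow(lat)) stop("ligand has no heavy atoms")
  unknown <- unique(prot$resName[!(prot$resName %in% .AA3)])
  if (length(unknown))
    warning("no donor/acceptor typing for residue type(s): ",
            paste(unknown, collapse = ", "), "; skipped")
  polar <- which(.isPolarProteinAtom(prot, criteria@includeBackbone) &
                   prot$resName %in% .AA3)
  ligPolar <- which(toupper(lat$element) %in% c("N", "O"))
  if (!length(polar) || !length(ligPolar)) return(.emptyContactTable())
  pxyz <- .xyzMatrix(prot); lxyz <- .xyzMatrix(lat)
  d <- .crossDist(pxyz[polar, , drop = FALSE],
                  lxyz[ligPolar, , drop = FALSE])
  hits <- which(d >= criteria@polarDistanceMin &
                  d <= criteria@polarDistanceMax, arr.ind = TRUE)
  if (!nrow(hits)) return(.emptyContactTable())
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    pi <- polar[hits[h, 1]]; li <- ligPolar[hits[h, 2]]
    if (!.angleOK(pxyz, prot$element, pi, lxyz[li, ], criteria@angleMin)) next
    if (!.angleOK(lxyz, lat$element, li, pxyz[pi, ], criteria@angleMin)) next
    rows[[length(rows) + 1]] <- data.frame(
      chainId = prot$chainId[pi], resSeq = prot$resSeq[pi],
      resName = prot$resName[pi], proteinAtom = prot$name[pi],
      partnerAtom = lat$name[li], partnerResSeq = lat$resSeq[li],
      distance = d[hits[h, 1], hits[h, 2]],
      backbone = prot$name[pi] %in% c("N", "O", "OXT"),
      kind = "protein-ligand", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.emptyContactTable())
  out <- do.call(rbind, rows)
  out <- out[order(out$chainId, out$resSeq, out$proteinAtom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect residue-residue polar contacts within a residue set
#'
#' Side-chain/backbone polar atoms of the listed residues are paired with
#' each other under the same geometric criteria as [polarContacts()].
#' Pairs within the same residue are skipped; each unordered pair is
#' counted once.
#'
#' @param model a [PdbStructure-class].
#' @param residues data.frame with chainId and resSeq columns selecting
#'   the residue set (e.g. from [residuesWithin()]).
#' @param criteria a [ContactCriteria-class].
#' @return contact data.frame in the [polarContacts()] layout with kind
#'   "residue-residue"; the partner columns describe the second residue.
#' @export
residuePolarContacts <- function(model, residues,
                                 criteria = new("ContactCriteria")) {
  stopifnot(is(model, "PdbStructure"), is(criteria, "ContactCriteria"))
  a <- model@atoms
  sel <- paste(a$chainId, a$resSeq) %in% paste(residues$chainId, residues$resSeq)
  prot <- a[sel & a$recordKind == "ATOM" & toupper(a$element) != "H", ,
            drop = FALSE]
  polar <- which(.isPolarProteinAtom(prot, criteria@includeBackbone) &
                   prot$resName %in% .AA3)
  if (length(polar) < 2) return(.emptyContactTable())
  xyz <- .xyzMatrix(prot)
  d <- .crossDist(xyz[polar, , drop = FALSE], xyz[polar, , drop = FALSE])
  rows <- list()
  for (u in seq_along(polar)) {
    for (v in seq_along(polar)) {
      if (v <= u) next
      i <- polar[u]; j <- polar[v]
      if (prot$chainId[i] == prot$chainId[j] &&
          prot$resSeq[i] == prot$resSeq[j]) next
      if (d[u, v] < criteria@polarDistanceMin ||
          d[u, v] > criteria@polarDistanceMax) next
      if (!.angleOK(xyz, prot$element, i, xyz[j, ], criteria@angleMin)) next
      if (!.angleOK(xyz, prot$element, j, xyz[i, ], criteria@angleMin)) next
      rows[[length(rows) + 1]] <- data.frame(
        chainId = prot$chainId[i], resSeq = prot$resSeq[i],
        resName = prot$resName[i], proteinAtom = prot$name[i],
        partnerAtom = prot$name[j], partnerResSeq = prot$resSeq[j],
        distance = d[u, v],
        backbone = prot$name[i] %in% c("N", "O", "OXT") ||
          prot$name[j] %in% c("N", "O", "OXT"),
        kind = "residue-residue", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyContactTable())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-residue polar-bond report across pipeline states
#'
#' Tabulates polar-contact counts per residue for up to three states
#' (before mutation, after mutation, after relax), with a totals row, and
#' lists pocket residues that make no contact in the "before" state but
#' lie within the neighbor cutoff: the residues with *potential* for
#' polar bonds, the redesign targets.
#'
#' @param before contact data.frame (see [polarContacts()]).
#' @param after optional contact data.frame for the post-mutation state.
#' @param afterRelax optional contact data.frame for the post-relax state.
#' @param pocketResidues optional data.frame (chainId, resSeq, resName),
#'   e.g. from [residuesWithin()]; zero-contact members are reported.
#' @return list with `table` (one row per residue plus a TOTAL row; count
#'   columns `before`, and `after`/`afterRelax` when supplied, and `delta`
#'   = last state minus before) and `potential` (zero-contact pocket
#'   residues).
#' @export
contactReport <- function(before, after = NULL, afterRelax = NULL,
                          pocketResidues = NULL) {
  states <- list(before = before)
  if (!is.null(after)) states$after <- after
  if (!is.null(afterRelax)) states$afterRelax <- afterRelax
  allKeys <- character(0)
  for (s in states)
    if (!is.null(s) && nrow(s))
      allKeys <- union(allKeys, paste(s$chainId, s$resSeq, s$resName,
                                      sep = "\r"))
  if (!is.null(pocketResidues) && nrow(pocketResidues))
    allKeys <- union(allKeys, paste(pocketResidues$chainId,
                                    pocketResidues$resSeq,
                                    pocketResidues$resName, sep = "\r"))
  parts <- strsplit(allKeys, "\r", fixed = TRUE)
  tab <- data.frame(
    chainId = vapply(parts, `[`, character(1), 1),
    resSeq = as.integer(vapply(parts, `[`, character(1), 2)),
    resName = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE)
  for (nm in names(states)) {
    s <- states[[nm]]
    cnt <- integer(nrow(tab))
    if (!is.null(s) && nrow(s)) {
      key <- paste(s$chainId, s$resSeq, s$resName, sep = "\r")
      t2 <- table(key)
      hit <- match(allKeys, names(t2))
      cnt <- ifelse(is.na(hit), 0L, as.integer(t2[hit]))
    }
    tab[[nm]] <- cnt
  }
  ord <- order(tab$chainId, tab$resSeq)
  tab <- tab[ord, , drop = FALSE]
  lastState <- names(states)[length(states)]
  tab$delta <- tab[[lastState]] - tab$before
  totals <- data.frame(chainId = "", resSeq = NA_integer_, resName = "TOTAL",
                       stringsAsFactors = FALSE)
  for (nm in names(states)) totals[[nm]] <- sum(tab[[nm]])
  totals$delta <- sum(tab$delta)
  tab <- rbind(tab, totals)
  rownames(tab) <- NULL
  potential <- tab[!is.na(tab$resSeq) & tab$before == 0L,
                   c("chainId", "resSeq", "resName"), drop = FALSE]
  rownames(potential) <- NULL
  list(table = tab, potential = potential)
}
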