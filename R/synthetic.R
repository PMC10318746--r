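# Synthetic structure generator: pockets of template residues planted
# around a built alditol at exact nearest-atom distances, so that pocket
# selection, polar-contact detection and design behaviour are known by
# construction. Geometry is planted by constraint satisfaction (the
# residue's reference atom is placed on a sphere of the target radius
# around a chosen ligand oxygen, residue body pointing away; a
# deterministic spin/tilt grid resolves overlaps), never by minimization,
# so ground truth stays analytic. Each ground-truth entry is verified
# against the corresponding analysis operation before the fixture is
# returned.

# Reference ("contact") atom per residue identity: the terminal polar
# atom for donors/acceptors, a terminal carbon otherwise.
.CONTACT_ATOM <- c(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
                   HIS = "NE2", LYS = "NZ", ARG = "NH1", ASP = "OD1",
                   GLU = "OE1", ASN = "ND2", GLN = "NE2", TRP = "NE1",
                   MET = "SD", VAL = "CG1", LEU = "CD1", ILE = "CD1",
                   PHE = "CZ", ALA = "CB", GLY = "CA", PRO = "CG")

.POLAR_IDENTITIES <- names(.SIDECHAIN_POLAR)

# One residue (backbone + side chain) in a local frame: CA at origin.
.templateResidue <- function(aa, chi = NULL) {
  if (is.null(chi)) {
    k <- .nChi(aa)
    chi <- if (k) defaultRotamerLibrary()@rotamers[[aa]]$chi[1, ] else numeric(0)
  }
  posCA <- c(0, 0, 0)
  posN <- c(1.46, 0, 0)
  posC <- 1.52 * c(cos(111 * pi / 180), sin(111 * pi / 180), 0)
  posO <- .placeInternal(posC, posCA, posN, 1.23, 120.5, 180)
  side <- .buildSideChain(aa, posN, posCA, posC, chi)
  pos <- c(list(N = posN, CA = posCA, C = posC, O = posO), side)
  do.call(rbind, lapply(names(pos), function(nm) {
    .mkAtom(0L, nm, .elementFromName(nm, aa), pos[[nm]], aa,
            chainId = "A", resSeq = 1L, recordKind = "ATOM")
  }))
}

.orthoVec <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross(v, w))
}

# Rigidly place a local-frame residue so its reference atom lands on
# `target` with the residue body pointing along +dir; `spin` (radians)
# then turns the residue about the outward axis through the target.
.placeResidue <- function(resAtoms, refName, target, dir, spin = 0) {
  xyz <- .xyzMatrix(resAtoms)
  q <- xyz[resAtoms$name == refName, , drop = FALSE][1, ]
  ctr <- colMeans(xyz)
  v <- ctr - q
  if (.vnorm(v) < 1e-6) v <- c(0, 0, 1)
  v <- .unit(v)
  d <- .unit(dir)
  ax <- .cross(v, d)
  Ralign <- if (.vnorm(ax) < 1e-9) {
    if (sum(v * d) > 0) diag(3) else .rotationMatrix(.orthoVec(v), pi)
  } else .rotationMatrix(ax, acos(max(-1, min(1, sum(v * d)))))
  R <- .rotationMatrix(d, spin) %*% Ralign
  xyz2 <- sweep(xyz, 2, q) %*% t(R)
  xyz2 <- sweep(xyz2, 2, target, "+")
  .setXyz(resAtoms, xyz2)
}

.minDistBetween <- function(a, b) min(.crossDist(.xyzMatrix(a), .xyzMatrix(b)))

#' Generate a synthetic pocket with planted contact geometry
#'
#' Builds a hexitol ligand and surrounds it with template residues whose
#' nearest-heavy-atom distances to the ligand equal the planted targets
#' within 0.05 Angstrom. Polar identities planted inside the
#' hydrogen-bond window create polar contacts by construction; filler
#' residues are kept outside the 4 Angstrom pocket. Optionally plants a
#' steric clash (a side chain overlapping the ligand) and a designable
#' site: a backbone placed so a serine chi1 = -60 rotamer would form a
#' polar contact with the ligand's O3 (the epimeric hydroxyl), then
#' mutated to valine so the contact exists only under redesign.
#'
#' @param spec a [FixtureSpec-class].
#' @return list with `model` (a [PdbStructure-class] of the complex),
#'   `ligand` (heavy-atom [Ligand-class] in the model frame) and `truth`
#'   (ground-truth record: per-residue table with planted distances,
#'   expected 4-Angstrom pocket membership, expected polar-contact
#'   count, designable and clash bookkeeping).
#' @export
makePocket <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  .withSeed(spec@seed, .makePocketImpl(spec))
}

.makePocketImpl <- function(spec) {
  lig <- if (spec@ligandName == "X9X") buildAllitol() else
    buildAlditol(sorbitolConfig(), resName = spec@ligandName)
  lig <- dropHydrogens(lig)
  latoms <- lig@atoms
  latoms$chainId <- "A"
  latoms$resSeq <- 500L
  ctr <- colMeans(.xyzMatrix(latoms))
  oxyNames <- c("O1", "O2", "O4", "O5", "O6", "O3")
  oxyPos <- lapply(oxyNames, function(nm)
    unlist(latoms[latoms$name == nm, c("x", "y", "z")]))
  names(oxyPos) <- oxyNames
  placed <- list()
  truthRows <- list()
  resSeqCounter <- 0L

  tryPlace <- function(aa, targetDist, anchor, chi = NULL,
                       extraCheck = NULL, exact = TRUE) {
    tmpl <- .templateResidue(aa, chi)
    ref <- .CONTACT_ATOM[[aa]]
    dir0 <- .unit(anchor - ctr)
    for (attempt in 0:31) {
      spin <- (attempt %% 8) * pi / 4 + stats::runif(1, 0, 0.2)
      tilt <- (attempt %/% 8) * 7 * pi / 180
      dir <- as.vector(.rotationMatrix(.orthoVec(dir0), tilt) %*% dir0)
      target <- anchor + targetDist * dir
      cand <- .placeResidue(tmpl, ref, target, dir, spin)
      dMin <- .minDistBetween(cand, latoms)
      if (exact && abs(dMin - targetDist) > 0.05) next
      if (!exact && dMin <= 4.5) next  # fillers must stay outside the pocket
      clash <- FALSE
      for (p in placed) if (.minDistBetween(cand, p) < 3.2) clash <- TRUE
      if (clash) next
      if (!is.null(extraCheck) && !extraCheck(cand)) next
      attr(cand, "minDist") <- dMin
      return(cand)
    }
    NULL
  }

  addResidue <- function(aa, targetDist, anchor, chi = NULL,
                         label = "planted", extraCheck = NULL) {
    cand <- tryPlace(aa, targetDist, anchor, chi, extraCheck,
                     exact = label != "filler")
    if (is.null(cand))
      stop("infeasible planting: cannot place ", aa, " at ", targetDist,
           " Angstrom without overlap")
    resSeqCounter <<- resSeqCounter + 1L
    rs <- 10L * resSeqCounter
    cand$resSeq <- rs
    dMin <- attr(cand, "minDist")
    placed[[length(placed) + 1]] <<- cand
    truthRows[[length(truthRows) + 1]] <<- data.frame(
      resSeq = rs, resName = aa,
      minDist = if (label == "filler") dMin else targetDist, label = label,
      polarExpected = label == "planted" && aa %in% .POLAR_IDENTITIES &&
        targetDist >= 2.4 && targetDist <= 3.5,
      stringsAsFactors = FALSE)
    rs
  }

  oxyUse <- 0L
  nextAnchor <- function() {
    oxyUse <<- oxyUse + 1L
    oxyPos[[oxyNames[(oxyUse - 1L) %% 5L + 1L]]]
  }
  planted <- spec@plantedContacts
  if (nrow(planted))
    for (i in seq_len(nrow(planted)))
      addResidue(planted$resName[i], planted$distance[i], nextAnchor())

  assembleModel <- function(extraResidues = placed) {
    prot <- do.call(rbind, extraResidues)
    allAtoms <- if (is.null(prot)) latoms else rbind(prot, latoms)
    allAtoms$serial <- seq_len(nrow(allAtoms))
    .newStructure(allAtoms)
  }

  designableSeq <- NA_integer_
  designAlphabet <- c("ALA", "VAL", "CYS", "SER", "THR")
  # For a sorbitol fixture the designable site targets O3, the epimeric
  # hydroxyl. When the fixture carries allitol (the ligand-swap
  # workflow), the site targets O5 instead: O3 is exactly the hydroxyl
  # that moves upon the allitol -> sorbitol swap, and the site must
  # survive it.
  designAnchor <- if (spec@ligandName == "X9X") "O5" else "O3"
  if (spec@designableSite) {
    # the serine version must gain a polar contact; the valine version
    # must make none while staying inside the 4 Angstrom pocket; and,
    # over the site's small-residue design alphabet, the minimum-energy
    # (identity, rotamer) assignment must be one that gains a contact --
    # the gain-of-contact property holds by construction
    ligProbe <- asLigand(latoms)
    lib <- defaultRotamerLibrary()
    check <- function(cand) {
      cand$resSeq <- 999L
      mSer <- assembleModel(c(placed, list(cand)))
      pcSer <- polarContacts(mSer, ligProbe)
      if (!any(pcSer$resSeq == 999L)) return(FALSE)
      mVal <- mutateResidue(mSer, "A", 999L, "VAL", chi = c(-60),
                            warnProline = FALSE)
      pcVal <- polarContacts(mVal, ligProbe)
      if (any(pcVal$resSeq == 999L)) return(FALSE)
      rw <- residuesWithin(mVal, ligProbe, 4.0)
      if (!(999L %in% rw$resSeq)) return(FALSE)
      bestE <- Inf; bestGains <- FALSE
      for (aa in designAlphabet) {
        chis <- lib@rotamers[[aa]]$chi
        for (ri in seq_len(nrow(chis))) {
          m <- mutateResidue(mVal, "A", 999L, aa,
                             if (ncol(chis)) chis[ri, ] else numeric(0),
                             warnProline = FALSE)
          e <- scoreEnergy(m)@total
          if (e < bestE - 1e-9) {
            bestE <- e
            bestGains <- any(polarContacts(m, ligProbe)$resSeq == 999L)
          }
        }
      }
      bestGains
    }
    designableSeq <- addResidue("SER", 2.9, oxyPos[[designAnchor]],
                                chi = c(-60), label = "designable",
                                extraCheck = check)
  }

  clashSeq <- NA_integer_
  if (spec@plantedClash) {
    anchor <- oxyPos[["O6"]]
    dir <- .unit(anchor - ctr)
    cand <- .placeResidue(.templateResidue("VAL"), "CG1",
                          anchor + 1.9 * dir, dir)
    resSeqCounter <- resSeqCounter + 1L
    rs <- 10L * resSeqCounter
    cand$resSeq <- rs
    placed[[length(placed) + 1]] <- cand
    truthRows[[length(truthRows) + 1]] <- data.frame(
      resSeq = rs, resName = "VAL", minDist = 1.9, label = "clash",
      polarExpected = FALSE, stringsAsFactors = FALSE)
    clashSeq <- rs
  }

  while (length(placed) < spec@nPocketResidues) {
    dist <- 6.5 + 0.7 * (length(placed) %% 4)
    done <- FALSE
    for (k in 1:5) {  # crowded directions are skipped, not fatal
      ok <- tryCatch({
        addResidue("VAL", dist, nextAnchor(), label = "filler")
        TRUE
      }, error = function(e) FALSE)
      if (ok) { done <- TRUE; break }
    }
    if (!done) stop("infeasible planting: no room for filler residues")
  }

  model <- assembleModel()
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(resSeq = integer(0), resName = character(0),
               minDist = numeric(0), label = character(0),
               polarExpected = logical(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$resSeq), , drop = FALSE]
  rownames(truth) <- NULL

  if (!is.na(designableSeq)) {
    model <- mutateResidue(model, "A", designableSeq, "VAL",
                           chi = c(-60), warnProline = FALSE)
    i <- truth$resSeq == designableSeq
    truth$resName[i] <- "VAL"
    truth$polarExpected[i] <- FALSE
    lp <- asLigand(latoms)
    rw <- residuesWithin(model, lp, 1e6)
    truth$minDist[i] <- rw$minDist[match(designableSeq, rw$resSeq)]
  }

  ligOut <- extractLigand(model, spec@ligandName)
  rec <- list(residues = truth,
              pocket4 = truth$resSeq[truth$minDist <= 4.0],
              nPolarContacts = sum(truth$polarExpected),
              designable = if (is.na(designableSeq)) NULL else
                list(resSeq = designableSeq, gainIdentity = "SER",
                     chi = c(-60), alphabet = designAlphabet),
              clashResSeq = clashSeq,
              ligandName = spec@ligandName)

  # generation and analysis must agree: verify before returning
  got <- residuesWithin(model, ligOut, 4.0)
  if (!identical(sort(as.integer(got$resSeq)), sort(as.integer(rec$pocket4))))
    stop("fixture self-check failed: pocket membership mismatch")
  pc <- polarContacts(model, ligOut)
  if (!is.na(clashSeq)) {
    if (nrow(pc) < rec$nPolarContacts)
      stop("fixture self-check failed: planted polar contacts missing")
  } else if (nrow(pc) != rec$nPolarContacts) {
    stop("fixture self-check failed: expected ", rec$nPolarContacts,
         " polar contacts, found ", nrow(pc))
  }
  list(model = model, ligand = ligOut, truth = rec)
}

#' Duplicate an assembly as a homodimer
#'
#' Adds a copy of chain A as chain B (each chain carrying its own ligand
#' copy), rigidly rotated and translated far enough that the chains do
#' not touch, emulating a crystallographic dimer of identical monomers.
#'
#' @param model a [PdbStructure-class] whose atoms are chain A.
#' @param separation minimum translation distance, Angstrom (>= 20).
#' @return a [PdbStructure-class] with chains A and B.
#' @export
makeDimer <- function(model, separation = 25) {
  stopifnot(is(model, "PdbStructure"), separation >= 20)
  a <- model@atoms
  span <- max(.crossDist(.xyzMatrix(a), .xyzMatrix(a)))
  shift <- max(separation, span + 20)
  tf <- new("RigidTransform", rotation = .rotationMatrix(c(0, 0, 1), pi),
            translation = c(shift, 0, 0))
  b <- .setXyz(a, applyTransform(.xyzMatrix(a), tf))
  b$chainId <- "B"
  out <- rbind(a, b)
  out$serial <- seq_len(nrow(out))
  .newStructure(out)
}

#' Build an epimeric pair of hexitols
#'
#' Returns an allitol-like hexitol and the stereoisomer obtained by
#' inverting exactly one internal stereocenter (default C3, the
#' allitol/sorbitol relationship).
#'
#' @param position epimerized carbon, in 2..5.
#' @return list of two [Ligand-class] objects, `reference` and `epimer`.
#' @export
makeStereoPair <- function(position = 3L) {
  if (!(position %in% 2:5)) stop("position must be an internal carbon (2..5)")
  ref <- allitolConfig()
  d <- ref@descriptors
  key <- as.character(position)
  d[key] <- if (d[key] == "R") "S" else "R"
  list(reference = buildAlditol(ref, resName = "X9X"),
       epimer = buildAlditol(new("StereoConfig", descriptors = d),
                             resName = "SOR"))
}
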