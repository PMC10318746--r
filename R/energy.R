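# Reduced all-atom energy model. A self-contained, hydrogen-free score
# in reduced energy units: pairwise Lennard-Jones and Coulomb terms under
# a distance-dependent dielectric with a switched cutoff, a square-well
# geometric hydrogen-bond term that reuses the polar-contact criteria,
# and a 3-fold side-chain torsion penalty. Deterministic for fixed input.

.ffCache <- new.env(parent = emptyenv())

#' Load a reduced force-field parameter file
#'
#' The plain-text format is documented in the file header: PARAM lines
#' (global constants), TYPE lines (Lennard-Jones types) and CHARGE lines
#' (per residue-template atom charges; residue '*' is the shared backbone
#' template).
#'
#' @param path parameter file; default the version-1 set shipped with the
#'   package.
#' @return a [ForceFieldParams-class].
#' @export
readForceField <- function(path = system.file("extdata", "reduced_ff_v1.txt",
                                              package = "PocketSwap")) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  params <- list()
  types <- list(); charges <- list()
  for (tk in toks) {
    kind <- tk[1]
    if (kind == "PARAM") {
      params[[tk[2]]] <- as.numeric(tk[3])
    } else if (kind == "TYPE") {
      types[[length(types) + 1]] <- data.frame(
        type = tk[2], sigma = as.numeric(tk[3]), epsilon = as.numeric(tk[4]),
        stringsAsFactors = FALSE)
    } else if (kind == "CHARGE") {
      charges[[length(charges) + 1]] <- data.frame(
        resName = tk[2], atomName = tk[3], type = tk[4],
        charge = as.numeric(tk[5]), stringsAsFactors = FALSE)
    } else stop("unknown record kind in force-field file: ", kind)
  }
  new("ForceFieldParams",
      types = do.call(rbind, types), charges = do.call(rbind, charges),
      dielectricSlope = params$dielectricSlope,
      coulombConstant = params$coulombConstant,
      hbondEnergy = params$hbondEnergy, torsionK = params$torsionK,
      cutoff = params$cutoff, switchStart = params$switchStart,
      scale14 = params$scale14, ljRepulsiveScale = 1,
      version = basename(path))
}

#' Default force-field parameters
#'
#' The version-1 reduced parameter set shipped with the package, cached
#' after the first load.
#'
#' @return a [ForceFieldParams-class].
#' @export
defaultForceField <- function() {
  if (is.null(.ffCache$default)) .ffCache$default <- readForceField()
  .ffCache$default
}

# Assign (type, charge) per atom; residue-specific entry first, then the
# '*' backbone template. Errors list every untypable atom.
.typeAtoms <- function(atomTable, params) {
  ch <- params@charges
  keyTable <- paste(ch$resName, ch$atomName)
  hit <- match(paste(atomTable$resName, atomTable$name), keyTable)
  fallback <- match(paste("*", atomTable$name), keyTable)
  hit[is.na(hit)] <- fallback[is.na(hit)]
  if (anyNA(hit)) {
    bad <- which(is.na(hit))
    stop("cannot parameterize atom(s): ",
         paste(sprintf("%s %s/%d %s", atomTable$resName[bad],
                       atomTable$chainId[bad], atomTable$resSeq[bad],
                       atomTable$name[bad])[seq_len(min(10, length(bad)))],
               collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  ti <- match(ch$type[hit], params@types$type)
  list(sigma = params@types$sigma[ti], epsilon = params@types$epsilon[ti],
       charge = ch$charge[hit])
}

# CHARMM-style switching function on [switchStart, cutoff].
.switchFactor <- function(r, rs, rc) {
  s <- rep(1, length(r))
  s[r >= rc] <- 0
  mid <- r > rs & r < rc
  if (any(mid)) {
    r2 <- r[mid]^2; rs2 <- rs^2; rc2 <- rc^2
    s[mid] <- (rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * rs2) / (rc2 - rs2)^3
  }
  s
}

# Graph distances 1..3 between atoms, from the perceived bond graph.
# Returns a list of matrices pairs1, pairs2, pairs3 (i < j).
.bondSeparation <- function(n, bonds) {
  adj <- .adjacencyList(n, bonds)
  p1 <- if (nrow(bonds)) bonds else matrix(integer(0), ncol = 2)
  sep <- new.env(parent = emptyenv())
  mark <- function(i, j, d) {
    if (i == j) return()
    key <- if (i < j) paste0(i, ".", j) else paste0(j, ".", i)
    old <- sep[[key]]
    if (is.null(old) || d < old) sep[[key]] <- d
  }
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      mark(i, j, 1L)
      for (k in adj[[j]]) {
        mark(i, k, 2L)
        for (l in adj[[k]]) mark(i, l, 3L)
      }
    }
  }
  keys <- ls(sep)
  if (!length(keys)) {
    z <- matrix(integer(0), ncol = 2)
    return(list(pairs = z, sepn = integer(0)))
  }
  ij <- do.call(rbind, strsplit(keys, ".", fixed = TRUE))
  list(pairs = cbind(as.integer(ij[, 1]), as.integer(ij[, 2])),
       sepn = vapply(keys, function(k) sep[[k]], integer(1), USE.NAMES = FALSE))
}

.isPolarElement <- function(element) toupper(element) %in% c("N", "O", "S")

# Geometric polar contacts among all polar heavy atoms of a coordinate
# set, excluding pairs closer than 4 bonds in the covalent graph.
# Returns the pair list (i < j): the pairs earn the hydrogen-bond well
# and are dropped from the Coulomb sum, since with the bridging proton
# absent the bare donor-acceptor charge product would register a
# spurious repulsion for an interaction that is in fact attractive.
.hbondPairs <- function(atomTable, xyz, bonds, sepIndex, criteria) {
  polar <- which(.isPolarElement(atomTable$element))
  pairs <- matrix(integer(0), ncol = 2)
  if (length(polar) < 2) return(pairs)
  d <- .crossDist(xyz[polar, , drop = FALSE], xyz[polar, , drop = FALSE])
  for (u in seq_along(polar)) {
    for (v in seq_along(polar)) {
      if (v <= u) next
      if (d[u, v] < criteria@polarDistanceMin ||
          d[u, v] > criteria@polarDistanceMax) next
      i <- polar[u]; j <- polar[v]
      key <- paste0(min(i, j), ".", max(i, j))
      if (!is.null(sepIndex[[key]])) next  # 1-2, 1-3 or 1-4: bonded context
      if (!.angleOK(xyz, atomTable$element, i, xyz[j, ], criteria@angleMin)) next
      if (!.angleOK(xyz, atomTable$element, j, xyz[i, ], criteria@angleMin)) next
      pairs <- rbind(pairs, c(min(i, j), max(i, j)))
    }
  }
  pairs
}

# Side-chain / ligand torsion bonds: C-C bonds outside the protein
# backbone whose two atoms each have >= 2 heavy neighbours.
.torsionEnergy <- function(atomTable, xyz, bonds, torsionK) {
  if (!nrow(bonds) || torsionK == 0) return(0)
  adj <- .adjacencyList(nrow(atomTable), bonds)
  deg <- lengths(adj)
  isC <- toupper(atomTable$element) == "C"
  bb <- atomTable$name %in% .BACKBONE_ATOMS & atomTable$recordKind == "ATOM"
  e <- 0
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (!isC[i] || !isC[j] || bb[i] || bb[j]) next
    if (deg[i] < 2 || deg[j] < 2) next
    a <- min(setdiff(adj[[i]], j)); dd <- min(setdiff(adj[[j]], i))
    phi <- .dihedralDeg(xyz[a, ], xyz[i, ], xyz[j, ], xyz[dd, ]) * pi / 180
    e <- e + torsionK * (1 + cos(3 * phi))
  }
  e
}

#' Score a structure with the reduced energy model
#'
#' Pairwise Lennard-Jones and Coulomb terms over non-excluded heavy-atom
#' pairs within the cutoff (1-2 and 1-3 pairs excluded, 1-4 scaled), a
#' square-well hydrogen-bond term over geometric polar contacts, and a
#' 3-fold side-chain torsion penalty. Hydrogens, if present, are ignored:
#' the model is parameterized for heavy atoms.
#'
#' @param model a [PdbStructure-class] or [Ligand-class].
#' @param params a [ForceFieldParams-class] (default [defaultForceField()]).
#' @param criteria [ContactCriteria-class] used by the hydrogen-bond term.
#' @return an [EnergyBreakdown-class]; total is in reduced units.
#' @export
scoreEnergy <- function(model, params = defaultForceField(),
                        criteria = new("ContactCriteria")) {
  a <- if (is(model, "Ligand")) model@atoms else atoms(model)
  a <- a[toupper(a$element) != "H", , drop = FALSE]
  if (!nrow(a)) stop("nothing to score: no heavy atoms")
  typed <- .typeAtoms(a, params)
  xyz <- .xyzMatrix(a)
  n <- nrow(a)
  bonds <- perceiveBonds(a, requireConnected = FALSE)
  sepInfo <- .bondSeparation(n, bonds)
  sepIndex <- new.env(parent = emptyenv())
  if (length(sepInfo$sepn))
    for (k in seq_along(sepInfo$sepn))
      sepIndex[[paste0(sepInfo$pairs[k, 1], ".",
                       sepInfo$pairs[k, 2])]] <- sepInfo$sepn[k]
  hbPairs <- .hbondPairs(a, xyz, bonds, sepIndex, criteria)
  hbKeys <- if (nrow(hbPairs))
    paste0(hbPairs[, 1], ".", hbPairs[, 2]) else character(0)
  lj <- 0; coul <- 0
  if (n > 1) {
    d <- .crossDist(xyz, xyz)
    iu <- which(upper.tri(d) & d < params@cutoff, arr.ind = TRUE)
    if (nrow(iu)) {
      i <- iu[, 1]; j <- iu[, 2]
      keys <- paste0(i, ".", j)
      sepn <- vapply(keys, function(k) {
        v <- sepIndex[[k]]; if (is.null(v)) 9L else v
      }, integer(1), USE.NAMES = FALSE)
      keep <- sepn >= 3L
      scale <- ifelse(sepn == 3L, params@scale14, 1)[keep]
      i <- i[keep]; j <- j[keep]
      r <- d[cbind(i, j)]
      sw <- .switchFactor(r, params@switchStart, params@cutoff)
      sij <- (typed$sigma[i] + typed$sigma[j]) / 2
      eij <- sqrt(typed$epsilon[i] * typed$epsilon[j])
      sr6 <- (sij / r)^6
      lj <- sum(scale * sw * 4 * eij *
                  (params@ljRepulsiveScale * sr6^2 - sr6))
      qq <- typed$charge[i] * typed$charge[j]
      # hydrogen-bonded pairs take the well instead of bare Coulomb
      qq[paste0(i, ".", j) %in% hbKeys] <- 0
      coul <- sum(scale * sw * params@coulombConstant * qq /
                    (params@dielectricSlope * r^2))
    }
  }
  hb <- params@hbondEnergy * nrow(hbPairs)
  tor <- .torsionEnergy(a, xyz, bonds, params@torsionK)
  new("EnergyBreakdown", lj = lj, coulomb = coul, hbond = hb, torsion = tor,
      total = lj + coul + hb + tor)
}

#' Component energies of a complex: G_C, G_P, G_L
#'
#' Scores the complex, the ligand-free protein and the free ligand with
#' identical parameters, the three states entering the binding free
#' energy dG_bind = G_C - (G_P + G_L).
#'
#' @param complex a [PdbStructure-class] containing exactly one copy of
#'   the ligand.
#' @param ligandCode het code of the ligand.
#' @param params a [ForceFieldParams-class].
#' @param criteria [ContactCriteria-class] for the hydrogen-bond term.
#' @return named numeric vector c(GC, GP, GL), reduced units.
#' @export
scoreParts <- function(complex, ligandCode, params = defaultForceField(),
                       criteria = new("ContactCriteria")) {
  stopifnot(is(complex, "PdbStructure"))
  lig <- extractLigand(complex, ligandCode)
  apo <- removeLigand(complex, ligandCode)
  c(GC = scoreEnergy(complex, params, criteria)@total,
    GP = scoreEnergy(apo, params, criteria)@total,
    GL = scoreEnergy(lig, params, criteria)@total)
}
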