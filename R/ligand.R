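# Ligand construction and perception for linear sugar alcohols.
#
# Alditols (e.g. the hexitols allitol and sorbitol) are acyclic polyols:
# an n-carbon chain carrying one hydroxyl per carbon. Configuration is
# carried by the internal carbons C2..C(n-1); epimers differ at exactly
# one of them. Descriptor assignment uses a fixed priority ranking
# appropriate to uniform polyol chains: OH > chain toward the farther
# terminus > chain toward the nearer terminus > H. For linear polyols the
# chain-length asymmetry resolves every priority comparison, so this
# coincides with constitutional CIP ranking; ties at the exact chain
# midpoint (odd backbones only) go to the higher-numbered side.

.COVALENT_RADII <- c(H = 0.37, C = 0.77, N = 0.70, O = 0.66, S = 1.04,
                     P = 1.07, F = 0.64, CL = 0.99, BR = 1.14)

.TET <- acos(-1 / 3) * 180 / pi  # 109.471 degrees

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their separation is below the sum of their
#' covalent radii plus `tol` (and above 0.4 Angstrom). The resulting graph
#' must be connected for a single molecule.
#'
#' @param atomTable data.frame of atoms (see [PdbStructure-class] layout)
#'   or a [Ligand-class]/[PdbStructure-class].
#' @param tol Angstrom added to the covalent-radius sum (default 0.45).
#' @param requireConnected error if the bond graph is disconnected?
#' @return two-column integer matrix of bonded atom row indices (i < j).
#' @export
perceiveBonds <- function(atomTable, tol = 0.45, requireConnected = TRUE) {
  if (is(atomTable, "Ligand") || is(atomTable, "PdbStructure"))
    atomTable <- atoms(atomTable)
  n <- nrow(atomTable)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  rad <- .COVALENT_RADII[toupper(atomTable$element)]
  rad[is.na(rad)] <- 0.77
  xyz <- .xyzMatrix(atomTable)
  d <- .crossDist(xyz, xyz)
  thr <- outer(rad, rad, "+") + tol
  # closed comparison: ideal-geometry bonds sit exactly at the radius sum
  hit <- which(d <= thr + 1e-9 & d > 0.4, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  bonds <- matrix(as.integer(hit), ncol = 2)
  colnames(bonds) <- c("i", "j")
  if (requireConnected && n > 1) {
    comp <- .connectedComponents(n, bonds)
    if (max(comp) > 1)
      stop("bond perception yields a disconnected graph (",
           max(comp), " components)")
  }
  bonds
}

.connectedComponents <- function(n, bonds) {
  comp <- integer(n); cur <- 0L
  adj <- .adjacencyList(n, bonds)
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

.adjacencyList <- function(n, bonds) {
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Longest simple path restricted to carbon atoms; exhaustive DFS (ligand
# scale only). Returns atom row indices in path order.
.longestCarbonChain <- function(atomTable, bonds) {
  carbons <- which(toupper(atomTable$element) == "C")
  if (!length(carbons)) return(integer(0))
  inC <- logical(nrow(atomTable)); inC[carbons] <- TRUE
  adj <- .adjacencyList(nrow(atomTable), bonds)
  adj <- lapply(adj, function(v) v[inC[v]])
  best <- integer(0)
  dfs <- function(v, path) {
    if (length(path) > length(best)) best <<- path
    for (w in adj[[v]]) if (!(w %in% path)) dfs(w, c(path, w))
  }
  for (s in carbons) dfs(s, s)
  best
}

.orientBackbone <- function(atomTable, chain) {
  # Prefer the numbering implied by C1..Cn atom names; otherwise put the
  # lower-serial terminus first.
  nm <- atomTable$name[chain]
  num <- suppressWarnings(as.integer(sub("^C", "", nm)))
  if (!anyNA(num)) {
    if (all(diff(num) < 0)) return(rev(chain))
    if (all(diff(num) > 0)) return(chain)
  }
  if (atomTable$serial[chain[1]] <= atomTable$serial[chain[length(chain)]])
    chain else rev(chain)
}

.hydroxylMap <- function(atomTable, bonds, backbone) {
  adj <- .adjacencyList(nrow(atomTable), bonds)
  out <- integer(0)
  for (k in seq_along(backbone)) {
    nb <- adj[[backbone[k]]]
    ox <- nb[toupper(atomTable$element[nb]) == "O" & !(nb %in% backbone)]
    if (length(ox)) out[as.character(k)] <- ox[1]
  }
  out
}

#' Interpret an atom set as a Ligand
#'
#' Perceives bonds, identifies the backbone as the longest carbon chain,
#' maps hydroxyl oxygens onto it and, when every backbone carbon carries a
#' hydroxyl (the alditol case), assigns stereo descriptors.
#'
#' @param x a [PdbStructure-class] or atom data.frame.
#' @param tol bond-perception tolerance, Angstrom.
#' @return a [Ligand-class].
#' @export
asLigand <- function(x, tol = 0.45) {
  atomTable <- if (is(x, "PdbStructure")) x@atoms else x
  rownames(atomTable) <- NULL
  bonds <- perceiveBonds(atomTable, tol = tol)
  backbone <- as.integer(.orientBackbone(atomTable,
                                         .longestCarbonChain(atomTable, bonds)))
  hmap <- .hydroxylMap(atomTable, bonds, backbone)
  lig <- new("Ligand", atoms = atomTable, bonds = bonds, backbone = backbone,
             hydroxylMap = hmap, stereo = character(0))
  if (length(backbone) >= 3 && length(hmap) == length(backbone))
    lig@stereo <- descriptors(stereoDescriptors(lig))
  lig
}

#' Molecular formula of a ligand
#'
#' @param ligand a [Ligand-class].
#' @return named integer vector of element counts in Hill order (C, H,
#'   then alphabetical); empty ligand gives an empty vector.
#' @examples
#' molecularFormula(buildSorbitol())  # C6 H14 O6
#' @export
molecularFormula <- function(ligand) {
  stopifnot(is(ligand, "Ligand"))
  if (!nrow(ligand@atoms)) return(setNames(integer(0), character(0)))
  cnt <- table(toupper(ligand@atoms$element))
  els <- names(cnt)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  setNames(as.integer(cnt[ord]), ord)
}

# Signed chirality at backbone position i: negative triple product of the
# (O, far-chain, near-chain) substituent directions corresponds to R under
# the fixed polyol ranking (calibrated against D-glyceraldehyde geometry).
.descriptorAt <- function(xyz, backbone, hmap, i) {
  n <- length(backbone)
  center <- xyz[backbone[i], ]
  farIdx <- if ((n - i) >= (i - 1)) i + 1L else i - 1L
  nearIdx <- if (farIdx == i + 1L) i - 1L else i + 1L
  a <- xyz[hmap[[as.character(i)]], ] - center
  b <- xyz[backbone[farIdx], ] - center
  c3 <- xyz[backbone[nearIdx], ] - center
  v <- sum(a * .cross(b, c3))
  if (v < 0) "R" else "S"
}

#' Stereo descriptors of a linear alditol
#'
#' Assigns R/S to each internal backbone carbon from the 3D coordinates
#' (signed volume of the ranked substituent directions; hydrogens are not
#' required). Priorities follow the fixed polyol ranking described in the
#' package vignette: OH > chain toward the farther terminus > chain toward
#' the nearer terminus > H.
#'
#' @param ligand a [Ligand-class] with backbone and hydroxyl map assigned.
#' @return a [StereoConfig-class]; descriptors named by carbon position.
#' @export
stereoDescriptors <- function(ligand) {
  stopifnot(is(ligand, "Ligand"))
  backbone <- ligand@backbone
  n <- length(backbone)
  if (n < 3) stop("backbone too short for stereo assignment")
  hmap <- ligand@hydroxylMap
  need <- as.character(2:(n - 1))
  if (!all(need %in% names(hmap)))
    stop("missing hydroxyl substituent at backbone position(s) ",
         paste(setdiff(need, names(hmap)), collapse = ", "))
  xyz <- .xyzMatrix(ligand@atoms)
  desc <- vapply(2:(n - 1), function(i) .descriptorAt(xyz, backbone, hmap, i),
                 character(1))
  new("StereoConfig", descriptors = setNames(desc, need))
}

# Two unit directions completing a tetrahedral center whose existing
# substituent directions are u1, u2; returned as a 2 x 3 matrix.
.tetraComplete <- function(u1, u2) {
  b <- -(u1 + u2)
  bh <- .unit(b)
  nrm <- .unit(.cross(u1, u2))
  cosphi <- (-1 / 3) / sum(bh * u1)
  cosphi <- max(-1, min(1, cosphi))
  phi <- acos(cosphi)
  rbind(cos(phi) * bh + sin(phi) * nrm,
        cos(phi) * bh - sin(phi) * nrm)
}

.mkAtom <- function(serial, name, element, pos, resName, chainId = "",
                    resSeq = 1L, recordKind = "HETATM") {
  data.frame(serial = as.integer(serial), name = name, altLoc = "",
             resName = resName, chainId = chainId, resSeq = as.integer(resSeq),
             x = pos[1], y = pos[2], z = pos[3], occupancy = 1, bFactor = 0,
             element = element, recordKind = recordKind,
             stringsAsFactors = FALSE)
}

#' Build an ideal-geometry linear alditol
#'
#' Constructs an n-carbon sugar alcohol in the extended (all-anti)
#' backbone conformation with tetrahedral centers, standard bond lengths
#' and explicit hydrogens, realizing the requested stereo descriptors at
#' each internal carbon. The result round-trips through
#' [stereoDescriptors()].
#'
#' @param config a [StereoConfig-class] (length n-2) or character vector
#'   of "R"/"S".
#' @param resName three-letter residue code for the atoms (default "LIG").
#' @param bondCC,bondCO,bondCH,bondOH ideal bond lengths, Angstrom.
#' @return a [Ligand-class] with C1..Cn / O1..On atom names.
#' @examples
#' srb <- buildAlditol(sorbitolConfig(), resName = "SOR")
#' molecularFormula(srb)
#' @export
buildAlditol <- function(config, resName = "LIG", bondCC = 1.54,
                         bondCO = 1.43, bondCH = 1.09, bondOH = 0.96) {
  desc <- if (is(config, "StereoConfig")) config@descriptors else config
  if (!length(desc) || !all(desc %in% c("R", "S")))
    stop("config must be R/S descriptors for the internal carbons")
  n <- length(desc) + 2L
  # extended backbone by internal coordinates
  cpos <- matrix(0, n, 3)
  cpos[1, ] <- c(0, 0, 0)
  cpos[2, ] <- c(bondCC, 0, 0)
  if (n >= 3)
    cpos[3, ] <- .placeInternal(cpos[2, ], cpos[1, ], c(0, 1, 0),
                                bondCC, .TET, 0)
  if (n >= 4)
    for (i in 4:n)
      cpos[i, ] <- .placeInternal(cpos[i - 1, ], cpos[i - 2, ], cpos[i - 3, ],
                                  bondCC, .TET, 180)
  opos <- matrix(NA_real_, n, 3)
  hpos <- list()
  # terminal carbons: one O and two H, placed around the single chain bond
  for (i in c(1L, n)) {
    nb <- if (i == 1L) 2L else n - 1L
    u <- .unit(cpos[nb, ] - cpos[i, ])
    ref <- if (i == 1L) cpos[min(3, n), ] else cpos[max(1, n - 2), ]
    p <- .unit(.cross(u, ref - cpos[i, ]))
    if (!all(is.finite(p))) p <- .unit(.cross(u, c(0, 0, 1)))
    q <- .cross(u, p)
    dirs <- t(vapply(0:2, function(k) {
      ang <- 2 * pi * k / 3
      cos(.TET * pi / 180) * u +
        sin(.TET * pi / 180) * (cos(ang) * p + sin(ang) * q)
    }, numeric(3)))
    opos[i, ] <- cpos[i, ] + bondCO * dirs[1, ]
    hpos[[paste0("H", i, "1")]] <- cpos[i, ] + bondCH * dirs[2, ]
    hpos[[paste0("H", i, "2")]] <- cpos[i, ] + bondCH * dirs[3, ]
  }
  # internal carbons: O/H on the two remaining tetrahedral directions,
  # side chosen to realize the requested descriptor
  for (i in 2:(n - 1)) {
    u1 <- .unit(cpos[i - 1, ] - cpos[i, ])
    u2 <- .unit(cpos[i + 1, ] - cpos[i, ])
    vv <- .tetraComplete(u1, u2)
    farIdx <- if ((n - i) >= (i - 1)) i + 1L else i - 1L
    nearIdx <- if (farIdx == i + 1L) i - 1L else i + 1L
    pick <- function(vO) {
      a <- bondCO * vO
      b <- cpos[farIdx, ] - cpos[i, ]
      c3 <- cpos[nearIdx, ] - cpos[i, ]
      if (sum(a * .cross(b, c3)) < 0) "R" else "S"
    }
    useFirst <- pick(vv[1, ]) == desc[[i - 1L]]
    vO <- if (useFirst) vv[1, ] else vv[2, ]
    vH <- if (useFirst) vv[2, ] else vv[1, ]
    opos[i, ] <- cpos[i, ] + bondCO * vO
    hpos[[paste0("H", i)]] <- cpos[i, ] + bondCH * vH
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- .mkAtom(serial, paste0("C", i), "C",
                                        cpos[i, ], resName)
  }
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- .mkAtom(serial, paste0("O", i), "O",
                                        opos[i, ], resName)
  }
  for (nm in names(hpos)) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- .mkAtom(serial, nm, "H", hpos[[nm]], resName)
  }
  # hydroxyl hydrogens, anti to the chain continuation for determinism
  for (i in seq_len(n)) {
    serial <- serial + 1L
    ref <- if (i < n) cpos[i + 1, ] else cpos[i - 1, ]
    hoh <- .placeInternal(opos[i, ], cpos[i, ], ref, 0.96, 107, 180)
    rows[[length(rows) + 1]] <- .mkAtom(serial, paste0("HO", i), "H",
                                        hoh, resName)
  }
  asLigand(do.call(rbind, rows))
}

#' Stereo configurations of the hexitol pair
#'
#' `allitolConfig()` is the configuration of allitol, the natural ligand
#' of the *A. vitis* solute-binding protein; `sorbitolConfig()` is its C3
#' epimer sorbitol (D-glucitol). Under the package's fixed polyol priority
#' ranking the descriptor lists differ at exactly the C3 position, the
#' epimeric center.
#'
#' @return a [StereoConfig-class] for carbons C2..C5.
#' @export
allitolConfig <- function() {
  new("StereoConfig",
      descriptors = setNames(c("S", "S", "R", "R"), as.character(2:5)))
}

#' @rdname allitolConfig
#' @export
sorbitolConfig <- function() {
  new("StereoConfig",
      descriptors = setNames(c("S", "R", "R", "R"), as.character(2:5)))
}

#' Convenience builders for the hexitol pair
#'
#' Ideal-geometry allitol (het code X9X) and sorbitol (het code SOR).
#'
#' @return a [Ligand-class].
#' @export
buildAllitol <- function() buildAlditol(allitolConfig(), resName = "X9X")

#' @rdname buildAllitol
#' @export
buildSorbitol <- function() buildAlditol(sorbitolConfig(), resName = "SOR")

#' Drop hydrogens from a ligand
#'
#' Crystal-structure ligands carry heavy atoms only; built ligands are
#' reduced to the same representation before matching against them.
#'
#' @param ligand a [Ligand-class].
#' @return a [Ligand-class] with hydrogens removed and bonds re-perceived.
#' @export
dropHydrogens <- function(ligand) {
  stopifnot(is(ligand, "Ligand"))
  keep <- toupper(ligand@atoms$element) != "H"
  asLigand(ligand@atoms[keep, , drop = FALSE])
}

#' Export a ligand as an SDF (V2000) file
#'
#' Minimal single-molecule writer for interoperability with
#' cheminformatics tools.
#'
#' @param ligand a [Ligand-class].
#' @param path output file path.
#' @param title molecule title line.
#' @return invisibly, the path written.
#' @export
writeLigandSdf <- function(ligand, path, title = "ligand") {
  stopifnot(is(ligand, "Ligand"))
  a <- ligand@atoms
  b <- ligand@bonds
  lines <- c(title, "  PocketSwap", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            a$x, a$y, a$z, a$element))
  if (nrow(b))
    lines <- c(lines, sprintf("%3d%3d%3d  0", b[, 1], b[, 2], 1L))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
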