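# Backbone-guided ligand placement: rigid Kabsch superposition of the
# carbon backbone plus cyclic torsion refinement of the hydroxyl groups,
# iterated; then ligand swap inside the complex.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimizing the RMSD between
#' corresponding points. Reflections are explicitly forbidden (the
#' determinant sign fix), since a reflection would invert ligand
#' stereochemistry.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param reference n x 3 matrix of target points.
#' @param correspondence optional two-column integer matrix of
#'   (mobile row, reference row) pairs; default pairs rows in order.
#' @return list with `transform` (a [RigidTransform-class]) and `rmsd`
#'   (Angstrom, over the correspondence atoms after transformation).
#' @examples
#' p <- matrix(rnorm(18), ncol = 3)
#' kabschSuperpose(p, p)$rmsd  # 0
#' @export
kabschSuperpose <- function(mobile, reference, correspondence = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(correspondence))
    correspondence <- cbind(seq_len(nrow(mobile)), seq_len(nrow(reference)))
  P <- mobile[correspondence[, 1], , drop = FALSE]
  Q <- reference[correspondence[, 2], , drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 corresponding pairs")
  if (nrow(P) != nrow(Q)) stop("correspondence must be one-to-one")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))  # H = t(Pc) Qc
  if (sv$d[2] < 1e-10) stop("degenerate correspondence: points are collinear")
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) stop("degenerate correspondence")
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cq - as.vector(cp %*% R)
  moved <- sweep(Pc %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = t),
       rmsd = rmsd)
}

#' Apply a rigid transform
#'
#' @param x a [Ligand-class], [PdbStructure-class] or n x 3 matrix.
#' @param transform a [RigidTransform-class].
#' @return object of the same kind with transformed coordinates.
#' @export
applyTransform <- function(x, transform) {
  stopifnot(is(transform, "RigidTransform"))
  f <- function(xyz) sweep(xyz %*% transform@rotation, 2,
                           transform@translation, "+")
  if (is.matrix(x)) return(f(x))
  if (is(x, "Ligand") || is(x, "PdbStructure")) {
    x@atoms <- .setXyz(x@atoms, f(.xyzMatrix(x@atoms)))
    return(x)
  }
  stop("cannot transform object of class ", class(x)[1])
}

# Atoms moved by rotating about the bond (a, b): the connected component
# containing b once the bond is cut.
.downstreamAtoms <- function(nAtoms, bonds, a, b) {
  keep <- !(bonds[, 1] == a & bonds[, 2] == b) &
    !(bonds[, 1] == b & bonds[, 2] == a)
  comp <- .connectedComponents(nAtoms, bonds[keep, , drop = FALSE])
  which(comp == comp[b] & seq_len(nAtoms) != a)
}

# Optimal rotation angle about axis u through point `pivot` minimizing
# sum ||p_k(theta) - t_k||^2; closed form A + B cos + C sin.
.optimalTorsionAngle <- function(moving, targets, pivot, u) {
  rel <- sweep(moving, 2, pivot)
  alpha <- as.vector(rel %*% u)
  r1 <- rel - outer(alpha, u)
  w <- sweep(outer(alpha, u), 2, pivot, "+") - targets
  ucross <- t(apply(r1, 1, function(r) .cross(u, r)))
  B <- 2 * sum(w * r1)
  C <- 2 * sum(w * ucross)
  if (abs(B) < 1e-14 && abs(C) < 1e-14) return(0)
  atan2(-C, -B)
}

#' Refine hydroxyl torsions against a reference ligand
#'
#' Cyclic coordinate descent over the rotatable backbone C-C torsions,
#' minimizing the summed squared deviation of hydroxyl oxygens from their
#' reference counterparts. The oxygen on `excludedCarbon` (default C3, the
#' epimeric center whose hydroxyl points the other way) is left out of the
#' objective. Each single-torsion subproblem has the closed form
#' A + B cos(theta) + C sin(theta) and is solved analytically; a 0.5-degree
#' grid check can be enabled as a safeguard. The objective is
#' non-increasing across sweeps.
#'
#' @param placed a [Ligand-class] already backbone-superposed on the
#'   reference.
#' @param reference a [Ligand-class] with a hydroxyl map.
#' @param excludedCarbon backbone position whose hydroxyl is excluded.
#' @param tol convergence tolerance on the objective decrease (Angstrom^2).
#' @param maxSweeps maximum number of coordinate-descent sweeps.
#' @param gridCheck also scan a 0.5-degree grid per torsion and keep the
#'   better angle? Default FALSE (the analytic optimum is exact).
#' @return the refined [Ligand-class]; attribute "objective" holds the
#'   per-sweep objective values.
#' @export
refineHydroxylTorsions <- function(placed, reference, excludedCarbon = 3L,
                                   tol = 1e-6, maxSweeps = 100L,
                                   gridCheck = FALSE) {
  stopifnot(is(placed, "Ligand"), is(reference, "Ligand"))
  if (!length(placed@hydroxylMap) || !length(reference@hydroxylMap))
    stop("both ligands need an assigned hydroxyl map")
  bb <- placed@backbone
  xyz <- .xyzMatrix(placed@atoms)
  refXyz <- .xyzMatrix(reference@atoms)
  pos <- intersect(names(placed@hydroxylMap), names(reference@hydroxylMap))
  pos <- setdiff(pos, as.character(excludedCarbon))
  oIdx <- placed@hydroxylMap[pos]
  tIdx <- reference@hydroxylMap[pos]
  objective <- function(x) sum((x[oIdx, , drop = FALSE] -
                                  refXyz[tIdx, , drop = FALSE])^2)
  torsionBonds <- cbind(bb[-length(bb)], bb[-1])
  objTrace <- objective(xyz)
  for (sweep_i in seq_len(maxSweeps)) {
    before <- objective(xyz)
    for (k in seq_len(nrow(torsionBonds))) {
      a <- torsionBonds[k, 1]; b <- torsionBonds[k, 2]
      moving <- .downstreamAtoms(nrow(xyz), placed@bonds, a, b)
      movingO <- intersect(moving, oIdx)
      if (!length(movingO)) next
      u <- .unit(xyz[b, ] - xyz[a, ])
      targets <- refXyz[tIdx[match(movingO, oIdx)], , drop = FALSE]
      theta <- .optimalTorsionAngle(xyz[movingO, , drop = FALSE], targets,
                                    xyz[b, ], u)
      if (gridCheck) {
        grid <- seq(-pi, pi, by = 0.5 * pi / 180)
        evalAt <- function(th) {
          moved <- .rotateAbout(xyz[movingO, , drop = FALSE], xyz[b, ], u, th)
          sum((moved - targets)^2)
        }
        gbest <- grid[which.min(vapply(grid, evalAt, numeric(1)))]
        if (evalAt(gbest) < evalAt(theta)) theta <- gbest
      }
      cand <- xyz
      cand[moving, ] <- .rotateAbout(xyz[moving, , drop = FALSE],
                                     xyz[b, ], u, theta)
      if (objective(cand) <= objective(xyz)) xyz <- cand
    }
    after <- objective(xyz)
    objTrace <- c(objTrace, after)
    if (before - after < tol) break
  }
  placed@atoms <- .setXyz(placed@atoms, xyz)
  attr(placed, "objective") <- objTrace
  placed
}

.backboneXyz <- function(lig) .xyzMatrix(lig@atoms)[lig@backbone, , drop = FALSE]

#' Dock a ligand onto a reference by backbone superposition
#'
#' Alternates Kabsch superposition of the carbon backbones (C1..Cn) with
#' hydroxyl torsion refinement until the backbone RMSD changes by less
#' than `tol` between rounds. Both the direct (C1-C1) and the reversed
#' (C1-Cn) backbone correspondence are scored and the lower-RMSD
#' orientation kept, since alditol numbering direction is a convention.
#' Rigid moves and torsion rotations cannot change chirality, so stereo
#' descriptors are invariant under the whole procedure.
#'
#' @param newLigand the [Ligand-class] to place.
#' @param referenceLigand the [Ligand-class] defining the pocket pose.
#' @param excludedCarbon hydroxyl excluded from torsion refinement
#'   (default 3, the epimeric center).
#' @param tol convergence tolerance on backbone RMSD change (Angstrom).
#' @param maxRounds cap on alignment/refinement rounds.
#' @return the placed [Ligand-class]; attributes "rmsd" (final backbone
#'   RMSD), "iterations", and "reversed" (was the reversed correspondence
#'   used?).
#' @export
dockByBackbone <- function(newLigand, referenceLigand, excludedCarbon = 3L,
                           tol = 1e-4, maxRounds = 50L) {
  stopifnot(is(newLigand, "Ligand"), is(referenceLigand, "Ligand"))
  n <- length(newLigand@backbone)
  if (n != length(referenceLigand@backbone))
    stop("backbone length mismatch: ", n, " vs ",
         length(referenceLigand@backbone))
  refBB <- .backboneXyz(referenceLigand)
  runOne <- function(lig) {
    lastRmsd <- Inf; iter <- 0L
    repeat {
      iter <- iter + 1L
      fit <- kabschSuperpose(.backboneXyz(lig), refBB)
      lig <- applyTransform(lig, fit$transform)
      if (abs(lastRmsd - fit$rmsd) < tol || iter >= maxRounds) {
        lastRmsd <- fit$rmsd
        break
      }
      lastRmsd <- fit$rmsd
      lig <- refineHydroxylTorsions(lig, referenceLigand,
                                    excludedCarbon = excludedCarbon)
    }
    list(lig = lig, rmsd = lastRmsd, iter = iter)
  }
  ligRev <- newLigand
  ligRev@backbone <- rev(ligRev@backbone)
  names(ligRev@hydroxylMap) <-
    as.character(n + 1L - as.integer(names(ligRev@hydroxylMap)))
  ligRev@hydroxylMap <- ligRev@hydroxylMap[order(as.integer(names(ligRev@hydroxylMap)))]
  direct <- runOne(newLigand)
  reversed <- runOne(ligRev)
  useRev <- reversed$rmsd < direct$rmsd
  best <- if (useRev) reversed else direct
  out <- best$lig
  attr(out, "rmsd") <- best$rmsd
  attr(out, "iterations") <- best$iter
  attr(out, "reversed") <- useRev
  out
}

#' Replace one ligand with another inside a complex
#'
#' Deletes the atoms of the old heteroatom residue and appends the new
#' ligand's heavy atoms as HETATM records with fresh serials, keeping the
#' old ligand's chain and residue number. Protein atoms are untouched.
#'
#' @param complex a [PdbStructure-class] containing the old ligand.
#' @param oldCode het code of the ligand to delete.
#' @param newLigand a [Ligand-class] already placed in the pocket frame.
#' @param newCode het code for the inserted ligand (default the new
#'   ligand's residue name).
#' @param chain optional chain selecting one copy of the old ligand.
#' @return a [PdbStructure-class] with the ligand swapped.
#' @export
swapLigand <- function(complex, oldCode, newLigand, newCode = NULL,
                       chain = NULL) {
  stopifnot(is(complex, "PdbStructure"), is(newLigand, "Ligand"))
  idx <- .hetResidueIndex(complex@atoms, oldCode, chain)
  oldChain <- complex@atoms$chainId[idx[1]]
  oldSeq <- complex@atoms$resSeq[idx[1]]
  rest <- complex@atoms[-idx, , drop = FALSE]
  add <- newLigand@atoms[toupper(newLigand@atoms$element) != "H", ,
                         drop = FALSE]
  if (is.null(newCode)) newCode <- add$resName[1]
  add$resName <- newCode
  add$chainId <- oldChain
  add$resSeq <- oldSeq
  add$recordKind <- "HETATM"
  out <- rbind(rest, add)
  out$serial <- seq_len(nrow(out))
  .newStructure(out)
}
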