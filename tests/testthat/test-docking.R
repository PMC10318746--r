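# Kabsch superposition, hydroxyl torsion refinement, backbone docking and
# ligand swap.

test_that("identical point sets give the identity transform and zero rmsd", {
  set.seed(1)
  p <- matrix(rnorm(18), ncol = 3)
  fit <- kabschSuperpose(p, p)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$transform@rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$transform@translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a known rigid transform is recovered to 1e-8", {
  set.seed(2)
  for (rep in 1:5) {
    p <- matrix(rnorm(24), ncol = 3)
    R <- randomRotation()
    t <- rnorm(3, sd = 5)
    q <- sweep(p %*% R, 2, t, "+")
    fit <- kabschSuperpose(p, q)
    expect_lt(fit$rmsd, 1e-8)
    expect_lt(max(abs(fit$transform@rotation - R)), 1e-8)
    expect_lt(max(abs(fit$transform@translation - t)), 1e-8)
  }
})

test_that("the fitted transform beats a 1e4 sample of random rigid transforms", {
  set.seed(3)
  p <- matrix(rnorm(18), ncol = 3)
  q <- sweep(p %*% randomRotation(), 2, c(1, 2, 3), "+") +
    matrix(rnorm(18, sd = 0.3), ncol = 3)   # noisy correspondence
  fit <- kabschSuperpose(p, q)
  rmsdOf <- function(R, t) {
    moved <- sweep(p %*% R, 2, t, "+")
    sqrt(mean(rowSums((moved - q)^2)))
  }
  best <- Inf
  for (k in seq_len(1e4)) {
    R <- randomRotation()
    # center-matching translation for each sampled rotation
    t <- colMeans(q) - colMeans(p %*% R)
    best <- min(best, rmsdOf(R, t + rnorm(3, sd = 0.05)))
  }
  expect_lte(fit$rmsd, best + 1e-12)
})

test_that("rotations are always proper, even against mirrored references", {
  set.seed(4)
  p <- matrix(rnorm(30), ncol = 3)
  q <- p
  q[, 1] <- -q[, 1]   # reflection: best proper fit is imperfect
  fit <- kabschSuperpose(p, q)
  expect_equal(det(fit$transform@rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0.1)
})

test_that("degenerate correspondences are rejected", {
  p2 <- matrix(rnorm(6), ncol = 3)
  expect_error(kabschSuperpose(p2, p2), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabschSuperpose(line, line), "collinear")
})

test_that("self-refinement of hydroxyl torsions is a no-op", {
  srb <- dropHydrogens(buildSorbitol())
  out <- refineHydroxylTorsions(srb, srb)
  expect_equal(atoms(out)$x, atoms(srb)$x, tolerance = 1e-9)
  obj <- attr(out, "objective")
  expect_lt(obj[length(obj)], 1e-12)
})

test_that("single-torsion refinement matches a half-degree grid search", {
  ref <- dropHydrogens(buildSorbitol())
  # perturb one terminal backbone torsion of a copy
  mob <- ref
  xyz <- as.matrix(atoms(mob)[, c("x", "y", "z")])
  bb <- mob@backbone
  axisA <- xyz[bb[5], ]; axisB <- xyz[bb[6], ]
  u <- (axisB - axisA) / sqrt(sum((axisB - axisA)^2))
  moving <- mob@hydroxylMap[["6"]]
  rot <- PocketSwap:::.rotationMatrix(u, 70 * pi / 180)
  xyz[moving, ] <- (xyz[moving, , drop = FALSE] -
                      matrix(axisB, 1, 3)) %*% t(rot) + matrix(axisB, 1, 3)
  mob@atoms$x <- xyz[, 1]; mob@atoms$y <- xyz[, 2]; mob@atoms$z <- xyz[, 3]
  out <- refineHydroxylTorsions(mob, ref)
  obj <- attr(out, "objective")
  # grid oracle over the perturbed torsion
  objAt <- function(theta) {
    x2 <- xyz
    rot <- PocketSwap:::.rotationMatrix(u, theta)
    x2[moving, ] <- (x2[moving, , drop = FALSE] -
                       matrix(axisB, 1, 3)) %*% t(rot) + matrix(axisB, 1, 3)
    refXyz <- as.matrix(atoms(ref)[, c("x", "y", "z")])
    pos <- setdiff(names(ref@hydroxylMap), "3")
    sum((x2[mob@hydroxylMap[pos], ] - refXyz[ref@hydroxylMap[pos], ])^2)
  }
  grid <- seq(-pi, pi, by = 0.5 * pi / 180)
  gridBest <- min(vapply(grid, objAt, numeric(1)))
  # agreement within the resolution of the half-degree grid
  expect_lte(obj[length(obj)], gridBest + 1e-4)
})

test_that("the excluded hydroxyl does not influence refinement", {
  ref <- dropHydrogens(buildSorbitol())
  mob <- applyTransform(ref, new("RigidTransform",
                                 rotation = diag(3),
                                 translation = c(0.2, -0.1, 0.15)))
  refPerturbed <- ref
  o3 <- ref@hydroxylMap[["3"]]
  refPerturbed@atoms$x[o3] <- refPerturbed@atoms$x[o3] + 2
  out1 <- refineHydroxylTorsions(mob, ref, excludedCarbon = 3)
  out2 <- refineHydroxylTorsions(mob, refPerturbed, excludedCarbon = 3)
  expect_equal(atoms(out1)$x, atoms(out2)$x, tolerance = 1e-12)
})

test_that("docking a ligand onto itself leaves every atom in place", {
  al <- dropHydrogens(buildAllitol())
  placed <- dockByBackbone(al, al)
  expect_lt(max(abs(as.matrix(atoms(placed)[, c("x", "y", "z")]) -
                      as.matrix(atoms(al)[, c("x", "y", "z")]))), 1e-6)
  expect_gte(attr(placed, "iterations"), 1L)
})

test_that("sorbitol docks onto allitol below 0.5 A backbone rmsd, stereo intact", {
  al <- dropHydrogens(buildAllitol())
  srb <- dropHydrogens(buildSorbitol())
  tf <- new("RigidTransform", rotation = randomRotation(),
            translation = c(8, -5, 3))
  set.seed(11)
  srbMoved <- applyTransform(srb, tf)
  placed <- dockByBackbone(srbMoved, al)
  expect_lt(attr(placed, "rmsd"), 0.5)
  expect_identical(descriptors(stereoDescriptors(placed)),
                   descriptors(sorbitolConfig()))
  # objective trace non-increasing within the final refinement
  obj <- attr(placed, "objective")
  if (!is.null(obj)) expect_true(all(diff(obj) <= 1e-9))
})

test_that("backbone length mismatches are rejected", {
  al <- dropHydrogens(buildAllitol())
  pent <- dropHydrogens(buildAlditol(setNames(c("R", "R", "R"),
                                              as.character(2:4))))
  expect_error(dockByBackbone(pent, al), "length mismatch")
})

test_that("ligand swap replaces the heteroatoms and nothing else", {
  pk <- standardPocket()
  al <- dropHydrogens(buildAllitol())
  placed <- dockByBackbone(al, pk$ligand)
  swapped <- swapLigand(pk$model, "SOR", placed, newCode = "X9X")
  aOld <- atoms(pk$model); aNew <- atoms(swapped)
  expect_equal(sum(aNew$recordKind == "ATOM"), sum(aOld$recordKind == "ATOM"))
  expect_equal(sum(aNew$recordKind == "HETATM"), nAtoms(placed))
  expect_true(all(aNew$resName[aNew$recordKind == "HETATM"] == "X9X"))
  # protein coordinates untouched
  expect_same_atoms(aNew[aNew$recordKind == "ATOM", ],
                    aOld[aOld$recordKind == "ATOM", ])
  # swapping a ligand for itself reproduces the complex geometry
  same <- swapLigand(pk$model, "SOR", pk$ligand)
  expect_same_atoms(atoms(same), atoms(pk$model), tol = 1e-9)
  # the swapped complex survives a serialization round trip
  f <- tempfile(fileext = ".pdb")
  writePdb(swapped, f)
  back <- readPdb(f)
  expect_equal(nAtoms(back), nAtoms(swapped))
})
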