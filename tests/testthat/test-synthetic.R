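# The fixture generator: planted geometry, determinism, dimerization and
# stereo pairs.

test_that("planted polar contacts are recovered exactly", {
  spec <- new("FixtureSpec", seed = 2L,
              plantedContacts = data.frame(resName = c("SER", "LYS", "ASN"),
                                           distance = c(2.9, 2.9, 2.9),
                                           stringsAsFactors = FALSE))
  pk <- makePocket(spec)
  pc <- polarContacts(pk$model, pk$ligand)
  expect_equal(nrow(pc), 3L)
  expect_equal(sort(pc$distance), rep(2.9, 3), tolerance = 0.05)
})

test_that("generation is deterministic for a fixed seed", {
  spec <- new("FixtureSpec", seed = 5L, nPocketResidues = 4L,
              plantedContacts = data.frame(resName = "HIS", distance = 3.0))
  p1 <- makePocket(spec)
  p2 <- makePocket(spec)
  expect_identical(atoms(p1$model), atoms(p2$model))
  expect_identical(p1$truth$residues, p2$truth$residues)
  # and the global RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(makePocket(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("infeasible plantings fail loudly", {
  spec <- new("FixtureSpec", seed = 1L,
              plantedContacts = data.frame(
                resName = rep("TRP", 14), distance = rep(2.9, 14),
                stringsAsFactors = FALSE))
  expect_error(makePocket(spec), "infeasible")
})

test_that("dimerization doubles the assembly and the monomer is recoverable", {
  pk <- standardPocket()
  dimer <- makeDimer(pk$model)
  expect_equal(nAtoms(dimer), 2L * nAtoms(pk$model))
  expect_setequal(unique(atoms(dimer)$chainId), c("A", "B"))
  expect_equal(sum(atoms(dimer)$resName == "SOR" &
                     !duplicated(paste(atoms(dimer)$chainId,
                                       atoms(dimer)$resSeq))), 2L)
  monA <- extractMonomer(dimer, "A")
  expect_same_atoms(atoms(monA), atoms(pk$model))
  # the two chains do not touch
  a <- atoms(dimer)
  dA <- as.matrix(a[a$chainId == "A", c("x", "y", "z")])
  dB <- as.matrix(a[a$chainId == "B", c("x", "y", "z")])
  expect_gt(min(PocketSwap:::.crossDist(dA, dB)), 15)
})

test_that("stereo pairs differ at exactly the requested center", {
  for (pos in 2:5) {
    pair <- makeStereoPair(pos)
    dr <- descriptors(stereoDescriptors(pair$reference))
    de <- descriptors(stereoDescriptors(pair$epimer))
    expect_identical(names(which(dr != de)), as.character(pos))
    expect_identical(molecularFormula(pair$reference),
                     molecularFormula(pair$epimer))
  }
  expect_error(makeStereoPair(6), "internal carbon")
})

test_that("an epimer docks onto its reference with a tight backbone fit", {
  pair <- makeStereoPair(3)
  set.seed(6)
  moved <- applyTransform(dropHydrogens(pair$epimer),
                          new("RigidTransform", rotation = randomRotation(),
                              translation = c(5, 5, -5)))
  placed <- dockByBackbone(moved, dropHydrogens(pair$reference))
  expect_lt(attr(placed, "rmsd"), 0.5)
})

test_that("fixtures serialize to PDB files the reader accepts", {
  pk <- designablePocket()
  f <- tempfile(fileext = ".pdb")
  writePdb(pk$model, f)
  m <- readPdb(f)
  expect_equal(nAtoms(m), nAtoms(pk$model))
  expect_equal(nAtoms(extractLigand(m, "SOR")), nAtoms(pk$ligand))
})

test_that("the designable site is inside the pocket and initially apolar", {
  pk <- designablePocket()
  rs <- pk$truth$designable$resSeq
  rw <- residuesWithin(pk$model, pk$ligand, 4.0)
  expect_true(rs %in% rw$resSeq)
  pc <- polarContacts(pk$model, pk$ligand)
  expect_false(rs %in% pc$resSeq)
})
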