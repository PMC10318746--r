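# Metropolis packing, minimization, relax and the resfile format.

test_that("metropolis criterion: downhill always, uphill at exp(-dE/kT)", {
  expect_true(all(vapply(1:50, function(i) metropolisStep(-1, 1),
                         logical(1))))
  set.seed(13)
  acc <- vapply(seq_len(1e5), function(i) metropolisStep(1, 1), logical(1))
  expect_equal(mean(acc), exp(-1), tolerance = 0.01)
  # near-zero temperature is greedy descent
  set.seed(14)
  accCold <- vapply(seq_len(1e4), function(i) metropolisStep(1, 1e-3),
                    logical(1))
  expect_equal(sum(accCold), 0L)
  expect_error(metropolisStep(1, 0))
})

test_that("an all-NATRO spec leaves the structure untouched", {
  pk <- standardPocket()
  out <- packResidues(pk$model, designSpec(defaultMode = "NATRO"))
  expect_same_atoms(atoms(out$model), atoms(pk$model))
  expect_equal(nrow(out$trajectory), 0L)
})

test_that("packing equals exhaustive enumeration on a small design problem", {
  pk <- designablePocket()
  rs <- pk$truth$designable$resSeq
  idents <- c("VAL", "SER", "CYS")          # 3 identities x 3 rotamers = 9
  lib <- defaultRotamerLibrary()
  bestE <- Inf; bestAss <- NULL
  for (aa in idents) {
    chis <- lib@rotamers[[aa]]$chi
    for (ri in seq_len(nrow(chis))) {
      m <- mutateResidue(pk$model, "A", rs, aa, chis[ri, ],
                         warnProline = FALSE)
      e <- scoreEnergy(m)@total
      if (e < bestE) { bestE <- e; bestAss <- c(aa, ri) }
    }
  }
  sched <- new("AnnealingSchedule", nSteps = 120L, seed = 3L)
  out <- packResidues(pk$model, designSpec("A", rs, "ALLAA"),
                      sched, allowedAA = idents)
  expect_equal(out$energy, bestE, tolerance = 1e-9)
  expect_equal(out$assignments$resName, bestAss[1])
})

test_that("packing is deterministic for a fixed seed", {
  pk <- designablePocket()
  rs <- pk$truth$designable$resSeq
  sched <- new("AnnealingSchedule", nSteps = 40L, seed = 17L)
  run <- function() packResidues(pk$model, designSpec("A", rs, "ALLAA"),
                                 sched,
                                 allowedAA = pk$truth$designable$alphabet)
  o1 <- run(); o2 <- run()
  expect_identical(o1$trajectory, o2$trajectory)
  expect_same_atoms(atoms(o1$model), atoms(o2$model))
})

test_that("design recovers the planted gain-of-contact identity", {
  pk <- designablePocket()
  rs <- pk$truth$designable$resSeq
  before <- nrow(polarContacts(pk$model, pk$ligand))
  sched <- new("AnnealingSchedule", nSteps = 150L, seed = 11L)
  out <- packResidues(pk$model, designSpec("A", rs, "ALLAA"), sched,
                      allowedAA = pk$truth$designable$alphabet)
  after <- nrow(polarContacts(out$model, extractLigand(out$model, "SOR")))
  expect_gt(after, before)
  expect_equal(out$assignments$resName, pk$truth$designable$gainIdentity)
})

test_that("torsion minimization solves a quadratic toy to its analytic minimum", {
  pk <- standardPocket()
  a <- atoms(pk$model)
  serRows <- which(a$resSeq == 10)   # planted HIS; use its chi1 torsion
  tor <- chiTorsions(pk$model, data.frame(chainId = "A", resSeq = 10))[[1]]
  target <- 37 * pi / 180
  chiOf <- function(m) residueChi(m, "A", 10)[1] * pi / 180
  toy <- function(m) {
    d <- chiOf(m) - target
    d <- atan2(sin(d), cos(d))
    5 * d^2
  }
  out <- minimizeTorsions(pk$model, list(tor), energyFn = toy,
                          tol = 1e-10, maxSweeps = 80, step0 = 0.5)
  expect_lt(abs(atan2(sin(chiOf(out$model) - target),
                      cos(chiOf(out$model) - target))), 1e-4)
  expect_lte(out$energy, out$initialEnergy)
  # restarting at the minimum changes nothing
  out2 <- minimizeTorsions(out$model, list(tor), energyFn = toy,
                           tol = 1e-10, maxSweeps = 10, step0 = 0.5)
  expect_lt(abs(chiOf(out2$model) - chiOf(out$model)), 1e-4)
})

test_that("minimization never raises the reduced-model energy", {
  pk <- standardPocket()
  out <- minimizeTorsions(pk$model, chiTorsions(pk$model), maxSweeps = 3)
  expect_lte(out$energy, out$initialEnergy)
  expect_error(minimizeTorsions(pk$model, list(),
                                energyFn = function(m) NaN), "non-finite")
})

test_that("relax resolves a planted clash and reports its best energy", {
  spec <- new("FixtureSpec", seed = 3L, nPocketResidues = 3L,
              plantedContacts = data.frame(resName = c("SER", "GLN"),
                                           distance = c(2.9, 3.1),
                                           stringsAsFactors = FALSE),
              plantedClash = TRUE)
  pk <- makePocket(spec)
  e0 <- scoreEnergy(pk$model)@total
  out <- relaxComplex(pk$model, nCycles = 1, stepsPerStage = 30, seed = 5)
  expect_lt(out$energy, e0)
  a <- atoms(out$model)
  prot <- as.matrix(a[a$recordKind == "ATOM", c("x", "y", "z")])
  lig <- as.matrix(a[a$recordKind == "HETATM", c("x", "y", "z")])
  minD <- min(PocketSwap:::.crossDist(prot, lig))
  expect_gt(minD, 2.4)
  # zero cycles is the identity
  id <- relaxComplex(pk$model, nCycles = 0)
  expect_same_atoms(atoms(id$model), atoms(pk$model))
})

test_that("repeated fixed-temperature optimization keeps the best sweep", {
  pk <- designablePocket()
  rs <- pk$truth$designable$resSeq
  spec <- designSpec("A", rs, "ALLAA")
  e0 <- scoreEnergy(pk$model)@total
  out <- repeatOptimize(pk$model, spec, kT = 1, n = 5, stepsPerSweep = 15,
                        seed = 2)
  expect_lte(out$energy, e0)
  expect_equal(out$energy, min(c(out$sweepEnergies, e0)))
  expect_gt(stats::var(out$sweepEnergies), 0)  # frustrated landscape
  # n = 1 equals a single sweep
  one <- repeatOptimize(pk$model, spec, kT = 1, n = 1, stepsPerSweep = 15,
                        seed = 2)
  expect_equal(one$sweepEnergies, out$sweepEnergies[1])
})

test_that("resfiles round-trip and malformed lines are rejected", {
  spec <- designSpec(c("A", "A", "B"), c(63L, 64L, 137L),
                     c("ALLAA", "NATAA", "NATRO"), defaultMode = "NATRO")
  f <- tempfile(fileext = ".resfile")
  writeResfile(spec, f)
  back <- readResfile(f)
  expect_identical(back@residues, spec@residues)
  expect_identical(back@defaultMode, "NATRO")
  bad <- tempfile()
  writeLines(c("DEFAULT NATRO", "63 A"), bad)
  expect_error(readResfile(bad), "malformed")
})

test_that("specs naming absent residues are rejected", {
  pk <- standardPocket()
  expect_error(packResidues(pk$model, designSpec("A", 777L, "ALLAA")),
               "absent")
})

test_that("mutation rebuilds side chains on a fixed backbone", {
  pk <- standardPocket()
  m <- mutateResidue(pk$model, "A", 10L, "TYR", c(-60, 90))
  a0 <- atoms(pk$model); a1 <- atoms(m)
  r0 <- a0[a0$resSeq == 10, ]; r1 <- a1[a1$resSeq == 10, ]
  expect_equal(r1$resName[1], "TYR")
  expect_true(all(c("CB", "CG", "CZ", "OH") %in% r1$name))
  for (nm in c("N", "CA", "C", "O")) {
    expect_equal(unlist(r1[r1$name == nm, c("x", "y", "z")]),
                 unlist(r0[r0$name == nm, c("x", "y", "z")]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # measured chi equals the requested rotamer
  expect_equal(residueChi(m, "A", 10L), c(-60, 90), tolerance = 1e-6)
  expect_warning(mutateResidue(pk$model, "A", 10L, "PRO"), "PRO")
})
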