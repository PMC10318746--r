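# PDB reading, writing and monomer / ligand extraction.

writeTinyPdb <- function(path) {
  # hand-written 5-atom single-residue file, fixed v3.3 columns
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.143  -4.934  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.531   7.354  -5.816  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      12.247   4.676  -4.963  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

test_that("a hand-written five-atom file parses into one chain, one residue", {
  f <- writeTinyPdb(tempfile(fileext = ".pdb"))
  m <- readPdb(f)
  expect_s4_class(m, "PdbStructure")
  expect_equal(nAtoms(m), 5L)
  expect_equal(chainIds(m), "A")
  rt <- residueTable(m)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$resName, "ALA")
  expect_equal(rt$nAtoms, 5L)
  expect_equal(atoms(m)$name, c("N", "CA", "C", "O", "CB"))
})

test_that("missing files and empty structures are rejected", {
  expect_error(readPdb(tempfile()), "cannot read")
  expect_error(writePdb(new("PdbStructure"), tempfile(fileext = ".pdb")),
               "empty")
})

test_that("write/read round trip preserves the atom table to format precision", {
  pk <- standardPocket()
  f <- tempfile(fileext = ".pdb")
  writePdb(pk$model, f)
  m2 <- readPdb(f)
  a1 <- atoms(pk$model); a2 <- atoms(m2)
  expect_identical(a2$name, a1$name)
  expect_identical(a2$resName, a1$resName)
  expect_identical(a2$resSeq, a1$resSeq)
  expect_identical(a2$recordKind, a1$recordKind)
  expect_lt(max(abs(a2$x - a1$x), abs(a2$y - a1$y), abs(a2$z - a1$z)), 1e-3)
  # second round trip is textually stable
  f2 <- tempfile(fileext = ".pdb")
  writePdb(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("monomer extraction halves a symmetric homodimer and is idempotent", {
  pk <- standardPocket()
  dimer <- makeDimer(pk$model)
  expect_equal(nAtoms(dimer), 2L * nAtoms(pk$model))
  monA <- extractMonomer(dimer, "A")
  expect_equal(nAtoms(monA), nAtoms(pk$model))
  expect_same_atoms(atoms(monA), atoms(pk$model))
  monAA <- extractMonomer(monA, "A")
  expect_same_atoms(atoms(monAA), atoms(monA))
  expect_error(extractMonomer(dimer, "Q"), "not present")
})

test_that("monomer extraction equals a brute-force chain filter", {
  pk <- standardPocket()
  a <- atoms(pk$model)
  # build a 3-chain model by relabeling copies
  b <- a; b$chainId <- "B"; b$x <- b$x + 40
  c3 <- a; c3$chainId <- "C"; c3$x <- c3$x + 80
  tri <- new("PdbStructure", atoms = {
    z <- rbind(a, b, c3); z$serial <- seq_len(nrow(z)); z
  })
  got <- atoms(extractMonomer(tri, "B"))
  oracle <- atoms(tri)[atoms(tri)$chainId == "B", , drop = FALSE]
  rownames(oracle) <- NULL
  expect_same_atoms(got, oracle)
})

test_that("orphan heteroatoms are assigned to the nearest protein chain", {
  pk <- standardPocket()
  dimer <- makeDimer(pk$model)
  a <- atoms(dimer)
  a$chainId[a$recordKind == "HETATM"] <- ""   # strip ligand chain ids
  stripped <- new("PdbStructure", atoms = a)
  monA <- extractMonomer(stripped, "A")
  expect_equal(sum(atoms(monA)$recordKind == "HETATM"),
               sum(atoms(pk$model)$recordKind == "HETATM"))
})

test_that("ligand extraction returns exactly the heteroatom residue", {
  pk <- standardPocket()
  lig <- extractLigand(pk$model, "SOR")
  expect_s4_class(lig, "Ligand")
  nHet <- sum(atoms(pk$model)$recordKind == "HETATM")
  expect_equal(nAtoms(lig), nHet)
  expect_error(extractLigand(pk$model, "ZZZ"), "not found")
  # extraction plus removal partition the atoms
  rest <- removeLigand(pk$model, "SOR")
  expect_equal(nAtoms(rest) + nAtoms(lig), nAtoms(pk$model))
  # two copies without a chain selector fail loudly
  dimer <- makeDimer(pk$model)
  expect_error(extractLigand(dimer, "SOR"), "multiple")
  expect_equal(nAtoms(extractLigand(dimer, "SOR", chain = "B")), nHet)
})

test_that("a real crystal structure parses", {
  f <- system.file("examples", "1hel.pdb", package = "bio3d")
  m <- readPdb(f)
  expect_gt(nAtoms(m), 900)
  expect_false(any(atoms(m)$resName == "HOH"))
})

test_that("waters are dropped by default and retained on request", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.530   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), f)
  expect_equal(nAtoms(readPdb(f)), 2L)
  withWater <- readPdb(f, keepWaters = TRUE)
  expect_equal(nAtoms(withWater), 3L)
  expect_true("HOH" %in% atoms(withWater)$resName)
})
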