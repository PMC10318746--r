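# Pocket residue selection and polar-contact detection.

test_that("pocket selection matches planted distances exactly", {
  spec <- new("FixtureSpec", seed = 21L,
              plantedContacts = data.frame(
                resName = c("VAL", "LEU", "ILE"),
                distance = c(3.0, 3.9, 4.1), stringsAsFactors = FALSE))
  pk <- makePocket(spec)
  rw <- residuesWithin(pk$model, pk$ligand, 4.0)
  expect_equal(nrow(rw), 2L)
  expect_equal(sort(rw$minDist), c(3.0, 3.9), tolerance = 0.05)
  expect_equal(nrow(residuesWithin(pk$model, pk$ligand, 0)), 0L)
})

test_that("pocket selection equals the brute-force all-pairs filter", {
  pk <- standardPocket()
  a <- atoms(pk$model)
  prot <- a[a$recordKind == "ATOM", , drop = FALSE]
  lxyz <- as.matrix(atoms(pk$ligand)[, c("x", "y", "z")])
  for (cutoff in c(2, 3.5, 4, 6, 9)) {
    keep <- character(0)
    for (i in seq_len(nrow(prot))) {       # explicit double loop oracle
      p <- c(prot$x[i], prot$y[i], prot$z[i])
      for (j in seq_len(nrow(lxyz))) {
        if (sqrt(sum((p - lxyz[j, ])^2)) <= cutoff) {
          keep <- union(keep, paste(prot$chainId[i], prot$resSeq[i]))
          break
        }
      }
    }
    got <- residuesWithin(pk$model, pk$ligand, cutoff)
    expect_setequal(paste(got$chainId, got$resSeq), keep)
  }
})

test_that("pocket selection is monotone in the cutoff", {
  pk <- standardPocket()
  cuts <- c(0, 2, 3, 3.5, 4, 5, 7, 10)
  sets <- lapply(cuts, function(cc)
    paste(residuesWithin(pk$model, pk$ligand, cc)$resSeq))
  for (k in seq_along(cuts)[-1])
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
})

test_that("polar contacts obey the distance window", {
  mk <- function(d) {
    # SER OG donor vs a ligand hydroxyl oxygen at distance d, with
    # antecedent carbons placed behind each polar atom
    prot <- data.frame(serial = 1:2, name = c("CB", "OG"), altLoc = "",
                       resName = "SER", chainId = "A", resSeq = 1L,
                       x = c(-1.45, 0), y = 0, z = 0, occupancy = 1,
                       bFactor = 0, element = c("C", "O"),
                       recordKind = "ATOM", stringsAsFactors = FALSE)
    lig <- data.frame(serial = 3:4, name = c("O1", "C1"), altLoc = "",
                      resName = "LIG", chainId = "A", resSeq = 9L,
                      x = c(d, d + 1.43), y = 0, z = 0, occupancy = 1,
                      bFactor = 0, element = c("O", "C"),
                      recordKind = "HETATM", stringsAsFactors = FALSE)
    model <- new("PdbStructure", atoms = rbind(prot, lig))
    list(model = model, ligand = extractLigand(model, "LIG"))
  }
  good <- mk(2.9)
  expect_equal(nrow(polarContacts(good$model, good$ligand)), 1L)
  expect_equal(nrow(polarContacts(mk(5.0)$model, mk(5.0)$ligand)), 0L)
  expect_equal(nrow(polarContacts(mk(2.0)$model, mk(2.0)$ligand)), 0L)
})

test_that("the antecedent angle criterion rejects occluded geometries", {
  # antecedent carbon placed between donor and acceptor: angle ~ 0
  prot <- data.frame(serial = 1:2, name = c("CB", "OG"), altLoc = "",
                     resName = "SER", chainId = "A", resSeq = 1L,
                     x = c(1.45, 0), y = 0, z = 0, occupancy = 1,
                     bFactor = 0, element = c("C", "O"),
                     recordKind = "ATOM", stringsAsFactors = FALSE)
  lig <- data.frame(serial = 3:4, name = c("O1", "C1"), altLoc = "",
                    resName = "LIG", chainId = "A", resSeq = 9L,
                    x = c(2.9, 4.33), y = 0, z = 0, occupancy = 1,
                    bFactor = 0, element = c("O", "C"),
                    recordKind = "HETATM", stringsAsFactors = FALSE)
  model <- new("PdbStructure", atoms = rbind(prot, lig))
  expect_equal(nrow(polarContacts(model, extractLigand(model, "LIG"))), 0L)
})

test_that("planted polar contacts are each detected exactly once", {
  pk <- standardPocket()
  pc <- polarContacts(pk$model, pk$ligand)
  expect_equal(nrow(pc), pk$truth$nPolarContacts)
  expect_false(any(duplicated(pc[, c("resSeq", "proteinAtom",
                                     "partnerAtom")])))
  # contacts live inside the polar-distance pocket
  rw <- residuesWithin(pk$model, pk$ligand, 3.5)
  expect_true(all(pc$resSeq %in% rw$resSeq))
})

test_that("unknown residue types are skipped with a warning", {
  pk <- standardPocket()
  a <- atoms(pk$model)
  a$resName[a$resSeq == 10] <- "XXX"
  m <- new("PdbStructure", atoms = a)
  expect_warning(pc <- polarContacts(m, pk$ligand), "XXX")
  expect_false(any(pc$resSeq == 10))
})

test_that("contact report tabulates states, deltas and totals", {
  pk <- standardPocket()
  pc <- polarContacts(pk$model, pk$ligand)
  same <- contactReport(pc, pc)
  tot <- same$table[same$table$resName == "TOTAL", ]
  expect_equal(tot$before, nrow(pc))
  expect_equal(tot$delta, 0L)
  expect_true(all(same$table$delta == 0L))
  # planted gain of one contact
  gain <- rbind(pc, pc[1, ])
  rep2 <- contactReport(pc, gain)
  row1 <- rep2$table[rep2$table$resSeq %in% pc$resSeq[1], ]
  expect_equal(row1$delta, 1L)
  # totals equal independent per-residue summation
  perRes <- table(pc$resSeq)
  tot2 <- rep2$table[rep2$table$resName == "TOTAL", ]
  expect_equal(tot2$before, sum(perRes))
  expect_equal(tot2$after, sum(perRes) + 1L)
})

test_that("zero-contact pocket residues are reported as potential sites", {
  pk <- designablePocket()
  pc <- polarContacts(pk$model, pk$ligand)
  rw <- residuesWithin(pk$model, pk$ligand, 4.0)
  rep <- contactReport(pc, pocketResidues = rw)
  expect_true(pk$truth$designable$resSeq %in% rep$potential$resSeq)
  expect_false(any(rep$potential$resSeq %in% pc$resSeq))
})

test_that("residue-residue polar contacts count each pair once", {
  # two serines hydrogen bonded to each other
  mkSer <- function(rs, x0) {
    data.frame(serial = 0L, name = c("CB", "OG"), altLoc = "",
               resName = "SER", chainId = "A", resSeq = rs,
               x = c(x0 + 1.45 * sign(x0), x0), y = 0, z = 0,
               occupancy = 1, bFactor = 0, element = c("C", "O"),
               recordKind = "ATOM", stringsAsFactors = FALSE)
  }
  a <- rbind(mkSer(1L, -1.45), mkSer(2L, 1.45))
  a$serial <- seq_len(nrow(a))
  m <- new("PdbStructure", atoms = a)
  rr <- residuePolarContacts(m, data.frame(chainId = "A", resSeq = 1:2))
  expect_equal(nrow(rr), 1L)
  expect_equal(rr$kind, "residue-residue")
})
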