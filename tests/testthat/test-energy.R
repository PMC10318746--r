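# Reduced energy model: closed forms, invariances, brute-force oracle.

test_that("two uncharged carbons at the LJ minimum score exactly -epsilon", {
  ff <- defaultForceField()
  sigma <- ff@types$sigma[ff@types$type == "C3"]
  eps <- ff@types$epsilon[ff@types$type == "C3"]
  eb <- scoreEnergy(twoCarbonModel(2^(1 / 6) * sigma))
  expect_equal(eb@lj, -eps, tolerance = 1e-12)
  expect_equal(eb@coulomb, 0)
  expect_equal(eb@hbond, 0)
  expect_equal(eb@total, eb@lj + eb@coulomb + eb@hbond + eb@torsion,
               tolerance = 1e-9)
})

test_that("repulsion grows monotonically as nonbonded atoms approach", {
  # separations kept above the covalent-perception threshold so the pair
  # stays nonbonded
  rs <- c(3.4, 3.0, 2.6, 2.3, 2.05)
  es <- vapply(rs, function(r) scoreEnergy(twoCarbonModel(r))@lj, numeric(1))
  expect_true(all(diff(es) > 0))   # decreasing r = increasing energy
  expect_gt(es[length(es)], 100)
})

test_that("the score is invariant under rigid transforms", {
  pk <- standardPocket()
  e0 <- scoreEnergy(pk$model)
  set.seed(5)
  tf <- new("RigidTransform", rotation = randomRotation(),
            translation = c(30, -12, 8))
  e1 <- scoreEnergy(applyTransform(pk$model, tf))
  expect_equal(e1@lj, e0@lj, tolerance = 1e-9)
  expect_equal(e1@coulomb, e0@coulomb, tolerance = 1e-9)
  expect_equal(e1@hbond, e0@hbond, tolerance = 1e-9)
  expect_equal(e1@torsion, e0@torsion, tolerance = 1e-9)
})

test_that("the pairwise sum equals an explicit double-loop oracle", {
  # free-floating polar and apolar single-atom residues, random positions
  set.seed(9)
  n <- 50
  resNames <- rep(c("SER", "ALA"), length.out = n)
  atomNames <- ifelse(resNames == "SER", "OG", "CB")
  # rejection-sample positions at pairwise separation > 2 A so that no
  # pair is perceived as covalently bonded
  xyz <- matrix(NA_real_, n, 3)
  k <- 0
  while (k < n) {
    p <- runif(3, 0, 14)
    if (k == 0 ||
        min(sqrt(rowSums(sweep(xyz[seq_len(k), , drop = FALSE], 2, p)^2))) > 2) {
      k <- k + 1
      xyz[k, ] <- p
    }
  }
  m <- atomsModel(resNames, atomNames, xyz)
  ff <- defaultForceField()
  eb <- scoreEnergy(m)
  # oracle: plain loops, same formulas, independent bookkeeping
  sig <- ifelse(atomNames == "OG", ff@types$sigma[ff@types$type == "OH"],
                ff@types$sigma[ff@types$type == "C3"])
  eps <- ifelse(atomNames == "OG", ff@types$epsilon[ff@types$type == "OH"],
                ff@types$epsilon[ff@types$type == "C3"])
  q <- ifelse(atomNames == "OG", -0.30, 0)
  swit <- function(r) {
    if (r >= ff@cutoff) return(0)
    if (r <= ff@switchStart) return(1)
    rc2 <- ff@cutoff^2; rs2 <- ff@switchStart^2; r2 <- r^2
    (rc2 - r2)^2 * (rc2 + 2 * r2 - 3 * rs2) / (rc2 - rs2)^3
  }
  # identify hydrogen-bonded pairs the same way the model defines them:
  # isolated O atoms have no antecedent, so the distance window decides
  hb <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (atomNames[i] == "OG" && atomNames[j] == "OG" &&
        r >= 2.4 && r <= 3.5) hb[i, j] <- TRUE
  }
  lj <- 0; coul <- 0; nhb <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (hb[i, j]) nhb <- nhb + 1
    if (r < ff@cutoff) {
      s <- (sig[i] + sig[j]) / 2
      e <- sqrt(eps[i] * eps[j])
      lj <- lj + swit(r) * 4 * e * ((s / r)^12 - (s / r)^6)
      if (!hb[i, j])
        coul <- coul + swit(r) * ff@coulombConstant * q[i] * q[j] /
          (ff@dielectricSlope * r^2)
    }
  }
  expect_equal(eb@lj, lj, tolerance = 1e-6)
  expect_equal(eb@coulomb, coul, tolerance = 1e-6)
  expect_equal(eb@hbond, ff@hbondEnergy * nhb, tolerance = 1e-9)
})

test_that("non-interacting parts are additive: dG of a far ligand is ~0", {
  pk <- standardPocket()
  a <- atoms(pk$model)
  far <- a$recordKind == "HETATM"
  a$x[far] <- a$x[far] + 100
  m <- new("PdbStructure", atoms = a)
  g <- scoreParts(m, "SOR")
  expect_equal(unname(g["GC"] - (g["GP"] + g["GL"])), 0, tolerance = 1e-9)
})

test_that("a planted favorable contact gives a negative binding energy", {
  pk <- standardPocket()
  g <- scoreParts(pk$model, "SOR")
  expect_lt(deltaGBind(g["GC"], g["GP"], g["GL"]), 0)
})

test_that("untypable atoms are reported by name", {
  a <- atoms(twoCarbonModel(4))
  a$name[1] <- "QQ"
  expect_error(scoreEnergy(new("PdbStructure", atoms = a)), "QQ")
  expect_error(scoreParts(standardPocket()$model, "ZZZ"), "not found")
})

test_that("the shipped parameter file loads with consistent tables", {
  ff <- readForceField()
  expect_s4_class(ff, "ForceFieldParams")
  expect_true(all(ff@charges$type %in% ff@types$type))
  expect_true(all(ff@types$sigma > 0 & ff@types$epsilon > 0))
  # neutral side chains sum to zero over side-chain atoms
  sc <- ff@charges[ff@charges$resName %in% c("SER", "THR", "ASN", "GLN",
                                             "HIS", "CYS", "TYR", "TRP",
                                             "MET"), ]
  sums <- tapply(sc$charge, sc$resName, sum)
  expect_true(all(abs(sums) < 0.11))
  # charged side chains carry unit charge
  for (res in c("ASP", "GLU")) {
    s <- sum(ff@charges$charge[ff@charges$resName == res])
    expect_equal(s, -1, tolerance = 1e-9)
  }
  for (res in c("LYS", "ARG")) {
    s <- sum(ff@charges$charge[ff@charges$resName == res])
    expect_equal(s, 1, tolerance = 1e-9)
  }
})
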