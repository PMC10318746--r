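# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

.fixtureCache <- new.env(parent = emptyenv())

# A pocket with three planted polar contacts, reused across test files.
standardPocket <- function() {
  if (is.null(.fixtureCache$standard)) {
    spec <- new("FixtureSpec", seed = 7L, nPocketResidues = 5L,
                plantedContacts = data.frame(
                  resName = c("HIS", "ARG", "GLN"),
                  distance = c(2.9, 3.0, 3.1), stringsAsFactors = FALSE))
    .fixtureCache$standard <- makePocket(spec)
  }
  .fixtureCache$standard
}

# A pocket with a designable gain-of-contact site.
designablePocket <- function() {
  if (is.null(.fixtureCache$designable)) {
    spec <- new("FixtureSpec", seed = 7L, nPocketResidues = 4L,
                plantedContacts = data.frame(
                  resName = c("HIS", "ARG"), distance = c(2.9, 3.0),
                  stringsAsFactors = FALSE),
                designableSite = TRUE)
    .fixtureCache$designable <- makePocket(spec)
  }
  .fixtureCache$designable
}

# Minimal structure of free-floating typed atoms (one single-atom residue
# per row), for energy-model tests.
atomsModel <- function(resNames, atomNames, xyz, recordKind = "ATOM") {
  n <- length(resNames)
  df <- data.frame(serial = seq_len(n), name = atomNames, altLoc = "",
                   resName = resNames, chainId = "A", resSeq = seq_len(n),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, bFactor = 0,
                   element = substr(atomNames, 1, 1),
                   recordKind = recordKind, stringsAsFactors = FALSE)
  new("PdbStructure", atoms = df)
}

# Two uncharged carbon probes at separation r.
twoCarbonModel <- function(r) {
  atomsModel(c("ALA", "ALA"), c("CB", "CB"),
             matrix(c(0, 0, 0, r, 0, 0), ncol = 3, byrow = TRUE))
}

randomRotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         nrow = 3, byrow = TRUE)
}

expect_same_atoms <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$name, b$name)
  expect_identical(a$resName, b$resName)
  expect_equal(a$x, b$x, tolerance = tol)
  expect_equal(a$y, b$y, tolerance = tol)
  expect_equal(a$z, b$z, tolerance = tol)
}
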