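# Fixed-backbone pocket design: Metropolis simulated annealing over
# (identity, rotamer) assignments, torsion-space minimization, and the
# repack/minimize relax protocol.

#' Construct a design specification
#'
#' @param chainId,resSeq,mode parallel vectors of residue selectors and
#'   modes (NATRO / NATAA / ALLAA).
#' @param defaultMode mode for unlisted residues (default NATRO).
#' @return a [DesignSpec-class].
#' @export
designSpec <- function(chainId = character(0), resSeq = integer(0),
                       mode = character(0), defaultMode = "NATRO") {
  new("DesignSpec",
      residues = data.frame(chainId = as.character(chainId),
                            resSeq = as.integer(resSeq),
                            mode = as.character(mode),
                            stringsAsFactors = FALSE),
      defaultMode = defaultMode)
}

#' Read a resfile-style design specification
#'
#' Text format: an optional `DEFAULT <mode>` header line followed by
#' `<resSeq> <chain> <mode>` lines, with modes NATRO, NATAA or ALLAA.
#'
#' @param path file to read.
#' @return a [DesignSpec-class].
#' @export
readResfile <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaultMode <- "NATRO"
  isDef <- grepl("^DEFAULT[[:space:]]", lines)
  if (any(isDef)) {
    defaultMode <- strsplit(lines[isDef][1], "[[:space:]]+")[[1]][2]
    lines <- lines[!isDef]
  }
  if (!length(lines)) return(designSpec(defaultMode = defaultMode))
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(toks, length, integer(1)) != 3
  if (any(bad)) stop("malformed resfile line(s): ",
                     paste(lines[bad], collapse = "; "))
  designSpec(chainId = vapply(toks, `[`, character(1), 2),
             resSeq = as.integer(vapply(toks, `[`, character(1), 1)),
             mode = vapply(toks, `[`, character(1), 3),
             defaultMode = defaultMode)
}

#' Write a design specification as a resfile
#'
#' @param spec a [DesignSpec-class].
#' @param path output file.
#' @return invisibly, the path written.
#' @export
writeResfile <- function(spec, path) {
  stopifnot(is(spec, "DesignSpec"))
  r <- spec@residues
  writeLines(c(paste("DEFAULT", spec@defaultMode),
               sprintf("%d %s %s", r$resSeq, r$chainId, r$mode)), path)
  invisible(path)
}

#' Metropolis acceptance criterion
#'
#' Downhill moves (deltaE <= 0) are always accepted; uphill moves are
#' accepted with probability exp(-deltaE / kT). Consumes one uniform
#' deviate from the current RNG stream for uphill moves.
#'
#' @param deltaE proposed energy change, reduced units.
#' @param kT temperature, reduced units (> 0).
#' @return logical: accept the move?
#' @export
metropolisStep <- function(deltaE, kT) {
  stopifnot(kT > 0)
  if (deltaE <= 0) return(TRUE)
  stats::runif(1) < exp(-deltaE / kT)
}

.resolveSpec <- function(model, spec) {
  a <- model@atoms
  prot <- a[a$recordKind == "ATOM", , drop = FALSE]
  key <- paste(prot$chainId, prot$resSeq)
  first <- !duplicated(key)
  res <- data.frame(chainId = prot$chainId[first], resSeq = prot$resSeq[first],
                    resName = prot$resName[first], stringsAsFactors = FALSE)
  listed <- paste(spec@residues$chainId, spec@residues$resSeq)
  if (length(listed) && !all(listed %in% paste(res$chainId, res$resSeq)))
    stop("design spec lists residue(s) absent from the model: ",
         paste(setdiff(listed, paste(res$chainId, res$resSeq)), collapse = ", "))
  hit <- match(paste(res$chainId, res$resSeq), listed)
  res$mode <- ifelse(is.na(hit), spec@defaultMode, spec@residues$mode[hit])
  res
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Repack and redesign residues by Metropolis simulated annealing
#'
#' Runs a Metropolis walk over (identity, rotamer) assignments for ALLAA
#' residues and rotamer assignments for NATAA residues, under geometric
#' cooling from `schedule@kTStart` to `schedule@kTEnd`. Each step rebuilds
#' one proposed residue on the fixed backbone and rescores the structure
#' with the reduced energy model; moves are accepted by the Metropolis
#' criterion. The best configuration ever seen is returned. Deterministic
#' for a fixed seed.
#'
#' @param complex a [PdbStructure-class].
#' @param spec a [DesignSpec-class].
#' @param schedule an [AnnealingSchedule-class]; by default the step count
#'   scales as 50 per designable residue.
#' @param library a [RotamerLibrary-class].
#' @param params a [ForceFieldParams-class].
#' @param criteria [ContactCriteria-class] for the hydrogen-bond term.
#' @param allowedAA identities offered at ALLAA positions (default all
#'   supported amino acids, proline included but flagged on acceptance).
#' @return list with `model` (best structure), `energy` (its total),
#'   `trajectory` (data.frame: step, kT, residue, proposal, deltaE,
#'   accepted, energy, best) and `assignments` (final per-residue
#'   identity and chi angles).
#' @export
packResidues <- function(complex, spec, schedule = NULL,
                         library = defaultRotamerLibrary(),
                         params = defaultForceField(),
                         criteria = new("ContactCriteria"),
                         allowedAA = designableAminoAcids()) {
  stopifnot(is(complex, "PdbStructure"), is(spec, "DesignSpec"))
  res <- .resolveSpec(complex, spec)
  design <- res[res$mode != "NATRO", , drop = FALSE]
  if (!nrow(design)) {
    return(list(model = complex,
                energy = scoreEnergy(complex, params, criteria)@total,
                trajectory = data.frame(), assignments = data.frame()))
  }
  if (is.null(schedule))
    schedule <- new("AnnealingSchedule", nSteps = 50L * nrow(design))
  stopifnot(is(schedule, "AnnealingSchedule"))
  .withSeed(schedule@seed, {
    cur <- complex
    curE <- scoreEnergy(cur, params, criteria)@total
    bestModel <- cur; bestE <- curE
    nS <- schedule@nSteps
    kTs <- schedule@kTStart *
      (schedule@kTEnd / schedule@kTStart)^(seq_len(nS) / max(1, nS))
    log <- vector("list", nS)
    for (step in seq_len(nS)) {
      di <- sample.int(nrow(design), 1)
      ch <- design$chainId[di]; rs <- design$resSeq[di]
      curAA <- cur@atoms$resName[.residueRows(cur@atoms, ch, rs)[1]]
      aa <- if (design$mode[di] == "ALLAA")
        allowedAA[sample.int(length(allowedAA), 1)] else curAA
      rots <- library@rotamers[[aa]]
      if (is.null(rots) || !nrow(rots$chi))
        stop("rotamer library has no entries for ", aa)
      ri <- sample.int(nrow(rots$chi), 1)
      chi <- if (ncol(rots$chi)) rots$chi[ri, ] else numeric(0)
      cand <- mutateResidue(cur, ch, rs, aa, chi, warnProline = FALSE)
      candE <- scoreEnergy(cand, params, criteria)@total
      dE <- candE - curE
      acc <- metropolisStep(dE, kTs[step])
      if (acc) {
        cur <- cand; curE <- candE
        if (curE < bestE) { bestE <- curE; bestModel <- cur }
      }
      log[[step]] <- data.frame(step = step, kT = kTs[step],
                                chainId = ch, resSeq = rs, proposal = aa,
                                rotamer = ri, deltaE = dE, accepted = acc,
                                energy = curE, best = bestE,
                                stringsAsFactors = FALSE)
    }
    finalRes <- .resolveSpec(bestModel, spec)
    finalRes <- finalRes[finalRes$mode != "NATRO", , drop = FALSE]
    finalRes$chi <- vapply(seq_len(nrow(finalRes)), function(i) {
      paste(round(residueChi(bestModel, finalRes$chainId[i],
                             finalRes$resSeq[i]), 1), collapse = ",")
    }, character(1))
    list(model = bestModel, energy = bestE, trajectory = do.call(rbind, log),
         assignments = finalRes)
  })
}

#' Chi-torsion descriptors for minimization
#'
#' Builds the movable-torsion list (axis atoms plus the downstream moving
#' set) for the side-chain chi angles of the given residues.
#'
#' @param model a [PdbStructure-class].
#' @param residues data.frame with chainId and resSeq columns; default all
#'   protein residues.
#' @return list of torsions, each a list(axisFrom, axisTo, moving) of atom
#'   row indices.
#' @export
chiTorsions <- function(model, residues = NULL) {
  a <- model@atoms
  if (is.null(residues)) {
    prot <- a[a$recordKind == "ATOM", , drop = FALSE]
    key <- !duplicated(paste(prot$chainId, prot$resSeq))
    residues <- data.frame(chainId = prot$chainId[key],
                           resSeq = prot$resSeq[key], stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(residues))) {
    rows <- .residueRows(a, residues$chainId[i], residues$resSeq[i])
    if (!length(rows)) next
    aa <- a$resName[rows[1]]
    tmpl <- .SIDECHAIN_TEMPLATES[[aa]]
    if (is.null(tmpl) || !nrow(tmpl)) next
    for (ci in seq_len(.nChi(aa))) {
      row <- tmpl[tmpl$chi == ci & tmpl$dih == 0, ][1, ]
      axisTo <- rows[a$name[rows] == row$p1]
      axisFrom <- rows[a$name[rows] == row$p2]
      if (!length(axisTo) || !length(axisFrom)) next
      # moving: template atoms at or beyond this chi
      beyond <- tmpl$name[tmpl$chi >= ci]
      moving <- rows[a$name[rows] %in% beyond]
      if (!length(moving)) next
      out[[length(out) + 1]] <- list(axisFrom = axisFrom[1], axisTo = axisTo[1],
                                     moving = moving)
    }
  }
  out
}

#' Torsion-space energy minimization
#'
#' Cyclic descent over the movable torsions: per torsion, a numeric
#' gradient picks the downhill direction and a shrinking line search
#' accepts only energy-lowering rotations, so the energy is non-increasing
#' per accepted step. Stops when a full sweep improves the energy by less
#' than `tol` or after `maxSweeps` sweeps.
#'
#' @param model a [PdbStructure-class].
#' @param movable torsion list as produced by [chiTorsions()].
#' @param energyFn function(model) -> numeric; default the reduced-model
#'   total of [scoreEnergy()].
#' @param tol convergence tolerance on the per-sweep energy decrease.
#' @param maxSweeps sweep cap.
#' @param step0 initial line-search step, radians.
#' @return list with `model`, `energy`, `initialEnergy`, `sweeps`.
#' @export
minimizeTorsions <- function(model, movable, energyFn = NULL, tol = 1e-4,
                             maxSweeps = 30L, step0 = 0.15) {
  stopifnot(is(model, "PdbStructure"))
  if (is.null(energyFn)) {
    params <- defaultForceField()
    energyFn <- function(m) scoreEnergy(m, params)@total
  }
  xyzOf <- function(m) .xyzMatrix(m@atoms)
  setOf <- function(m, xyz) { m@atoms <- .setXyz(m@atoms, xyz); m }
  e0 <- energyFn(model)
  if (!is.finite(e0)) stop("non-finite energy at minimization start")
  cur <- model; curE <- e0
  h <- 1e-3
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    before <- curE
    for (t in movable) {
      xyz <- xyzOf(cur)
      u <- .unit(xyz[t$axisTo, ] - xyz[t$axisFrom, ])
      evalAt <- function(theta) {
        x2 <- xyz
        x2[t$moving, ] <- .rotateAbout(xyz[t$moving, , drop = FALSE],
                                       xyz[t$axisTo, ], u, theta)
        energyFn(setOf(cur, x2))
      }
      g <- (evalAt(h) - evalAt(-h)) / (2 * h)
      if (!is.finite(g) || abs(g) < 1e-12) next
      dir <- -sign(g)
      step <- step0
      while (step > 1e-5) {
        eNew <- evalAt(dir * step)
        if (eNew < curE - 1e-12) {
          xyz[t$moving, ] <- .rotateAbout(xyz[t$moving, , drop = FALSE],
                                          xyz[t$axisTo, ], u, dir * step)
          cur <- setOf(cur, xyz)
          curE <- eNew
          break
        }
        step <- step / 2
      }
    }
    if (before - curE < tol || sweeps >= maxSweeps) break
  }
  list(model = cur, energy = curE, initialEnergy = e0, sweeps = sweeps)
}

#' Repack-and-minimize relax protocol
#'
#' Runs `nCycles` cycles of: ramp the Lennard-Jones repulsion from soft
#' to full over the inner stages, repacking side chains (NATAA
#' everywhere in `residues`) and minimizing chi torsions at each stage.
#' The best full-repulsion energy seen is kept, so the reported energy
#' never increases across cycles. `nCycles = 0` returns the input.
#'
#' @param complex a [PdbStructure-class].
#' @param nCycles number of relax cycles.
#' @param residues data.frame (chainId, resSeq) of repackable residues;
#'   default all protein residues.
#' @param ramp repulsive scaling stages per cycle.
#' @param stepsPerStage Metropolis steps per packing stage.
#' @param library,params,criteria as in [packResidues()].
#' @param seed integer seed.
#' @return list with `model`, `energy` (full-repulsion total), `history`
#'   (per-stage energies).
#' @export
relaxComplex <- function(complex, nCycles = 2L, residues = NULL,
                         ramp = c(0.1, 0.4, 1.0), stepsPerStage = 60L,
                         library = defaultRotamerLibrary(),
                         params = defaultForceField(),
                         criteria = new("ContactCriteria"), seed = 1L) {
  stopifnot(is(complex, "PdbStructure"))
  if (is.null(residues)) {
    a <- complex@atoms
    prot <- a[a$recordKind == "ATOM", , drop = FALSE]
    key <- !duplicated(paste(prot$chainId, prot$resSeq))
    residues <- data.frame(chainId = prot$chainId[key],
                           resSeq = prot$resSeq[key], stringsAsFactors = FALSE)
  }
  fullE <- function(m) scoreEnergy(m, params, criteria)@total
  cur <- complex
  bestModel <- cur; bestE <- fullE(cur)
  history <- data.frame()
  if (nCycles >= 1L) {
    spec <- designSpec(residues$chainId, residues$resSeq,
                       rep("NATAA", nrow(residues)))
    for (cyc in seq_len(nCycles)) {
      for (si in seq_along(ramp)) {
        p <- params
        p@ljRepulsiveScale <- ramp[si]
        sched <- new("AnnealingSchedule", kTStart = 10, kTEnd = 0.3,
                     nSteps = as.integer(stepsPerStage),
                     seed = as.integer(seed + 1000L * cyc + si))
        packed <- packResidues(cur, spec, sched, library, p, criteria)
        minimized <- minimizeTorsions(packed$model, chiTorsions(packed$model,
                                                                residues),
                                      energyFn = function(m)
                                        scoreEnergy(m, p, criteria)@total)
        cur <- minimized$model
        eFull <- fullE(cur)
        history <- rbind(history,
                         data.frame(cycle = cyc, stage = si, repScale = ramp[si],
                                    energy = eFull))
        if (eFull < bestE) { bestE <- eFull; bestModel <- cur }
      }
    }
  }
  list(model = bestModel, energy = bestE, history = history)
}

#' Repeated fixed-temperature optimization
#'
#' Runs `n` independent Metropolis sweeps at constant temperature `kT`
#' (different sub-seeds) and keeps the best result, the iterate-and-keep
#' -best preset with defaults kT = 1, n = 20.
#'
#' @param complex a [PdbStructure-class].
#' @param spec a [DesignSpec-class] (typically NATAA over the pocket).
#' @param kT constant temperature, reduced units.
#' @param n number of independent sweeps.
#' @param stepsPerSweep Metropolis steps per sweep.
#' @param library,params,criteria as in [packResidues()].
#' @param seed integer seed.
#' @return list with `model`, `energy`, `sweepEnergies` (length n).
#' @export
repeatOptimize <- function(complex, spec, kT = 1, n = 20L,
                           stepsPerSweep = 30L,
                           library = defaultRotamerLibrary(),
                           params = defaultForceField(),
                           criteria = new("ContactCriteria"), seed = 1L) {
  stopifnot(is(complex, "PdbStructure"), n >= 1L)
  bestModel <- complex
  bestE <- scoreEnergy(complex, params, criteria)@total
  inputE <- bestE
  sweepE <- numeric(n)
  for (i in seq_len(n)) {
    sched <- new("AnnealingSchedule", kTStart = kT, kTEnd = kT,
                 nSteps = as.integer(stepsPerSweep),
                 seed = as.integer(seed + i))
    out <- packResidues(complex, spec, sched, library, params, criteria)
    sweepE[i] <- out$energy
    if (out$energy < bestE) { bestE <- out$energy; bestModel <- out$model }
  }
  list(model = bestModel, energy = min(bestE, inputE), sweepEnergies = sweepE)
}
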