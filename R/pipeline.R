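# End-to-end pipeline driver: prepare -> build ligand -> dock -> contacts
# -> score -> design -> score -> contacts -> relax -> contacts -> ddG,
# writing every intermediate structure under its lineage nickname
# (protein, allitol, sorbitol, proall, prosor, minprosor, finprosor,
# fastprosor) plus a machine-readable JSON manifest.

#' Rebuild incomplete side chains from templates
#'
#' Residues missing template side-chain atoms (common in crystal
#' structures) are rebuilt on their backbone at the measured chi angles
#' (missing chis default to -60 degrees). Each repair is logged via
#' message().
#'
#' @param model a [PdbStructure-class].
#' @return a [PdbStructure-class] with complete side chains.
#' @export
repairSideChains <- function(model) {
  stopifnot(is(model, "PdbStructure"))
  a <- model@atoms
  prot <- a[a$recordKind == "ATOM", , drop = FALSE]
  key <- !duplicated(paste(prot$chainId, prot$resSeq))
  res <- data.frame(chainId = prot$chainId[key], resSeq = prot$resSeq[key],
                    resName = prot$resName[key], stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    aa <- res$resName[i]
    tmpl <- .SIDECHAIN_TEMPLATES[[aa]]
    if (is.null(tmpl)) next
    rows <- .residueRows(model@atoms, res$chainId[i], res$resSeq[i])
    have <- model@atoms$name[rows]
    expect <- c(if (aa != "GLY") "CB", tmpl$name)
    if (!all(c("N", "CA", "C") %in% have) || all(expect %in% have)) next
    chi <- residueChi(model, res$chainId[i], res$resSeq[i])
    chi[is.na(chi)] <- -60
    message("rebuilding incomplete side chain: ", aa, " ",
            res$chainId[i], "/", res$resSeq[i])
    model <- mutateResidue(model, res$chainId[i], res$resSeq[i], aa,
                           chi = chi, warnProline = FALSE)
  }
  model
}

.ligandAsStructure <- function(lig, heavyOnly = TRUE) {
  a <- lig@atoms
  if (heavyOnly) a <- a[toupper(a$element) != "H", , drop = FALSE]
  a$recordKind <- "HETATM"
  a$serial <- seq_len(nrow(a))
  .newStructure(a)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Either
#' `proteinPdb` (a PDB file whose pocket holds the reference ligand) or
#' `preset = "pocket"` (a generated fixture) must be given.
#'
#' @param proteinPdb optional input PDB path.
#' @param preset "pocket" to generate a synthetic complex instead of
#'   reading a file.
#' @param chain monomer to keep (default the first chain).
#' @param ligandCode het code of the bound reference ligand ("X9X").
#' @param newLigandCode het code given to the replacement ligand ("SOR").
#' @param excludeCarbon hydroxyl excluded from torsion matching (3, the
#'   epimeric center).
#' @param cutoff pocket selection radius, Angstrom.
#' @param designModes optional data.frame (chainId, resSeq, mode)
#'   overriding the default design set (ALLAA at the zero-contact pocket
#'   residues, the "potential for polar bonds" set).
#' @param allowedAA identities offered at ALLAA positions; default all
#'   supported amino acids, or the fixture's designable-site alphabet
#'   when the synthetic preset plants one.
#' @param packSteps Metropolis steps per designable residue.
#' @param relaxCycles relax protocol cycles.
#' @param relaxSteps Metropolis steps per relax packing stage.
#' @param minimizeSweeps torsion-minimization sweep cap.
#' @param seed integer seed recorded in the manifest and used by every
#'   stochastic stage.
#' @param outDir output directory (created if absent).
#' @param dimerize for the synthetic preset: build the input as a
#'   homodimer so the prepare stage has a monomer to extract.
#' @param fixtureSpec optional [FixtureSpec-class] for the preset.
#' @return a named list (class "PipelineConfig").
#' @export
pipelineConfig <- function(proteinPdb = NULL, preset = NULL, chain = NULL,
                           ligandCode = "X9X", newLigandCode = "SOR",
                           excludeCarbon = 3L, cutoff = 4.0,
                           designModes = NULL, allowedAA = NULL,
                           packSteps = 40L,
                           relaxCycles = 1L, relaxSteps = 40L,
                           minimizeSweeps = 10L, seed = 1L,
                           outDir = tempfile("run"),
                           dimerize = TRUE, fixtureSpec = NULL) {
  if (is.null(proteinPdb) && is.null(preset))
    stop("either proteinPdb or preset must be given")
  if (!is.null(proteinPdb) && !file.exists(proteinPdb))
    stop("input PDB not found: ", proteinPdb)
  structure(list(proteinPdb = proteinPdb, preset = preset, chain = chain,
                 ligandCode = ligandCode, newLigandCode = newLigandCode,
                 excludeCarbon = as.integer(excludeCarbon), cutoff = cutoff,
                 designModes = designModes, allowedAA = allowedAA,
                 packSteps = as.integer(packSteps),
                 relaxCycles = as.integer(relaxCycles),
                 relaxSteps = as.integer(relaxSteps),
                 minimizeSweeps = as.integer(minimizeSweeps),
                 seed = as.integer(seed),
                 outDir = outDir, dimerize = dimerize,
                 fixtureSpec = fixtureSpec),
            class = "PipelineConfig")
}

.stageMsg <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full redesign pipeline
#'
#' Executes the lineage: prepare (monomer + reference-ligand extraction)
#' -> build replacement ligand -> backbone-guided dock and ligand swap ->
#' pocket contacts (before) -> score wild type (G_C, G_P) -> torsion
#' minimization -> pocket design (pack) -> score mutant (G_C*, G_P*) ->
#' contacts (after) -> relax -> contacts (after relax) -> ddG verdict.
#' The ddG pairing uses the wild-type energies scored before any
#' minimization: stabilizing the unbound state first would bias the
#' cycle, so post-minimization wild-type energies are never used there.
#'
#' @param config a [pipelineConfig()] list.
#' @return the run manifest (list), invisibly also written as
#'   manifest.json in the output directory.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  manifest <- list(package = "PocketSwap",
                   version = as.character(utils::packageVersion("PocketSwap")),
                   seed = config$seed, cutoff = config$cutoff,
                   wildTypeScoreState = "pre-minimization",
                   stages = list(), files = list(), scores = list())
  params <- defaultForceField()
  criteria <- new("ContactCriteria", neighborCutoff = config$cutoff)
  stage <- "prepare"
  res <- tryCatch({
    # ---- prepare ----------------------------------------------------
    if (!is.null(config$preset)) {
      fspec <- config$fixtureSpec
      if (is.null(fspec))
        fspec <- new("FixtureSpec", seed = config$seed,
                     nPocketResidues = 5L,
                     plantedContacts = data.frame(
                       resName = c("HIS", "ARG", "GLN"),
                       distance = c(2.9, 3.0, 3.1),
                       stringsAsFactors = FALSE),
                     designableSite = TRUE, ligandName = config$ligandCode)
      pocket <- makePocket(fspec)
      if (is.null(config$allowedAA) && !is.null(pocket$truth$designable))
        config$allowedAA <- pocket$truth$designable$alphabet
      input <- if (config$dimerize) makeDimer(pocket$model) else pocket$model
    } else {
      input <- readPdb(config$proteinPdb)
    }
    writePdb(input, out("protein.pdb"))
    chain <- if (is.null(config$chain)) chainIds(input)[1] else config$chain
    proall <- extractMonomer(input, chain)
    proall <- repairSideChains(proall)
    writePdb(proall, out("proall.pdb"))
    refLigand <- extractLigand(proall, config$ligandCode)
    writePdb(.ligandAsStructure(refLigand), out("allitol.pdb"))
    .stageMsg(stage, "monomer chain ", chain, ": ", nAtoms(proall),
              " atoms; reference ligand ", config$ligandCode)
    manifest$stages$prepare <- list(chain = chain, atoms = nAtoms(proall))

    # ---- build-ligand ----------------------------------------------
    stage <- "build-ligand"
    newLig <- buildAlditol(sorbitolConfig(), resName = config$newLigandCode)
    writePdb(.ligandAsStructure(newLig, heavyOnly = FALSE),
             out("sorbitol.pdb"))
    manifest$stages$buildLigand <-
      list(formula = as.list(molecularFormula(newLig)),
           stereo = as.list(descriptors(stereoDescriptors(newLig))))

    # ---- dock -------------------------------------------------------
    stage <- "dock"
    placed <- dockByBackbone(dropHydrogens(newLig), refLigand,
                             excludedCarbon = config$excludeCarbon)
    prosor <- swapLigand(proall, config$ligandCode, placed,
                         newCode = config$newLigandCode)
    writePdb(prosor, out("prosor.pdb"))
    .stageMsg(stage, sprintf("backbone rmsd %.3f A in %d iteration(s)",
                             attr(placed, "rmsd"), attr(placed, "iterations")))
    manifest$stages$dock <- list(rmsd = attr(placed, "rmsd"),
                                 iterations = attr(placed, "iterations"),
                                 reversed = attr(placed, "reversed"))

    # ---- contacts (before) -----------------------------------------
    stage <- "contacts"
    sorLig <- extractLigand(prosor, config$newLigandCode)
    pocketRes <- residuesWithin(prosor, sorLig, config$cutoff)
    contactsBefore <- polarContacts(prosor, sorLig, criteria)
    utils::write.table(contactsBefore, out("contacts_before.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    .stageMsg(stage, nrow(pocketRes), " pocket residue(s), ",
              nrow(contactsBefore), " polar contact(s) before design")

    # ---- score wild type (pre-minimization: enters the ddG cycle) ---
    stage <- "score"
    gWT <- scoreParts(prosor, config$newLigandCode, params, criteria)
    manifest$scores$GC <- unname(gWT["GC"])
    manifest$scores$GP <- unname(gWT["GP"])
    manifest$scores$GL <- unname(gWT["GL"])

    # ---- minimize (lineage only; never feeds the ddG wild type) -----
    stage <- "minimize"
    minned <- minimizeTorsions(prosor, chiTorsions(prosor, pocketRes),
                               energyFn = function(m)
                                 scoreEnergy(m, params, criteria)@total,
                               maxSweeps = config$minimizeSweeps)
    writePdb(minned$model, out("minprosor.pdb"))
    manifest$scores$minimizedComplex <- minned$energy

    # ---- design -----------------------------------------------------
    stage <- "design"
    if (is.null(config$designModes)) {
      rep0 <- contactReport(contactsBefore, pocketResidues = pocketRes)
      pot <- rep0$potential
      dspec <- designSpec(pot$chainId, pot$resSeq,
                          rep("ALLAA", nrow(pot)))
    } else {
      dspec <- designSpec(config$designModes$chainId,
                          config$designModes$resSeq,
                          config$designModes$mode)
    }
    writeResfile(dspec, out("pocket.resfile"))
    nDesign <- sum(dspec@residues$mode != "NATRO")
    sched <- new("AnnealingSchedule",
                 nSteps = max(1L, config$packSteps * max(1L, nDesign)),
                 seed = config$seed)
    packed <- packResidues(prosor, dspec, sched, params = params,
                           criteria = criteria,
                           allowedAA = if (is.null(config$allowedAA))
                             designableAminoAcids() else config$allowedAA)
    finprosor <- packed$model
    writePdb(finprosor, out("finprosor.pdb"))
    .stageMsg(stage, nDesign, " designable residue(s); best energy ",
              sprintf("%.3f", packed$energy))
    manifest$stages$design <-
      list(nDesignable = nDesign,
           assignments = if (nrow(packed$assignments))
             packed$assignments[, c("chainId", "resSeq", "resName", "chi")])

    # ---- score mutant ----------------------------------------------
    gMut <- scoreParts(finprosor, config$newLigandCode, params, criteria)
    manifest$scores$GCstar <- unname(gMut["GC"])
    manifest$scores$GPstar <- unname(gMut["GP"])

    # ---- contacts (after design) -----------------------------------
    contactsAfter <- polarContacts(finprosor,
                                   extractLigand(finprosor,
                                                 config$newLigandCode),
                                   criteria)
    utils::write.table(contactsAfter, out("contacts_after.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    # ---- relax ------------------------------------------------------
    stage <- "relax"
    relaxed <- relaxComplex(prosor, nCycles = config$relaxCycles,
                            residues = pocketRes,
                            stepsPerStage = config$relaxSteps,
                            params = params,
                            criteria = criteria, seed = config$seed)
    writePdb(relaxed$model, out("fastprosor.pdb"))
    contactsRelax <- polarContacts(relaxed$model,
                                   extractLigand(relaxed$model,
                                                 config$newLigandCode),
                                   criteria)
    utils::write.table(contactsRelax, out("contacts_after_relax.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$scores$relaxedComplex <- relaxed$energy

    # ---- report -----------------------------------------------------
    stage <- "report"
    rep <- contactReport(contactsBefore, contactsAfter, contactsRelax,
                         pocketResidues = pocketRes)
    utils::write.table(rep$table, out("contact_report.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    ddg <- ddgBind(GC = manifest$scores$GC, GP = manifest$scores$GP,
                   GCstar = manifest$scores$GCstar,
                   GPstar = manifest$scores$GPstar)
    manifest$ddg <- ddg
    manifest$verdict <- isFavorable(ddg)
    manifest$contactCounts <- list(
      before = nrow(contactsBefore), after = nrow(contactsAfter),
      afterRelax = nrow(contactsRelax))
    .stageMsg(stage, sprintf("ddG_bind = %.4f (%s)", ddg, manifest$verdict))
    manifest$files <- as.list(stats::setNames(
      file.path(config$outDir, c("protein.pdb", "allitol.pdb", "sorbitol.pdb",
                                 "proall.pdb", "prosor.pdb", "minprosor.pdb",
                                 "finprosor.pdb", "fastprosor.pdb")),
      c("protein", "allitol", "sorbitol", "proall", "prosor", "minprosor",
        "finprosor", "fastprosor")))
    manifest
  }, error = function(e) {
    manifest$failedStage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
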