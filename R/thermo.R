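# Binding thermodynamic cycle: dG_bind = G_C - (G_P + G_L) for a state,
# and the mutation effect ddG_bind = G_C* - G_P* - G_C + G_P, in which
# the free-ligand energy cancels. Negative ddG_bind means the mutant
# binds more favorably.

#' Binding free energy of one state
#'
#' dG_bind = G_C - (G_P + G_L): complex energy minus the separated
#' protein and ligand energies, reduced units.
#'
#' @param GC complex energy.
#' @param GP apo-protein energy.
#' @param GL free-ligand energy. If unknown (NA), an error directs the
#'   caller to [ddgBind()], where it cancels; it is never silently
#'   treated as zero.
#' @return numeric, reduced units.
#' @export
deltaGBind <- function(GC, GP, GL) {
  if (is.na(GL))
    stop("free-ligand energy GL is unknown; it cancels in ddgBind(), ",
         "use that for mutation comparisons")
  stopifnot(is.finite(GC), is.finite(GP), is.finite(GL))
  GC - (GP + GL)
}

#' Change in binding free energy upon mutation
#'
#' ddG_bind = G_C* - G_P* - G_C + G_P. Independent of the free-ligand
#' energy by construction. The wild-type energies must be the
#' pre-minimization ones: stabilizing the apo protein before mutation
#' would bias the cycle (see [cycleReport()] and the pipeline driver,
#' which enforce this pairing).
#'
#' @param cycle a [ThermodynamicCycle-class]; alternatively omit it and
#'   give the four state energies by name.
#' @param GC,GP,GCstar,GPstar the state energies when `cycle` is not
#'   given.
#' @return numeric ddG, reduced units.
#' @examples
#' ddgBind(GC = -140.67, GP = -171.51, GCstar = -224.80, GPstar = -228.27)
#' @export
ddgBind <- function(cycle = NULL, GC = NULL, GP = NULL, GCstar = NULL,
                    GPstar = NULL) {
  if (is(cycle, "ThermodynamicCycle")) {
    vals <- list(GC = cycle@GC, GP = cycle@GP, GCstar = cycle@GCstar,
                 GPstar = cycle@GPstar)
  } else {
    if (is.numeric(cycle) && is.null(GC)) GC <- cycle
    vals <- list(GC = GC, GP = GP, GCstar = GCstar, GPstar = GPstar)
  }
  for (nm in c("GC", "GP", "GCstar", "GPstar"))
    if (is.null(vals[[nm]]) || is.na(vals[[nm]]) || !is.finite(vals[[nm]]))
      stop("missing or non-finite state energy: ", nm)
  unname(vals$GCstar - vals$GPstar - vals$GC + vals$GP)
}

#' Favorability verdict on a ddG value
#'
#' Negative ddG_bind means the mutated complex binds more favorably.
#'
#' @param ddg numeric, reduced units.
#' @return "favorable", "neutral" or "unfavorable".
#' @export
isFavorable <- function(ddg) {
  stopifnot(is.finite(ddg))
  if (ddg < 0) "favorable" else if (ddg == 0) "neutral" else "unfavorable"
}

#' Tabulate labeled state energies with provenance
#'
#' Builds the energy-score report: one row per labeled state, with a
#' provenance column distinguishing energies computed by this package
#' from externally supplied values (e.g. literature scores fed into the
#' ddG arithmetic, whose absolute scale is opaque).
#'
#' @param computed named numeric vector of energies computed here.
#' @param supplied named numeric vector of externally supplied energies.
#' @return data.frame with state, energy, provenance.
#' @export
cycleReport <- function(computed = numeric(0), supplied = numeric(0)) {
  rows <- rbind(
    if (length(computed))
      data.frame(state = names(computed), energy = unname(computed),
                 provenance = "computed", stringsAsFactors = FALSE),
    if (length(supplied))
      data.frame(state = names(supplied), energy = unname(supplied),
                 provenance = "supplied", stringsAsFactors = FALSE))
  if (is.null(rows))
    rows <- data.frame(state = character(0), energy = numeric(0),
                       provenance = character(0), stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  rows
}

#' Build a thermodynamic cycle object
#'
#' @param GC,GP,GCstar,GPstar state energies, reduced units.
#' @param GL free-ligand energy; NA (default) marks it unknown.
#' @return a [ThermodynamicCycle-class].
#' @export
thermodynamicCycle <- function(GC, GP, GCstar, GPstar, GL = NA_real_) {
  new("ThermodynamicCycle", GC = GC, GP = GP, GL = GL,
      GCstar = GCstar, GPstar = GPstar)
}
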