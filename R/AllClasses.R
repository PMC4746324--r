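#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
NULL

## Default compartment vocabulary. The vocabulary is open (any string is
## accepted); this list names the ten compartments of a fully
## compartmentalized green-algal model and is used by the synthetic
## generators.
#' Default compartment identifiers
#'
#' Ten single-letter compartment tags covering a fully compartmentalized
#' eukaryotic microalgal cell, plus the extracellular space. The compartment
#' vocabulary of a [MetabolicNetwork] is open: any string is a valid
#' compartment id, and this vector is merely the documented default set.
#'
#' @return Named character vector mapping compartment id to a human-readable
#'   name.
#' @examples
#' defaultCompartments()
#' @export
defaultCompartments <- function() {
  c(c = "cytosol", h = "chloroplast", m = "mitochondrion", n = "nucleus",
    x = "glyoxysome", g = "golgi", r = "endoplasmic reticulum",
    v = "vacuole", f = "flagellum", e = "extracellular")
}

#' Compartmentalized metabolic network
#'
#' S4 container for a compartmentalized, constraint-based metabolic network:
#' the object every stage of the CO2-sensitivity workflow consumes. Rows of
#' the derived stoichiometric matrix are metabolites, columns are reactions.
#'
#' @slot compartments character vector of compartment ids (possibly named
#'   with display names).
#' @slot metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`; one row per metabolite. Metabolite ids carry their
#'   compartment tag in square brackets, e.g. `"co2[h]"`.
#' @slot reactions data.frame with columns `id`, `name`, `lb`, `ub`, `ec`,
#'   `pathway`, `genes` and a list column `stoich` of named numeric vectors
#'   (names are metabolite ids, negative coefficients consume). Flux bounds
#'   are in mmol/gDW/h (the biomass reaction's flux is 1/h, photon exchange
#'   in mE/gDW/h). Reversibility is encoded purely through `lb < 0`.
#' @slot objectiveId id of the objective (biomass) reaction.
#'
#' @seealso [MetabolicNetwork()] constructor, [readNetwork()],
#'   [stoichiometricMatrix()], [solveNetwork()].
#' @name MetabolicNetwork-class
#' @rdname MetabolicNetwork-class
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
  representation(
    compartments = "character",
    metabolites  = "data.frame",
    reactions    = "data.frame",
    objectiveId  = "character"
  )
)

.validMetabolicNetwork <- function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  needMet <- c("id", "name", "compartment", "formula")
  needRxn <- c("id", "name", "lb", "ub", "ec", "pathway", "genes", "stoich")
  if (!all(needMet %in% names(met)))
    return(paste("metabolites must have columns", paste(needMet, collapse = ", ")))
  if (!all(needRxn %in% names(rxn)))
    return(paste("reactions must have columns", paste(needRxn, collapse = ", ")))
  if (nrow(rxn) == 0L) msg <- c(msg, "network has no reactions")
  if (anyDuplicated(met$id))
    msg <- c(msg, paste("duplicated metabolite ids:",
                        paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  if (anyDuplicated(rxn$id))
    msg <- c(msg, paste("duplicated reaction ids:",
                        paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  badComp <- setdiff(unique(met$compartment), object@compartments)
  if (length(badComp))
    msg <- c(msg, paste("metabolite compartments not declared:",
                        paste(badComp, collapse = ", ")))
  if (nrow(rxn)) {
    if (any(lengths(rxn$stoich) == 0L))
      msg <- c(msg, paste("empty stoichiometry in reactions:",
                          paste(rxn$id[lengths(rxn$stoich) == 0L], collapse = ", ")))
    dangling <- setdiff(unique(unlist(lapply(rxn$stoich, names))), met$id)
    if (length(dangling))
      msg <- c(msg, paste("reactions reference undeclared metabolites:",
                          paste(dangling, collapse = ", ")))
    if (any(rxn$lb > rxn$ub))
      msg <- c(msg, paste("lb > ub for reactions:",
                          paste(rxn$id[rxn$lb > rxn$ub], collapse = ", ")))
    if (any(!is.finite(rxn$lb)) || any(!is.finite(rxn$ub)))
      msg <- c(msg, "flux bounds must be finite (use a large finite default)")
  }
  if (length(object@objectiveId) != 1L || !(object@objectiveId %in% rxn$id))
    msg <- c(msg, paste0("objective reaction '",
                         paste(object@objectiveId, collapse = ","),
                         "' is not in the network"))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
}

setValidity("MetabolicNetwork", .validMetabolicNetwork)

#' Linear program for flux balance analysis
#'
#' The LP `max c'v  s.t.  S v = 0, LB <= v <= UB` assembled from a
#' [MetabolicNetwork]: `S` is the sparse stoichiometric matrix, the
#' objective vector has a single 1 at the biomass column.
#'
#' @slot S sparse stoichiometric matrix (`dgCMatrix`) with metabolite row
#'   names and reaction column names.
#' @slot objective numeric objective vector c (one entry per reaction).
#' @slot lower,upper numeric bound vectors LB and UB.
#' @name LPProblem-class
#' @rdname LPProblem-class
#' @seealso [assembleLP()], [solveFBA()]
#' @exportClass LPProblem
setClass("LPProblem",
  representation(
    S         = "Matrix",
    objective = "numeric",
    lower     = "numeric",
    upper     = "numeric"
  )
)

setValidity("LPProblem", function(object) {
  n <- ncol(object@S)
  msg <- character()
  if (length(object@objective) != n || length(object@lower) != n ||
      length(object@upper) != n)
    msg <- c(msg, "objective and bound vectors must match ncol(S)")
  if (sum(object@objective != 0) != 1L)
    msg <- c(msg, "objective vector must have exactly one nonzero entry")
  if (any(object@lower > object@upper))
    msg <- c(msg, "LB must be <= UB elementwise")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Flux solution of one FBA problem
#'
#' @slot fluxes named numeric flux vector v (mmol/gDW/h; biomass 1/h).
#' @slot objective objective value (biomass flux at the optimum).
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @name FluxSolution-class
#' @rdname FluxSolution-class
#' @seealso [solveFBA()], [solveParsimonious()]
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(
    fluxes    = "numeric",
    objective = "numeric",
    status    = "character"
  )
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})
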