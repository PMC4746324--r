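#' Assemble the stoichiometric matrix
#'
#' Returns the sparse m x n matrix S whose entry (i, j) is the coefficient
#' of metabolite i in reaction j (negative = consumed). Rows are named by
#' metabolite id, columns by reaction id, in network order. Mass balance at
#' steady state is `S v = 0`.
#'
#' @param x a [MetabolicNetwork-class]
#' @return a `dgCMatrix` with dimnames.
#' @examples
#' stoichiometricMatrix(toyNetwork())
#' @rdname stoichiometricMatrix
#' @export
setMethod("stoichiometricMatrix", "MetabolicNetwork", function(x) {
  met <- x@metabolites$id
  rxn <- x@reactions$id
  st <- x@reactions$stoich
  i <- unlist(lapply(st, function(s) match(names(s), met)))
  j <- rep(seq_along(st), lengths(st))
  Matrix::sparseMatrix(i = i, j = j, x = unlist(st, use.names = FALSE),
                       dims = c(length(met), length(rxn)),
                       dimnames = list(met, rxn))
})

#' Find dead-end metabolites
#'
#' A dead-end metabolite can only be produced or only consumed, so it
#' cannot carry steady-state flux. A reversible reaction (`lb < 0`)
#' supplies both roles to every metabolite it touches; exchange/sink
#' reactions likewise connect their metabolite to the boundary in the
#' direction(s) their bounds allow.
#'
#' @param net a [MetabolicNetwork-class]
#' @return sorted character vector of dead-end metabolite ids.
#' @examples
#' findDeadEnds(toyNetwork())
#' @export
findDeadEnds <- function(net) {
  stopifnot(is(net, "MetabolicNetwork"))
  rxn <- net@reactions
  produced <- consumed <- character()
  for (i in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[i]]
    fwd <- rxn$ub[i] > 0   # reaction can run forward
    bwd <- rxn$lb[i] < 0   # reaction can run backward
    if (fwd) {
      produced <- c(produced, names(st)[st > 0])
      consumed <- c(consumed, names(st)[st < 0])
    }
    if (bwd) {
      produced <- c(produced, names(st)[st < 0])
      consumed <- c(consumed, names(st)[st > 0])
    }
  }
  ids <- net@metabolites$id
  sort(ids[!(ids %in% produced & ids %in% consumed)])
}

#' CO2 condition table
#'
#' A condition fixes the photon uptake (the light regime, mE/gDW/h) and
#' caps the CO2 exchange flux (mmol/gDW/h) that corresponds to a CO2
#' concentration in the gas phase (% v/v). `defaultConditions()` returns
#' the five levels used throughout: 0.04% (air, the low reference), 2.5, 5,
#' 8 and 10% (the high reference), with light fixed at 57.54 mE/gDW/h and
#' the CO2 exchange bound scaling linearly with the percentage
#' (`co2FluxPerPercent`, default 1 mmol/gDW/h per %).
#'
#' @param co2Percent CO2 concentrations (% v/v).
#' @param lightFlux fixed photon uptake, mE/gDW/h.
#' @param co2FluxPerPercent linear map from % CO2 to the exchange upper
#'   bound.
#' @return data.frame with columns `name`, `co2_percent`, `co2_flux_ub`,
#'   `light_flux`.
#' @examples
#' defaultConditions()
#' @export
defaultConditions <- function(co2Percent = c(0.04, 2.5, 5, 8, 10),
                              lightFlux = 57.54,
                              co2FluxPerPercent = 1) {
  stopifnot(all(co2Percent >= 0), lightFlux >= 0, co2FluxPerPercent > 0)
  data.frame(
    name = ifelse(co2Percent == 0.04, "air",
                  paste0("co2_", vapply(co2Percent, function(p)
                    sprintf("%g", p), character(1)))),
    co2_percent = co2Percent,
    co2_flux_ub = co2Percent * co2FluxPerPercent,
    light_flux = lightFlux,
    stringsAsFactors = FALSE)
}

.checkConditions <- function(conditions) {
  need <- c("name", "co2_percent", "co2_flux_ub", "light_flux")
  if (!all(need %in% names(conditions)))
    stop("condition table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(conditions$name))
    stop("duplicate condition names: ",
         paste(unique(conditions$name[duplicated(conditions$name)]),
               collapse = ", "))
  if (any(conditions$co2_percent < 0) || any(conditions$co2_flux_ub < 0) ||
      any(conditions$light_flux < 0))
    stop("condition values must be non-negative")
  invisible(conditions)
}

#' Read a condition table
#'
#' Tab-separated file with columns `name`, `co2_percent`, `co2_flux_ub`,
#' `light_flux` (UTF-8, `#` comments).
#'
#' @param path file path.
#' @return validated condition data.frame.
#' @export
readConditions <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  .checkConditions(x)
  x
}

#' Apply a CO2/light condition to a network
#'
#' Sets the upper bound of the designated CO2 exchange reaction to the
#' condition's CO2 flux cap and pins the photon exchange to the condition's
#' light flux (`lb = ub = light_flux`), representing autotrophic growth at
#' a fixed light regime. No other bounds are touched, so applying the same
#' condition twice is idempotent.
#'
#' @param net a [MetabolicNetwork-class] containing the two designated
#'   exchange reactions.
#' @param condition one row of a condition table (see
#'   [defaultConditions()]), or a list with elements `co2_flux_ub` and
#'   `light_flux`.
#' @param co2Id,photonId ids of the CO2 and photon exchange reactions.
#' @return the network with condition bounds applied.
#' @examples
#' net <- generateNetwork(networkBlueprint(seed = 1))$network
#' cond <- defaultConditions()[1, ]
#' net <- setConditionBounds(net, cond)
#' getBounds(net, "EX_co2")
#' @export
setConditionBounds <- function(net, condition, co2Id = "EX_co2",
                               photonId = "EX_photon") {
  stopifnot(is(net, "MetabolicNetwork"))
  for (id in c(co2Id, photonId))
    if (!id %in% net@reactions$id)
      stop("configuration error: designated exchange reaction '", id,
           "' is not in the network")
  co2 <- condition[["co2_flux_ub"]]
  light <- condition[["light_flux"]]
  if (is.null(co2) || is.null(light) || is.na(co2) || is.na(light))
    stop("condition must provide co2_flux_ub and light_flux")
  net <- setBounds(net, co2Id, ub = co2)
  net <- setBounds(net, photonId, lb = light, ub = light)
  net
}

#' A three-reaction toy network
#'
#' Minimal linear chain (uptake, conversion, biomass drain) used in
#' examples and unit tests.
#'
#' @param ub uptake bound of the exchange reaction.
#' @return a [MetabolicNetwork-class] with 2 metabolites and 3 reactions.
#' @examples
#' toyNetwork()
#' @export
toyNetwork <- function(ub = 10) {
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "c", formula = NA_character_,
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "R1", "BIO"),
                     name = c("A exchange", "A to B", "biomass"),
                     lb = 0, ub = c(ub, 1000, 1000),
                     stringsAsFactors = FALSE)
  rxns$stoich <- list(c("A[c]" = 1), c("A[c]" = -1, "B[c]" = 1),
                      c("B[c]" = -1))
  MetabolicNetwork(mets, rxns, objectiveId = "BIO")
}
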