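#' Scan CO2 conditions and classify CO2-sensitive reactions
#'
#' `scanConditions` solves the parsimonious flux balance problem once per
#' condition (CO2 exchange bound set per condition, photon exchange pinned
#' to the light flux) and collects the flux vectors. `classifySensitive`
#' adds the flux variation coefficient rho of every reaction across the
#' scan and flags the reactions with `rho >= rhoThreshold` (inclusive,
#' default 0.01) as CO2-sensitive.
#'
#' The result is a [SummarizedExperiment::SummarizedExperiment] with one
#' row per reaction and one column per condition: assay `"flux"` holds the
#' parsimonious flux vectors, `rowData` carries `pathway`, `compartment`
#' (a reaction's single compartment, or `"transport"` when it spans
#' several), `rho` and `sensitive`, `colData` is the condition table, and
#' `metadata(se)$objectives` records the optimal biomass flux per
#' condition.
#'
#' @param net a [MetabolicNetwork-class].
#' @param conditions condition table (see [defaultConditions()]); at least
#'   two rows with unique names.
#' @param co2Id,photonId designated exchange reaction ids.
#' @param rhoThreshold sensitivity threshold on rho.
#' @return a `SummarizedExperiment` as described.
#' @examples
#' gen <- generateNetwork(networkBlueprint(seed = 1))
#' se <- scanConditions(gen$network, defaultConditions())
#' head(SummarizedExperiment::rowData(se))
#' @export
scanConditions <- function(net, conditions, co2Id = "EX_co2",
                           photonId = "EX_photon", rhoThreshold = 0.01) {
  stopifnot(is(net, "MetabolicNetwork"))
  .checkConditions(conditions)
  if (nrow(conditions) < 2L)
    stop("at least two conditions are required")
  fluxMat <- matrix(NA_real_, nrow = nReactions(net), ncol = nrow(conditions),
                    dimnames = list(reactionIds(net), conditions$name))
  objectives <- structure(numeric(nrow(conditions)), names = conditions$name)
  for (i in seq_len(nrow(conditions))) {
    condNet <- setConditionBounds(net, conditions[i, ], co2Id, photonId)
    sol <- solveNetwork(condNet, parsimonious = TRUE)
    if (solutionStatus(sol) != "optimal")
      stop("condition '", conditions$name[i], "' is ", solutionStatus(sol))
    fluxMat[, i] <- fluxes(sol)[rownames(fluxMat)]
    objectives[i] <- objectiveValue(sol)
  }
  rd <- S4Vectors::DataFrame(
    pathway = ifelse(is.na(net@reactions$pathway), "unannotated",
                     net@reactions$pathway),
    compartment = .reactionCompartment(net),
    row.names = reactionIds(net))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(flux = fluxMat),
    rowData = rd,
    colData = S4Vectors::DataFrame(conditions, row.names = conditions$name))
  S4Vectors::metadata(se)$objectives <- objectives
  classifySensitive(se, rhoThreshold)
}

.reactionCompartment <- function(net) {
  compOf <- structure(net@metabolites$compartment,
                      names = net@metabolites$id)
  vapply(net@reactions$stoich, function(st) {
    cc <- unique(unname(compOf[names(st)]))
    if (length(cc) == 1L) cc else "transport"
  }, character(1))
}

#' Flux variation coefficient
#'
#' Dispersion of one reaction's optimal flux across environmental
#' conditions: the sample standard deviation divided by the absolute mean,
#' guarded by `eps` so that all-zero flux profiles give rho = 0 instead of
#' 0/0. rho is dimensionless, non-negative, and invariant under scaling
#' all fluxes by a nonzero constant.
#'
#' @param x numeric vector of fluxes across conditions (length >= 2).
#' @param eps denominator guard (default 1e-9).
#' @return rho.
#' @examples
#' fluxVariationCoefficient(c(1, 1, 1, 1, 3))  # 0.6389
#' fluxVariationCoefficient(rep(2, 5))         # 0
#' @export
fluxVariationCoefficient <- function(x, eps = 1e-9) {
  if (length(x) < 2L)
    stop("rho needs at least two condition fluxes")
  stats::sd(x) / max(abs(mean(x)), eps)
}

#' @rdname scanConditions
#' @param se a `SummarizedExperiment` from `scanConditions`.
#' @export
classifySensitive <- function(se, rhoThreshold = 0.01) {
  flux <- SummarizedExperiment::assay(se, "flux")
  rho <- apply(flux, 1, fluxVariationCoefficient)
  SummarizedExperiment::rowData(se)$rho <- rho
  SummarizedExperiment::rowData(se)$sensitive <- rho >= rhoThreshold
  S4Vectors::metadata(se)$rho_threshold <- rhoThreshold
  se
}

#' Reactions flagged as CO2-sensitive
#'
#' @param se scan result from [scanConditions()].
#' @return character vector of sensitive reaction ids.
#' @export
sensitiveReactions <- function(se) {
  rownames(se)[SummarizedExperiment::rowData(se)$sensitive]
}

#' Aggregate sensitive reactions by pathway and compartment
#'
#' Counts the CO2-sensitive reactions per pathway annotation and per
#' compartment (reactions spanning compartments count under
#' `"transport"`; missing pathway annotations under `"unannotated"`), with
#' percentage shares that sum to 100.
#'
#' @param se scan result from [scanConditions()].
#' @return list with data.frames `pathway` and `compartment`, each with
#'   columns `label`, `n`, `percent`, sorted by decreasing count.
#' @export
aggregateSensitivity <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  sens <- rd[rd$sensitive, , drop = FALSE]
  one <- function(label) {
    if (nrow(sens) == 0L)
      return(data.frame(label = character(), n = integer(),
                        percent = numeric()))
    tab <- sort(table(sens[[label]]), decreasing = TRUE)
    data.frame(label = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / sum(tab),
               row.names = NULL)
  }
  list(pathway = one("pathway"), compartment = one("compartment"))
}

#' Net flux of a metabolite through its sensitive reactions
#'
#' Sums production minus consumption of one metabolite over the
#' CO2-sensitive reactions at one condition: production reactions are
#' added and consumer reactions subtracted through the signed
#' stoichiometric coefficients, i.e. the dot product of the metabolite's
#' stoichiometric row (restricted to sensitive reactions) with the
#' condition's flux vector. Returns 0 when no sensitive reaction touches
#' the metabolite.
#'
#' @param se scan result from [scanConditions()].
#' @param net the scanned [MetabolicNetwork-class].
#' @param metaboliteId metabolite id.
#' @param condition condition name (a column of `se`).
#' @return net flux, mmol/gDW/h.
#' @export
netMetaboliteFlux <- function(se, net, metaboliteId, condition) {
  stopifnot(is(net, "MetabolicNetwork"))
  if (!metaboliteId %in% net@metabolites$id)
    stop("unknown metabolite: ", metaboliteId)
  if (!condition %in% colnames(se))
    stop("unknown condition: ", condition)
  S <- stoichiometricMatrix(net)
  sens <- sensitiveReactions(se)
  if (length(sens) == 0L) return(0)
  v <- SummarizedExperiment::assay(se, "flux")[sens, condition]
  sum(S[metaboliteId, sens] * v)
}

#' Low/high CO2 net-flux ratio records
#'
#' `fluxRatioLowHigh` forms the ratio of a metabolite's net flux at low
#' CO2 over its net flux at high CO2; the ratio is undefined (flagged, not
#' an error) when the high-CO2 net flux is within `eps` of zero.
#' `netFluxTable` builds the records for a set of metabolites from a scan,
#' using the low/high reference conditions (defaults `"air"` = 0.04% and
#' `"co2_10"` = 10%).
#'
#' @param low,high net fluxes at the low and high CO2 reference
#'   conditions.
#' @param eps threshold below which the denominator is treated as zero.
#' @return `fluxRatioLowHigh`: list with `net_flux_low`, `net_flux_high`,
#'   `ratio` (NA when undefined) and `defined`. `netFluxTable`: data.frame
#'   with those columns plus `metabolite_id`.
#' @examples
#' fluxRatioLowHigh(2, 4)   # ratio 0.5
#' fluxRatioLowHigh(2, 0)   # undefined
#' @export
fluxRatioLowHigh <- function(low, high, eps = 1e-9) {
  defined <- abs(high) > eps
  list(net_flux_low = low, net_flux_high = high,
       ratio = if (defined) low / high else NA_real_,
       defined = defined)
}

#' @rdname fluxRatioLowHigh
#' @param se scan result from [scanConditions()].
#' @param net the scanned [MetabolicNetwork-class].
#' @param metaboliteIds metabolites to evaluate.
#' @param lowCondition,highCondition condition names of the low/high CO2
#'   references.
#' @export
netFluxTable <- function(se, net, metaboliteIds,
                         lowCondition = "air", highCondition = "co2_10",
                         eps = 1e-9) {
  rows <- lapply(metaboliteIds, function(mid) {
    lo <- netMetaboliteFlux(se, net, mid, lowCondition)
    hi <- netMetaboliteFlux(se, net, mid, highCondition)
    r <- fluxRatioLowHigh(lo, hi, eps)
    data.frame(metabolite_id = mid, net_flux_low = r$net_flux_low,
               net_flux_high = r$net_flux_high, ratio = r$ratio,
               defined = r$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
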