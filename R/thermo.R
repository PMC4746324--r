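#' Group-contribution parameter tables
#'
#' Formation Gibbs energies are estimated by group contribution: a
#' compound's standard formation energy is the table's origin term plus the
#' sum, over its structural groups, of group count times group
#' contribution. The bundled conditions are 27 degrees C (300.15 K) and
#' pH 7; no concentration or ionic-strength corrections are applied.
#' Group decompositions are input data (no structure parsing is done).
#'
#' `readGroupTable` reads a TSV with columns `group_id`,
#' `contribution_kj_mol`; a row with `group_id == "origin"` supplies the
#' origin term. `readGroupDecomposition` reads a TSV with columns
#' `metabolite_id`, `group_id`, `count` and returns a named list of named
#' count vectors.
#'
#' @param contributions named numeric vector of group contributions
#'   (kJ/mol).
#' @param origin origin term (kJ/mol).
#' @param path file path.
#' @return `groupContributionTable` returns a list with elements
#'   `origin`, `contributions`, `temperature_k` (300.15) and `ph` (7).
#' @examples
#' tab <- groupContributionTable(c(g1 = -10, g2 = 4), origin = -20)
#' estimateFormationEnergy(c(g1 = 2), tab)
#' @export
groupContributionTable <- function(contributions, origin = 0) {
  stopifnot(is.numeric(contributions), !is.null(names(contributions)),
            all(is.finite(contributions)), is.finite(origin))
  list(origin = origin, contributions = contributions,
       temperature_k = 300.15, ph = 7)
}

#' @rdname groupContributionTable
#' @export
readGroupTable <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("group_id", "contribution_kj_mol") %in% names(x)))
  origin <- 0
  o <- x$group_id == "origin"
  if (any(o)) origin <- x$contribution_kj_mol[o][1]
  groupContributionTable(
    structure(x$contribution_kj_mol[!o], names = x$group_id[!o]),
    origin = origin)
}

#' @rdname groupContributionTable
#' @export
readGroupDecomposition <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "group_id", "count") %in% names(x)))
  stopifnot(all(x$count >= 0))
  split(structure(x$count, names = x$group_id), x$metabolite_id)
}

#' Estimate formation and reaction Gibbs energies
#'
#' `estimateFormationEnergy` computes the group-contribution formation
#' energy of one metabolite: origin + sum of count * contribution.
#' `estimateReactionEnergy` sums formation energies weighted by
#' stoichiometric coefficients to give the standard reaction Gibbs energy.
#'
#' @param groupCounts named non-negative integer vector (group id ->
#'   count).
#' @param table a [groupContributionTable()].
#' @return energy in kJ/mol.
#' @examples
#' tab <- groupContributionTable(c(g1 = -10), origin = 0)
#' estimateFormationEnergy(c(g1 = 2), tab)  # -20
#' @export
estimateFormationEnergy <- function(groupCounts, table) {
  if (length(groupCounts) == 0L) return(table$origin)
  stopifnot(!is.null(names(groupCounts)), all(groupCounts >= 0))
  missing <- setdiff(names(groupCounts), names(table$contributions))
  if (length(missing))
    stop("estimation error: group(s) absent from contribution table: ",
         paste(missing, collapse = ", "))
  table$origin + sum(groupCounts * table$contributions[names(groupCounts)])
}

#' @rdname estimateFormationEnergy
#' @param stoich named numeric stoichiometry (negative = consumed).
#' @param formationEnergies named numeric vector of formation energies
#'   (kJ/mol) covering every species in `stoich`.
#' @export
estimateReactionEnergy <- function(stoich, formationEnergies) {
  missing <- setdiff(names(stoich), names(formationEnergies))
  if (length(missing))
    stop("estimation error: no formation energy for species: ",
         paste(missing, collapse = ", "))
  sum(stoich * formationEnergies[names(stoich)])
}

#' Classify reaction directionality from its Gibbs energy
#'
#' A reaction is called reversible when its standard reaction Gibbs energy
#' is within `tau` of zero; strongly negative energies make it forward
#' irreversible and strongly positive energies reverse irreversible (the
#' written orientation is thermodynamically disfavoured and is flipped by
#' [applyThermodynamics()]). The default threshold of 30 kJ/mol is a
#' common constraint-based-modelling heuristic.
#'
#' @param dgr reaction Gibbs energy, kJ/mol.
#' @param tau positive reversibility threshold, kJ/mol.
#' @return one of `"reversible"`, `"forward_irreversible"`,
#'   `"reverse_irreversible"`.
#' @examples
#' classifyReversibility(0)       # reversible
#' classifyReversibility(-45)     # forward_irreversible
#' classifyReversibility(31, 30)  # reverse_irreversible
#' @export
classifyReversibility <- function(dgr, tau = 30) {
  stopifnot(tau > 0, is.finite(dgr))
  if (abs(dgr) <= tau) "reversible"
  else if (dgr < 0) "forward_irreversible"
  else "reverse_irreversible"
}

#' Assign directionality of reactions from group-contribution energies
#'
#' For each requested reaction whose species are all covered by the group
#' decomposition, estimates the reaction Gibbs energy and sets the flux
#' bounds accordingly: forward irreversible `[0, bound]`, reversible
#' `[-bound, bound]`, reverse irreversible reactions are flipped (stoich
#' negated) and then constrained `[0, bound]`. Reactions with undecomposed
#' species are left untouched and reported with verdict `"skipped"`.
#' An optional override table (`reaction_id`, `verdict`) forces verdicts
#' for specific reactions, standing in for directionality assignments
#' taken from the literature rather than from thermodynamics.
#'
#' @param net a [MetabolicNetwork-class].
#' @param decomposition named list of group-count vectors per metabolite id
#'   (see [readGroupDecomposition()]).
#' @param table a [groupContributionTable()].
#' @param reactionIds reactions to evaluate (default: all).
#' @param tau reversibility threshold, kJ/mol.
#' @param overrides optional data.frame with columns `reaction_id`,
#'   `verdict`.
#' @param bound bound magnitude used when rewriting bounds.
#' @return list with `network` (bounds updated) and `energies`
#'   (data.frame: `reaction_id`, `dgr`, `verdict`).
#' @examples
#' tab <- groupContributionTable(c(g1 = -20, g2 = 5))
#' dec <- list("A[c]" = c(g1 = 1), "B[c]" = c(g2 = 2))
#' res <- applyThermodynamics(toyNetwork(), dec, tab)
#' res$energies
#' @export
applyThermodynamics <- function(net, decomposition, table,
                                reactionIds = NULL, tau = 30,
                                overrides = NULL, bound = 1000) {
  stopifnot(is(net, "MetabolicNetwork"))
  rxn <- net@reactions
  if (is.null(reactionIds)) reactionIds <- rxn$id
  known <- names(decomposition)
  dgf <- structure(
    vapply(known, function(mid)
      estimateFormationEnergy(decomposition[[mid]], table), numeric(1)),
    names = known)
  out <- data.frame(reaction_id = reactionIds, dgr = NA_real_,
                    verdict = "skipped", stringsAsFactors = FALSE)
  for (k in seq_along(reactionIds)) {
    i <- match(reactionIds[k], rxn$id)
    if (is.na(i)) stop("unknown reaction id: ", reactionIds[k])
    st <- rxn$stoich[[i]]
    if (!all(names(st) %in% known)) next
    dgr <- estimateReactionEnergy(st, dgf)
    verdict <- classifyReversibility(dgr, tau)
    if (!is.null(overrides)) {
      j <- match(reactionIds[k], overrides$reaction_id)
      if (!is.na(j)) verdict <- overrides$verdict[j]
    }
    out$dgr[k] <- dgr
    out$verdict[k] <- verdict
    if (verdict == "forward_irreversible") {
      rxn$lb[i] <- 0; rxn$ub[i] <- bound
    } else if (verdict == "reversible") {
      rxn$lb[i] <- -bound; rxn$ub[i] <- bound
    } else if (verdict == "reverse_irreversible") {
      rxn$stoich[[i]] <- -st
      rxn$lb[i] <- 0; rxn$ub[i] <- bound
    } else stop("unknown verdict: ", verdict)
  }
  net@reactions <- rxn
  validObject(net)
  list(network = net, energies = out)
}
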