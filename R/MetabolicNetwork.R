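#' Construct a compartmentalized metabolic network
#'
#' Builds and validates a [MetabolicNetwork-class] from a metabolite table
#' and a reaction table. Most users will instead obtain networks from
#' [readNetwork()] or [generateNetwork()].
#'
#' @param metabolites data.frame with columns `id`, `compartment` and
#'   optionally `name`, `formula`. Metabolite ids conventionally embed the
#'   compartment tag (`"glc[c]"`).
#' @param reactions data.frame with columns `id`, `stoich` (list column of
#'   named numeric vectors; negative = consumed) and optionally `name`,
#'   `lb`, `ub`, `ec`, `pathway`, `genes`. Missing bounds default to
#'   `[0, defaultBound]`.
#' @param objectiveId id of the biomass (objective) reaction.
#' @param compartments compartment ids; defaults to those appearing in
#'   `metabolites`.
#' @param defaultBound finite magnitude used for unspecified bounds
#'   (default 1000 mmol/gDW/h).
#' @return A validated `MetabolicNetwork`.
#' @examples
#' mets <- data.frame(id = c("A[c]", "B[c]"), compartment = "c")
#' rxns <- data.frame(id = c("EX_A", "R1", "BIO"))
#' rxns$stoich <- list(c("A[c]" = 1), c("A[c]" = -1, "B[c]" = 1), c("B[c]" = -1))
#' rxns$ub <- c(10, 1000, 1000)
#' net <- MetabolicNetwork(mets, rxns, objectiveId = "BIO")
#' net
#' @export
MetabolicNetwork <- function(metabolites, reactions, objectiveId,
                             compartments = NULL, defaultBound = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (nrow(reactions) == 0L) stop("network has no reactions")
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  metabolites <- metabolites[c("id", "name", "compartment", "formula")]
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lb)) reactions$lb <- 0
  if (is.null(reactions$ub)) reactions$ub <- defaultBound
  if (is.null(reactions$ec)) reactions$ec <- NA_character_
  if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
  if (is.null(reactions$genes)) reactions$genes <- ""
  stoich <- reactions$stoich
  class(stoich) <- NULL          # strip AsIs from I() list columns
  stoich <- lapply(stoich, function(s) s[order(names(s))])  # canonical order
  reactions <- reactions[c("id", "name", "lb", "ub", "ec", "pathway", "genes")]
  reactions$stoich <- stoich
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  if (is.null(compartments))
    compartments <- unique(metabolites$compartment)
  new("MetabolicNetwork",
      compartments = compartments,
      metabolites = metabolites,
      reactions = reactions,
      objectiveId = objectiveId)
}

#' @rdname MetabolicNetwork-class
#' @export
setMethod("metabolites", "MetabolicNetwork", function(x) x@metabolites)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactions", "MetabolicNetwork", function(x) x@reactions)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("compartments", "MetabolicNetwork", function(x) x@compartments)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("objectiveId", "MetabolicNetwork", function(x) x@objectiveId)

#' @rdname MetabolicNetwork-class
#' @export
setReplaceMethod("objectiveId", "MetabolicNetwork", function(x, value) {
  x@objectiveId <- value
  validObject(x)
  x
})

#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactionIds", "MetabolicNetwork", function(x) x@reactions$id)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites$id)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("nMetabolites", "MetabolicNetwork", function(x) nrow(x@metabolites))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("nReactions", "MetabolicNetwork", function(x) nrow(x@reactions))

setMethod("show", "MetabolicNetwork", function(object) {
  rxn <- object@reactions
  cat("MetabolicNetwork with", nrow(object@metabolites), "metabolites,",
      nrow(rxn), "reactions,", length(object@compartments), "compartments\n")
  cat("  objective:", object@objectiveId, "\n")
  cat("  reversible:", sum(rxn$lb < 0),
      " exchange:", sum(lengths(rxn$stoich) == 1L), "\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
})

#' Reversibility and exchange status of reactions
#'
#' Reversibility is derived purely from the lower bound (`lb < 0`); an
#' exchange reaction is a boundary reaction touching exactly one metabolite.
#'
#' @param net a [MetabolicNetwork-class]
#' @return logical vector, one entry per reaction (in network order).
#' @examples
#' net <- toyNetwork()
#' table(isExchange(net))
#' @export
isReversible <- function(net) {
  stopifnot(is(net, "MetabolicNetwork"))
  structure(net@reactions$lb < 0, names = net@reactions$id)
}

#' @rdname isReversible
#' @export
isExchange <- function(net) {
  stopifnot(is(net, "MetabolicNetwork"))
  structure(lengths(net@reactions$stoich) == 1L, names = net@reactions$id)
}

#' Look up or replace flux bounds of one reaction
#'
#' @param net a [MetabolicNetwork-class]
#' @param id reaction id
#' @param lb,ub new bounds; `NULL` leaves the bound untouched.
#' @return `setBounds` returns the modified network; `getBounds` a numeric
#'   vector `c(lb, ub)`.
#' @examples
#' net <- toyNetwork()
#' net <- setBounds(net, "EX_A", ub = 5)
#' getBounds(net, "EX_A")
#' @export
setBounds <- function(net, id, lb = NULL, ub = NULL) {
  stopifnot(is(net, "MetabolicNetwork"))
  i <- match(id, net@reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  if (!is.null(lb)) net@reactions$lb[i] <- lb
  if (!is.null(ub)) net@reactions$ub[i] <- ub
  validObject(net)
  net
}

#' @rdname setBounds
#' @export
getBounds <- function(net, id) {
  stopifnot(is(net, "MetabolicNetwork"))
  i <- match(id, net@reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  c(lb = net@reactions$lb[i], ub = net@reactions$ub[i])
}

#' Add reactions (and any new metabolites) to a network
#'
#' Metabolites referenced by the new reactions but absent from the network
#' are registered automatically, with their compartment parsed from the
#' bracket tag of the metabolite id.
#'
#' @param net a [MetabolicNetwork-class]
#' @param reactions data.frame in the same shape accepted by
#'   [MetabolicNetwork()].
#' @return the extended network.
#' @export
addReactions <- function(net, reactions) {
  stopifnot(is(net, "MetabolicNetwork"))
  if (nrow(reactions) == 0L) return(net)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lb)) reactions$lb <- 0
  if (is.null(reactions$ub)) reactions$ub <- 1000
  if (is.null(reactions$ec)) reactions$ec <- NA_character_
  if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
  if (is.null(reactions$genes)) reactions$genes <- ""
  stoich <- reactions$stoich
  class(stoich) <- NULL
  stoich <- lapply(stoich, function(s) s[order(names(s))])
  reactions <- reactions[c("id", "name", "lb", "ub", "ec", "pathway", "genes")]
  reactions$stoich <- stoich
  newSpecies <- setdiff(unique(unlist(lapply(stoich, names))),
                        net@metabolites$id)
  if (length(newSpecies)) {
    comp <- vapply(newSpecies, .compartmentOfId, character(1))
    net@metabolites <- rbind(net@metabolites, data.frame(
      id = newSpecies, name = .nameOfId(newSpecies),
      compartment = comp, formula = NA_character_,
      stringsAsFactors = FALSE))
    net@compartments <- union(net@compartments, comp)
  }
  net@reactions <- rbind(net@reactions, reactions)
  rownames(net@reactions) <- NULL
  validObject(net)
  net
}

## "glc[c]" -> compartment "c"; untagged ids fall back to "c"
.compartmentOfId <- function(id) {
  m <- regmatches(id, regexec("\\[([^]]+)\\]$", id))[[1]]
  if (length(m) == 2L) m[2] else "c"
}

## "glc[c]" -> species name "glc"
.nameOfId <- function(id) sub("\\[[^]]+\\]$", "", id)

#' Compartment-agnostic species names of a stoichiometry
#'
#' Strips the bracketed compartment tag from metabolite ids, giving the
#' species identity used by the reactant filter and deduplication of the
#' complementation stage.
#'
#' @param ids character vector of metabolite ids like `"glc[c]"`.
#' @return character vector of bare species names.
#' @examples
#' speciesName(c("glc[c]", "co2[h]"))
#' @export
speciesName <- function(ids) .nameOfId(ids)
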