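#' Read a homology-hit table
#'
#' Accepts either a BLAST outfmt-6-style tab-separated table with a header
#' that includes `evalue`, `bitscore` and an added `ec` column (query id in
#' the first column), or a minimal two-column `protein_id` / `ec` map.
#' EC numbers are four dot-separated fields, dash wildcards allowed
#' (`"2.7.1.-"`).
#'
#' @param path file path (UTF-8, tab-separated, `#` comments).
#' @return data.frame with columns `protein_id`, `ec`, `evalue`,
#'   `bitscore`.
#' @export
readHomologyHits <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"ec" %in% names(x))
    stop("homology table must carry an 'ec' column")
  protCol <- intersect(c("protein_id", "qseqid", "query"), names(x))[1]
  if (is.na(protCol)) protCol <- names(x)[1]
  out <- data.frame(protein_id = x[[protCol]], ec = x$ec,
                    evalue = if ("evalue" %in% names(x)) x$evalue else 0,
                    bitscore = if ("bitscore" %in% names(x)) x$bitscore
                               else NA_real_,
                    stringsAsFactors = FALSE)
  bad <- !grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", out$ec)
  if (any(bad))
    stop("malformed EC number(s): ", paste(unique(out$ec[bad]), collapse = ", "))
  if (any(out$evalue < 0)) stop("negative evalue in homology table")
  out
}

#' Read an EC-indexed reaction catalog
#'
#' Tab-separated file with columns `catalog_id`, `ec`, `equation`,
#' `pathway`; equations are in the generic (compartment-free) dialect of
#' [parseEquation()], i.e. species are bare names. A `<->` arrow marks the
#' catalog reaction as reversible.
#'
#' @param path file path.
#' @return data.frame with the source columns plus list column `stoich`
#'   and logical `reversible`.
#' @export
readReactionCatalog <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("catalog_id", "ec", "equation", "pathway")
  if (!all(need %in% names(x)))
    stop("reaction catalog must have columns ", paste(need, collapse = ", "))
  parsed <- lapply(x$equation, parseEquation)
  x$stoich <- lapply(parsed, `[[`, "stoich")
  x$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  x
}

## EC match with dash wildcards on either side
.ecMatches <- function(a, b) {
  fa <- strsplit(a, ".", fixed = TRUE)[[1]]
  fb <- strsplit(b, ".", fixed = TRUE)[[1]]
  all(fa == fb | fa == "-" | fb == "-")
}

#' Associate catalog reactions with homology hits
#'
#' Every catalog reaction reachable from the EC number of an accepted hit
#' (e-value at most `evalueMax`) becomes a reaction candidate; candidates
#' hit multiple times are collapsed and the result is ordered by
#' `catalog_id`, making the stage deterministic. Hit ECs absent from the
#' catalog are recorded in the `unmatchedEC` attribute, not errors.
#'
#' @param hits data.frame from [readHomologyHits()].
#' @param catalog data.frame from [readReactionCatalog()].
#' @param evalueMax homology acceptance threshold (the e-value cutoff of
#'   the upstream search is not part of the table, so acceptance is
#'   re-checked here; default 1e-10).
#' @return candidate data.frame: catalog columns plus `genes` (semicolon
#'   list of contributing proteins) and an ordered `verdicts` list column
#'   tracking every filter a candidate has seen.
#' @seealso [complementNetwork()] for the full pipeline.
#' @export
associateReactions <- function(hits, catalog, evalueMax = 1e-10) {
  keep <- hits$evalue <= evalueMax
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L || nrow(catalog) == 0L) {
    out <- catalog[integer(), , drop = FALSE]
    out$genes <- character()
    out$verdicts <- list()
    attr(out, "unmatchedEC") <- unique(hits$ec)
    return(out)
  }
  hitEC <- unique(hits$ec)
  rows <- which(vapply(catalog$ec, function(ce)
    any(vapply(hitEC, .ecMatches, logical(1), b = ce)), logical(1)))
  out <- catalog[rows, , drop = FALSE]
  out <- out[!duplicated(out$catalog_id), , drop = FALSE]
  out <- out[order(out$catalog_id), , drop = FALSE]
  out$genes <- vapply(out$ec, function(ce)
    paste(sort(unique(hits$protein_id[vapply(hits$ec, .ecMatches, logical(1),
                                             b = ce)])), collapse = ";"),
    character(1))
  out$verdicts <- rep(list(c(associate = "pass")), nrow(out))
  matched <- vapply(hitEC, function(he)
    any(vapply(catalog$ec, .ecMatches, logical(1), a = he)), logical(1))
  attr(out, "unmatchedEC") <- hitEC[!matched]
  rownames(out) <- NULL
  out
}

## orientation-normalized signature of a generic stoichiometry
.stoichSignature <- function(st) {
  st <- st[order(names(st))]
  paste(names(st), format(st, digits = 12, trim = TRUE), sep = ":",
        collapse = "|")
}

.recordVerdict <- function(cands, idx, filter, status) {
  for (k in seq_along(idx)) {
    v <- cands$verdicts[[idx[k]]]
    v[filter] <- status[k]
    cands$verdicts[[idx[k]]] <- v
  }
  cands
}

#' Remove candidates already present in the base network
#'
#' A candidate duplicates a base reaction when the compartment-stripped
#' species multiset and coefficients agree; for reversible reactions
#' (candidate or base) the comparison is orientation-insensitive.
#'
#' @param cands candidate data.frame (see [associateReactions()]).
#' @param base the base [MetabolicNetwork-class].
#' @return the surviving candidates; removed ones are available in the
#'   `removed` attribute with their verdicts.
#' @export
dedupeAgainstBase <- function(cands, base) {
  stopifnot(is(base, "MetabolicNetwork"))
  baseSigs <- character()
  for (i in seq_len(nrow(base@reactions))) {
    st <- base@reactions$stoich[[i]]
    gen <- tapply(st, speciesName(names(st)), sum)
    gen <- structure(as.numeric(gen), names = names(gen))
    baseSigs <- c(baseSigs, .stoichSignature(gen))
    if (base@reactions$lb[i] < 0)
      baseSigs <- c(baseSigs, .stoichSignature(-gen))
  }
  dup <- logical(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    st <- cands$stoich[[k]]
    dup[k] <- .stoichSignature(st) %in% baseSigs ||
      (cands$reversible[k] && .stoichSignature(-st) %in% baseSigs)
  }
  cands <- .recordVerdict(cands, seq_len(nrow(cands)), "dedupe",
                          ifelse(dup, "fail: duplicates base reaction",
                                 "pass"))
  out <- cands[!dup, , drop = FALSE]
  attr(out, "removed") <- cands[dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only candidates whose reactants are already known
#'
#' A candidate passes when every species it uses (compartment-agnostic)
#' already occurs in the base network; species on the generic-name
#' blacklist ("an alcohol" and friends, which cannot be wired into a
#' network) fail the filter as well. The failing species are named in the
#' verdict.
#'
#' @inheritParams dedupeAgainstBase
#' @param genericBlacklist character vector of generic species names that
#'   always fail.
#' @return surviving candidates; removed ones in the `removed` attribute.
#' @export
filterKnownReactants <- function(cands, base, genericBlacklist = character()) {
  stopifnot(is(base, "MetabolicNetwork"))
  known <- unique(speciesName(base@metabolites$id))
  status <- character(nrow(cands))
  ok <- logical(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    sp <- names(cands$stoich[[k]])
    unknown <- setdiff(sp, known)
    banned <- intersect(sp, genericBlacklist)
    bad <- union(unknown, banned)
    ok[k] <- length(bad) == 0L
    status[k] <- if (ok[k]) "pass"
                 else paste0("fail: unknown reactant(s): ",
                             paste(sort(bad), collapse = ", "))
  }
  cands <- .recordVerdict(cands, seq_len(nrow(cands)), "reactants", status)
  out <- cands[ok, , drop = FALSE]
  attr(out, "removed") <- cands[!ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place candidates into compartments
#'
#' A candidate is placed in every compartment in which all of its species
#' already exist in the base network; one reaction per viable compartment
#' is emitted (id suffixed `_<compartment>`, species tagged with that
#' compartment). Candidates with no compartment hosting all their species
#' are dropped with verdict "no viable compartment".
#'
#' @inheritParams dedupeAgainstBase
#' @param bound bound magnitude for the new reactions; reversible catalog
#'   equations get `[-bound, bound]`, others `[0, bound]`.
#' @return list with `reactions` (data.frame ready for [addReactions()],
#'   with a `catalog_id` provenance column) and `candidates` (the input
#'   with placement verdicts).
#' @export
compartmentalize <- function(cands, base, bound = 1000) {
  stopifnot(is(base, "MetabolicNetwork"))
  compOf <- split(base@metabolites$compartment,
                  speciesName(base@metabolites$id))
  rows <- list()
  status <- character(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    sp <- names(cands$stoich[[k]])
    viable <- Reduce(intersect, lapply(sp, function(s)
      unique(compOf[[s]] %||% character())))
    if (length(viable) == 0L) {
      status[k] <- "fail: no viable compartment"
      next
    }
    status[k] <- paste0("pass: ", paste(sort(viable), collapse = ","))
    for (comp in sort(viable)) {
      st <- cands$stoich[[k]]
      names(st) <- paste0(names(st), "[", comp, "]")
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(cands$catalog_id[k], "_", comp),
        name = cands$catalog_id[k],
        lb = if (cands$reversible[k]) -bound else 0, ub = bound,
        ec = cands$ec[k], pathway = cands$pathway[k],
        genes = cands$genes[k],
        stoich = I(list(st)),
        catalog_id = cands$catalog_id[k],
        stringsAsFactors = FALSE)
    }
  }
  cands <- .recordVerdict(cands, seq_len(nrow(cands)), "compartmentalize",
                          status)
  list(reactions = if (length(rows)) do.call(rbind, rows)
                   else data.frame(),
       candidates = cands)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fill network gaps from a catalog, with sink fallback
#'
#' For each dead-end metabolite, searches the catalog for the shortest
#' reaction path (breadth-first on the bipartite metabolite-reaction
#' structure, ties broken lexicographically by catalog id) that gives the
#' metabolite its missing role using only species already present in its
#' compartment. Paths longer than `maxDepth` are not considered; when no
#' path exists a boundary sink/source reaction `SK_<metabolite>` is added,
#' mirroring the insertion of exchange reactions that connect new
#' metabolites to guarantee origin and consumption of reagents. After gap
#' filling, no dead ends remain among the metabolites that were treated or
#' introduced.
#'
#' @param net a [MetabolicNetwork-class].
#' @param catalog data.frame from [readReactionCatalog()]; may be empty.
#' @param maxDepth maximum catalog path length (default 3).
#' @param metaboliteIds dead ends to treat; default every dead end of
#'   `net`.
#' @param bound bound magnitude for added reactions.
#' @return list with `network` and `added` (data.frame: `id`, `source`
#'   being a catalog id or `"sink"`, `for_metabolite`).
#' @export
gapFill <- function(net, catalog, maxDepth = 3, metaboliteIds = NULL,
                    bound = 1000) {
  stopifnot(is(net, "MetabolicNetwork"))
  targets <- metaboliteIds %||% findDeadEnds(net)
  added <- data.frame(id = character(), source = character(),
                      for_metabolite = character(), stringsAsFactors = FALSE)
  for (round in seq_len(10L)) {
    targets <- sort(intersect(targets, findDeadEnds(net)))
    if (length(targets) == 0L) break
    d <- targets[1]
    fix <- .fixDeadEnd(net, catalog, d, maxDepth, bound)
    newIds <- setdiff(fix$network@metabolites$id, net@metabolites$id)
    net <- fix$network
    added <- rbind(added, fix$added)
    targets <- unique(c(targets[-1], newIds))
  }
  stillDead <- intersect(findDeadEnds(net), targets)
  for (d in stillDead) {   # safety net: sink anything a path left behind
    fix <- .addSink(net, d, bound)
    net <- fix$network
    added <- rbind(added, fix$added)
  }
  list(network = net, added = added)
}

.metaboliteRoles <- function(net) {
  rxn <- net@reactions
  produced <- consumed <- character()
  for (i in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[i]]
    if (rxn$ub[i] > 0) {
      produced <- c(produced, names(st)[st > 0])
      consumed <- c(consumed, names(st)[st < 0])
    }
    if (rxn$lb[i] < 0) {
      produced <- c(produced, names(st)[st < 0])
      consumed <- c(consumed, names(st)[st > 0])
    }
  }
  list(produced = unique(produced), consumed = unique(consumed))
}

.addSink <- function(net, d, bound, needsProducer = FALSE) {
  id <- paste0("SK_", d)
  st <- structure(if (needsProducer) 1 else -1, names = d)
  rxn <- data.frame(id = id, name = paste("sink for", d),
                    lb = 0, ub = bound, ec = NA_character_,
                    pathway = "gap-fill sink", genes = "",
                    stoich = I(list(st)), stringsAsFactors = FALSE)
  list(network = addReactions(net, rxn),
       added = data.frame(id = id, source = "sink", for_metabolite = d,
                          stringsAsFactors = FALSE))
}

.fixDeadEnd <- function(net, catalog, d, maxDepth, bound) {
  roles <- .metaboliteRoles(net)
  needsConsumer <- !(d %in% roles$consumed)
  comp <- .compartmentOfId(d)
  path <- .bfsCatalogPath(net, catalog, d, comp, needsConsumer, maxDepth,
                          roles)
  if (is.null(path))
    return(.addSink(net, d, bound, needsProducer = !needsConsumer))
  rows <- list(); prov <- list()
  for (k in path) {
    st <- catalog$stoich[[k]]
    names(st) <- paste0(names(st), "[", comp, "]")
    id <- paste0(catalog$catalog_id[k], "_", comp)
    if (id %in% net@reactions$id) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, name = catalog$catalog_id[k],
      lb = if (catalog$reversible[k]) -bound else 0, ub = bound,
      ec = catalog$ec[k], pathway = catalog$pathway[k], genes = "",
      stoich = I(list(st)), stringsAsFactors = FALSE)
    prov[[length(prov) + 1L]] <- data.frame(
      id = id, source = catalog$catalog_id[k], for_metabolite = d,
      stringsAsFactors = FALSE)
  }
  list(network = if (length(rows)) addReactions(net, do.call(rbind, rows))
                 else net,
       added = if (length(prov)) do.call(rbind, prov)
               else data.frame(id = character(), source = character(),
                               for_metabolite = character()))
}

## breadth-first search for the shortest catalog path that gives metabolite
## d its missing role in compartment comp; returns catalog row indices or
## NULL. State: set of species (tagged ids) still needing the role.
.bfsCatalogPath <- function(net, catalog, d, comp, needsConsumer, maxDepth,
                            roles) {
  if (nrow(catalog) == 0L) return(NULL)
  ord <- order(catalog$catalog_id)
  tag <- function(sp) paste0(sp, "[", comp, "]")
  known <- net@metabolites$id
  satisfied <- if (needsConsumer) roles$consumed else roles$produced
  available <- if (needsConsumer) roles$produced else roles$consumed
  queue <- list(list(needs = d, path = integer()))
  seen <- character()
  while (length(queue)) {
    stately <- queue[[1]]; queue <- queue[-1]
    if (length(stately$path) >= maxDepth) next
    target <- stately$needs[1]
    for (k in ord) {
      st <- catalog$stoich[[k]]
      ids <- tag(names(st))
      if (!all(ids %in% known)) next        # restricted to known species
      takes <- if (needsConsumer) ids[st < 0] else ids[st > 0]
      gives <- if (needsConsumer) ids[st > 0] else ids[st < 0]
      if (catalog$reversible[k] && !(target %in% takes)) {
        takes2 <- if (needsConsumer) ids[st > 0] else ids[st < 0]
        if (target %in% takes2) { tmp <- takes; takes <- takes2; gives <- tmp }
      }
      if (!(target %in% takes)) next
      ## the reaction's other inputs must already be available
      if (!all(setdiff(takes, target) %in% c(available, satisfied))) next
      newNeeds <- unique(c(stately$needs[-1],
                           gives[!(gives %in% satisfied)]))
      key <- paste(sort(newNeeds), collapse = "|")
      if (length(newNeeds) == 0L) return(c(stately$path, k))
      if (key %in% seen) next
      seen <- c(seen, key)
      queue[[length(queue) + 1L]] <- list(needs = newNeeds,
                                          path = c(stately$path, k))
    }
  }
  NULL
}

#' Complement a base network from homology evidence
#'
#' Runs the full complementation pipeline in its documented order:
#' associate catalog reactions to homology hits, reject blacklisted
#' pathways, remove reactions already in the base network, keep only
#' candidates with known reactants, place survivors into compartments, add
#' them, and gap-fill any dead ends the additions introduced. Counts are
#' non-increasing through the dedup and reactant-filter stages and the
#' whole procedure is deterministic, so identical inputs give identical
#' networks.
#'
#' @inheritParams associateReactions
#' @param base the base [MetabolicNetwork-class].
#' @param genericBlacklist generic species names that fail the reactant
#'   filter (default none).
#' @param pathwayBlacklist pathway labels rejected outright, standing in
#'   for manual curation of implausible pathways (default none).
#' @param maxDepth gap-fill search depth.
#' @param bound bound magnitude for added reactions.
#' @return list of class `ComplementReport` with elements `network`,
#'   `counts` (per-stage), `added` (provenance of every added reaction),
#'   `candidates` (with full verdict trails) and `unmatchedEC`.
#' @examples
#' gen <- generateNetwork(networkBlueprint(seed = 1))
#' hom <- generateHomologyInputs(gen$network, seed = 1)
#' rep <- complementNetwork(gen$network, hom$hits, hom$catalog)
#' rep$counts
#' @export
complementNetwork <- function(base, hits, catalog, evalueMax = 1e-10,
                              genericBlacklist = character(),
                              pathwayBlacklist = character(),
                              maxDepth = 3, bound = 1000) {
  stopifnot(is(base, "MetabolicNetwork"))
  cands <- associateReactions(hits, catalog, evalueMax = evalueMax)
  unmatched <- attr(cands, "unmatchedEC")
  nAssoc <- nrow(cands)

  if (length(pathwayBlacklist)) {
    banned <- cands$pathway %in% pathwayBlacklist
    cands <- .recordVerdict(cands, seq_len(nrow(cands)), "pathway",
                            ifelse(banned, "fail: blacklisted pathway",
                                   "pass"))
    cands <- cands[!banned, , drop = FALSE]
  }
  trail <- list()
  cands <- dedupeAgainstBase(cands, base)
  trail$dedupe <- attr(cands, "removed")
  nDedup <- nrow(cands)
  cands <- filterKnownReactants(cands, base, genericBlacklist)
  trail$reactants <- attr(cands, "removed")
  nFilter <- nrow(cands)
  placed <- compartmentalize(cands, base, bound = bound)
  nPlaced <- if (nrow(placed$reactions)) nrow(placed$reactions) else 0L

  net <- base
  preMets <- net@metabolites$id
  if (nPlaced > 0L) {
    prov <- placed$reactions$catalog_id
    rxns <- placed$reactions[setdiff(names(placed$reactions), "catalog_id")]
    net <- addReactions(net, rxns)
    addedRxn <- data.frame(id = rxns$id, source = prov,
                           for_metabolite = NA_character_,
                           stringsAsFactors = FALSE)
  } else addedRxn <- data.frame(id = character(), source = character(),
                                for_metabolite = character())

  ## gap-fill only gaps introduced by the additions
  touched <- setdiff(net@metabolites$id, preMets)
  touched <- union(touched,
                   unlist(lapply(placed$reactions$stoich, names)))
  newDead <- intersect(findDeadEnds(net), touched)
  gf <- gapFill(net, catalog, maxDepth = maxDepth, metaboliteIds = newDead,
                bound = bound)
  net <- gf$network
  counts <- c(associated = as.integer(nAssoc),
              deduplicated = as.integer(nDedup),
              reactant_filtered = as.integer(nFilter),
              compartmentalized = as.integer(nPlaced),
              gap_filled = sum(gf$added$source != "sink"),
              exchanges_added = sum(gf$added$source == "sink"))
  allCand <- rbind(placed$candidates, trail$dedupe, trail$reactants)
  allCand <- allCand[order(allCand$catalog_id), , drop = FALSE]
  structure(list(network = net, counts = counts,
                 added = rbind(addedRxn, gf$added),
                 candidates = allCand, unmatchedEC = unmatched),
            class = "ComplementReport")
}

#' @export
print.ComplementReport <- function(x, ...) {
  cat("ComplementReport\n  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-20s %d\n", nm, x$counts[[nm]]))
  cat("  reactions added:", nrow(x$added), "\n")
  if (length(x$unmatchedEC))
    cat("  unmatched hit ECs:", paste(x$unmatchedEC, collapse = ", "), "\n")
  invisible(x)
}
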