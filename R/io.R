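#' Read and write compartmentalized metabolic networks
#'
#' Two on-disk formats are supported. The tabular dialect is a UTF-8,
#' tab-separated file with `#` comment lines, `#!` directive lines and one
#' reaction per row (columns `id`, `name`, `equation`, `lb`, `ub`, `ec`,
#' `pathway`, `genes`); compartments are carried in square brackets per
#' species inside the equation. Directives declare the objective
#' (`#! objective<TAB>BIO`), compartments
#' (`#! compartment<TAB>c<TAB>cytosol`) and, optionally, metabolites
#' (`#! met<TAB>co2[c]<TAB>carbon dioxide<TAB>CO2`). When any `#! met`
#' directive is present the file is read in strict mode: an equation
#' referencing an undeclared metabolite is an integrity error. The SBML
#' format is minimal Level 3 core (species, reactions, bounds via
#' parameters, objective via annotation; no fbc/groups/layout packages).
#'
#' `writeNetwork` followed by `readNetwork` is the identity on valid
#' networks. Reversibility is encoded purely through the sign of the lower
#' bound and the equation arrow; it is never stored separately.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sbml"`; default guessed from the file
#'   extension (`.xml`/`.sbml` read as SBML).
#' @param net a [MetabolicNetwork-class].
#' @return `readNetwork` returns a [MetabolicNetwork-class];
#'   `writeNetwork` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeNetwork(toyNetwork(), f)
#' net <- readNetwork(f)
#' net
#' @export
readNetwork <- function(path, format = c("guess", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, tsv = .readNetworkTSV(path), sbml = .readNetworkSBML(path))
}

#' @rdname readNetwork
#' @export
writeNetwork <- function(net, path, format = c("guess", "tsv", "sbml")) {
  stopifnot(is(net, "MetabolicNetwork"))
  validObject(net)
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  switch(format,
         tsv = .writeNetworkTSV(net, path),
         sbml = .writeNetworkSBML(net, path))
  invisible(path)
}

## ---------------------------------------------------------------- TSV ----

.readNetworkTSV <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  isDirective <- startsWith(lines, "#!")
  directives <- lines[isDirective]
  body <- lines[!isDirective & !startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("parse error in ", path, ": no reaction rows found")

  comp <- character(); compName <- character()
  metDecl <- data.frame(id = character(), name = character(),
                        formula = character(), stringsAsFactors = FALSE)
  objective <- NA_character_
  for (d in directives) {
    f <- strsplit(sub("^#!\\s*", "", d), "\t", fixed = TRUE)[[1]]
    key <- f[1]
    if (key == "objective") objective <- f[2]
    else if (key == "compartment") {
      comp <- c(comp, f[2])
      compName <- c(compName, if (length(f) >= 3L) f[3] else f[2])
    } else if (key == "met") {
      metDecl <- rbind(metDecl, data.frame(
        id = f[2],
        name = if (length(f) >= 3L) f[3] else .nameOfId(f[2]),
        formula = if (length(f) >= 4L) f[4] else NA_character_,
        stringsAsFactors = FALSE))
    } else stop("unknown directive '", key, "' in ", path)
  }

  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("id", "name", "equation", "lb", "ub", "ec", "pathway", "genes")
  if (!identical(header[seq_along(need)], need))
    stop("parse error in ", path, ": header must be ",
         paste(need, collapse = "\t"))
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  rxn <- do.call(rbind, lapply(seq_along(rows), function(k) {
    f <- rows[[k]]
    length(f) <- length(need)
    f[is.na(f)] <- ""
    p <- tryCatch(parseEquation(f[3]),
                  error = function(e) stop("parse error at reaction row ", k,
                                           " of ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    data.frame(id = f[1], name = f[2],
               lb = as.numeric(f[4]), ub = as.numeric(f[5]),
               ec = if (nzchar(f[6])) f[6] else NA_character_,
               pathway = if (nzchar(f[7])) f[7] else NA_character_,
               genes = f[8],
               stoich = I(list(p$stoich)),
               stringsAsFactors = FALSE)
  }))

  used <- unique(unlist(lapply(rxn$stoich, names)))
  if (nrow(metDecl)) {
    unknown <- setdiff(used, metDecl$id)
    if (length(unknown))
      stop("integrity error in ", path,
           ": equations reference undeclared metabolites: ",
           paste(unknown, collapse = ", "))
    met <- metDecl
  } else {
    met <- data.frame(id = used, name = .nameOfId(used),
                      formula = NA_character_, stringsAsFactors = FALSE)
  }
  met$compartment <- vapply(met$id, .compartmentOfId, character(1))
  if (length(comp) == 0L) {
    comp <- unique(met$compartment)
    compName <- comp
  }
  if (is.na(objective))
    stop("integrity error in ", path, ": no '#! objective' directive")
  MetabolicNetwork(met, rxn, objectiveId = objective,
                   compartments = structure(comp, names = NULL))
}

.writeNetworkTSV <- function(net, path) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  met <- net@metabolites
  rxn <- net@reactions
  writeLines(c(
    paste0("#! objective\t", net@objectiveId),
    paste0("#! compartment\t", net@compartments),
    paste0("#! met\t", met$id, "\t", met$name, "\t",
           ifelse(is.na(met$formula), "", met$formula))
  ), con)
  writeLines(paste(c("id", "name", "equation", "lb", "ub", "ec", "pathway",
                     "genes"), collapse = "\t"), con)
  eqs <- vapply(seq_len(nrow(rxn)), function(i)
    formatEquation(rxn$stoich[[i]], reversible = rxn$lb[i] < 0), character(1))
  writeLines(paste(rxn$id, rxn$name, eqs,
                   vapply(rxn$lb, .num2str, character(1)),
                   vapply(rxn$ub, .num2str, character(1)),
                   ifelse(is.na(rxn$ec), "", rxn$ec),
                   ifelse(is.na(rxn$pathway), "", rxn$pathway),
                   rxn$genes, sep = "\t"), con)
}

.num2str <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

## --------------------------------------------------------------- SBML ----

.sbmlNS <- "http://www.sbml.org/sbml/level3/version1/core"
.co2fluxNS <- "https://example.org/co2flux/sbml"

.sanitizeSId <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", out), paste0("x", out), out)
}

.writeNetworkSBML <- function(net, path) {
  met <- net@metabolites
  rxn <- net@reactions
  sidMet <- structure(make.unique(paste0("M_", .sanitizeSId(met$id))),
                      names = met$id)
  sidRxn <- structure(make.unique(paste0("R_", .sanitizeSId(rxn$id))),
                      names = rxn$id)
  doc <- xml2::xml_new_root("sbml",
                            xmlns = .sbmlNS, "xmlns:cf" = .co2fluxNS,
                            level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "model")
  ann <- xml2::xml_add_child(model, "annotation")
  xml2::xml_add_child(ann, "cf:objective",
                      id = sidRxn[[net@objectiveId]],
                      originalId = net@objectiveId)
  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in net@compartments)
    xml2::xml_add_child(loc, "compartment", id = .sanitizeSId(cid),
                        name = cid, constant = "true")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(los, "species",
                              id = sidMet[[met$id[i]]], name = met$name[i],
                              compartment = .sanitizeSId(met$compartment[i]),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    a <- xml2::xml_add_child(sp, "annotation")
    xml2::xml_add_child(a, "cf:metabolite", originalId = met$id[i],
                        formula = ifelse(is.na(met$formula[i]), "",
                                         met$formula[i]))
  }
  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (i in seq_len(nrow(rxn))) {
    xml2::xml_add_child(lop, "parameter", id = paste0("lb_", sidRxn[[rxn$id[i]]]),
                        value = .num2str(rxn$lb[i]), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("ub_", sidRxn[[rxn$id[i]]]),
                        value = .num2str(rxn$ub[i]), constant = "true")
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(rxn))) {
    r <- xml2::xml_add_child(lor, "reaction", id = sidRxn[[rxn$id[i]]],
                             name = rxn$name[i],
                             reversible = tolower(rxn$lb[i] < 0),
                             fast = "false")
    a <- xml2::xml_add_child(r, "annotation")
    xml2::xml_add_child(a, "cf:reaction", originalId = rxn$id[i],
                        ec = ifelse(is.na(rxn$ec[i]), "", rxn$ec[i]),
                        pathway = ifelse(is.na(rxn$pathway[i]), "",
                                         rxn$pathway[i]),
                        genes = rxn$genes[i])
    st <- rxn$stoich[[i]]
    sub <- st[st < 0]; prod <- st[st > 0]
    if (length(sub)) {
      lr <- xml2::xml_add_child(r, "listOfReactants")
      for (s in names(sub))
        xml2::xml_add_child(lr, "speciesReference", species = sidMet[[s]],
                            stoichiometry = .num2str(-sub[[s]]),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(r, "listOfProducts")
      for (s in names(prod))
        xml2::xml_add_child(lp, "speciesReference", species = sidMet[[s]],
                            stoichiometry = .num2str(prod[[s]]),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
}

.readNetworkSBML <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = .sbmlNS, cf = .co2fluxNS)
  getAttr <- xml2::xml_attr

  spNodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sid <- getAttr(spNodes, "id")
  metAnn <- lapply(spNodes, xml2::xml_find_first, ".//cf:metabolite", ns)
  origId <- vapply(seq_along(spNodes), function(i) {
    o <- if (!inherits(metAnn[[i]], "xml_missing"))
      getAttr(metAnn[[i]], "originalId") else NA_character_
    if (is.na(o)) sid[i] else o
  }, character(1))
  formula <- vapply(seq_along(spNodes), function(i) {
    f <- if (!inherits(metAnn[[i]], "xml_missing"))
      getAttr(metAnn[[i]], "formula") else NA_character_
    if (is.na(f) || f == "") NA_character_ else f
  }, character(1))
  met <- data.frame(id = origId, name = getAttr(spNodes, "name"),
                    formula = formula, stringsAsFactors = FALSE)
  met$compartment <- vapply(met$id, .compartmentOfId, character(1))
  sid2orig <- structure(origId, names = sid)

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- structure(as.numeric(getAttr(params, "value")),
                    names = getAttr(params, "id"))

  rxNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxNodes) == 0L) stop("parse error in ", path, ": no reactions")
  rxn <- do.call(rbind, lapply(rxNodes, function(node) {
    rid <- getAttr(node, "id")
    a <- xml2::xml_find_first(node, ".//cf:reaction", ns)
    orig <- if (!inherits(a, "xml_missing")) getAttr(a, "originalId") else NA
    if (is.na(orig)) orig <- rid
    grab <- function(attr) {
      v <- if (!inherits(a, "xml_missing")) getAttr(a, attr) else NA_character_
      if (is.na(v) || v == "") NA_character_ else v
    }
    refs <- function(xp, sgn) {
      nn <- xml2::xml_find_all(node, xp, ns)
      if (length(nn) == 0L) return(numeric())
      structure(sgn * as.numeric(getAttr(nn, "stoichiometry")),
                names = unname(sid2orig[getAttr(nn, "species")]))
    }
    st <- c(refs(".//s:listOfReactants/s:speciesReference", -1),
            refs(".//s:listOfProducts/s:speciesReference", +1))
    lb <- pval[paste0("lb_", rid)]; ub <- pval[paste0("ub_", rid)]
    data.frame(id = orig, name = getAttr(node, "name"),
               lb = if (is.na(lb)) 0 else lb,
               ub = if (is.na(ub)) 1000 else ub,
               ec = grab("ec"), pathway = grab("pathway"),
               genes = {g <- grab("genes"); if (is.na(g)) "" else g},
               stoich = I(list(st)), stringsAsFactors = FALSE)
  }))

  objNode <- xml2::xml_find_first(doc, ".//cf:objective", ns)
  if (inherits(objNode, "xml_missing"))
    stop("integrity error in ", path, ": no objective annotation")
  objective <- getAttr(objNode, "originalId")
  if (is.na(objective)) objective <- getAttr(objNode, "id")

  compNodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  comp <- getAttr(compNodes, "name")
  comp[is.na(comp)] <- getAttr(compNodes, "id")[is.na(comp)]
  MetabolicNetwork(met, rxn, objectiveId = objective, compartments = comp)
}
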