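#' Run the full CO2-sensitivity workflow from a configuration
#'
#' Orchestrates the analysis end to end: load the base network; if
#' homology inputs are configured, complement it (associate, dedupe,
#' reactant filter, compartmentalize, gap fill); if group-contribution
#' tables are configured, assign directionality of the newly added
#' reactions; scan the CO2 conditions and classify sensitive reactions;
#' and, if qPCR / metabolomics inputs are configured, compute expression
#' ratios, normalized fold changes and the concordance of measured
#' directions with predicted net fluxes. All stage outputs are written as
#' tab-separated tables under the configured output directory together
#' with a JSON run report; identical configuration and inputs always
#' produce identical outputs.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' keys: `base_network` (required), `conditions` (required),
#' `homology_hits` + `reaction_catalog`, `group_contributions` +
#' `group_decomposition`, `qpcr_ct`, `fluorescence`, `metabolites`,
#' `out_dir`, `co2_exchange` / `photon_exchange` (default `EX_co2` /
#' `EX_photon`), `low_condition` / `high_condition` (default `air` /
#' `co2_10`), and a `thresholds` block (`rho`, `tau`, `evalue`, `alpha`).
#'
#' @param config path to a YAML configuration file, or a named list.
#' @return invisibly, the run report (a named list, also written as
#'   `report.json`).
#' @examples
#' \donttest{
#' dir <- tempfile(); bundle <- writeSyntheticBundle(dir, seed = 7)
#' report <- runPipeline(bundle$config)
#' report$sensitivity$n_sensitive
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfgDir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    ## resolve input paths relative to the config file
    pathKeys <- c("base_network", "conditions", "homology_hits",
                  "reaction_catalog", "group_contributions",
                  "group_decomposition", "qpcr_ct", "fluorescence",
                  "metabolites", "out_dir")
    for (k in intersect(pathKeys, names(config)))
      if (!startsWith(config[[k]], "/"))
        config[[k]] <- file.path(cfgDir, config[[k]])
  }
  stopifnot(is.list(config))
  for (k in c("base_network", "conditions"))
    if (is.null(config[[k]]))
      stop("configuration error: missing required key '", k, "'")
  for (k in c("base_network", "conditions", "homology_hits",
              "reaction_catalog", "group_contributions",
              "group_decomposition", "qpcr_ct", "fluorescence",
              "metabolites"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      stop("configuration error: input '", k, "' not found at ",
           config[[k]])
  thr <- config$thresholds %||% list()
  rho <- thr$rho %||% 0.01
  tau <- thr$tau %||% 30
  evalueMax <- thr$evalue %||% 1e-10
  co2Id <- config$co2_exchange %||% "EX_co2"
  photonId <- config$photon_exchange %||% "EX_photon"
  lowCond <- config$low_condition %||% "air"
  highCond <- config$high_condition %||% "co2_10"
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[!vapply(config, is.list, logical(1))])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  net <- stage("load", readNetwork(config$base_network))
  conditions <- stage("load", readConditions(config$conditions))
  report$network <- list(metabolites = nMetabolites(net),
                         reactions = nReactions(net))

  addedIds <- character()
  if (!is.null(config$homology_hits) && !is.null(config$reaction_catalog)) {
    comp <- stage("complement", {
      hits <- readHomologyHits(config$homology_hits)
      catalog <- readReactionCatalog(config$reaction_catalog)
      complementNetwork(net, hits, catalog, evalueMax = evalueMax)
    })
    net <- comp$network
    addedIds <- comp$added$id
    report$complement <- as.list(comp$counts)
    utils::write.table(comp$added, file.path(outDir, "added_reactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$group_contributions) &&
      !is.null(config$group_decomposition) && length(addedIds)) {
    th <- stage("thermo", {
      tab <- readGroupTable(config$group_contributions)
      dec <- readGroupDecomposition(config$group_decomposition)
      applyThermodynamics(net, dec, tab, reactionIds = addedIds, tau = tau)
    })
    net <- th$network
    report$thermo <- as.list(table(th$energies$verdict))
    utils::write.table(th$energies, file.path(outDir, "reaction_energies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  se <- stage("scan", scanConditions(net, conditions, co2Id = co2Id,
                                     photonId = photonId,
                                     rhoThreshold = rho))
  rd <- SummarizedExperiment::rowData(se)
  sensTab <- data.frame(reaction_id = rownames(se),
                        as.data.frame(SummarizedExperiment::assay(se, "flux")),
                        rho = rd$rho, sensitive = rd$sensitive,
                        pathway = rd$pathway, compartment = rd$compartment,
                        check.names = FALSE)
  utils::write.table(sensTab, file.path(outDir, "sensitivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- aggregateSensitivity(se)
  utils::write.table(agg$pathway, file.path(outDir, "pathway_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(agg$compartment,
                     file.path(outDir, "compartment_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$sensitivity <- list(
    n_sensitive = length(sensitiveReactions(se)),
    objectives = as.list(S4Vectors::metadata(se)$objectives),
    sensitive = sensitiveReactions(se))

  if (!is.null(config$qpcr_ct)) {
    ratios <- stage("validate", {
      ct <- utils::read.csv(config$qpcr_ct, stringsAsFactors = FALSE)
      ct$melt_ok <- as.logical(ct$melt_ok)
      refGene <- config$reference_gene %||% "ACT"
      targets <- setdiff(unique(ct$gene), refGene)
      do.call(rbind, lapply(targets, function(g) {
        r <- pfafflRatio(ct, g, reference = refGene)
        data.frame(gene = g, ratio = r$ratio,
                   reference = paste(refGene, collapse = ";"),
                   stringsAsFactors = FALSE)
      }))
    })
    utils::write.table(ratios, file.path(outDir, "expression_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$expression <- list(n_genes = nrow(ratios))
  }

  if (!is.null(config$metabolites)) {
    stage("validate", {
      mtab <- utils::read.csv(config$metabolites, stringsAsFactors = FALSE)
      norm <- normalizeMetabolites(mtab)
      fc <- log2FoldChange(norm)
      utils::write.table(fc, file.path(outDir, "metabolite_fc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$metabolomics <- list(
        n_analytes = nrow(fc),
        n_significant = sum(fc$p_adj < (thr$alpha %||% 0.05), na.rm = TRUE))
      ## reconcile with predicted net fluxes where names can be matched
      shared <- metaboliteIds(net)[speciesName(metaboliteIds(net)) %in%
                                     fc$analyte]
      shared <- shared[!duplicated(speciesName(shared))]
      if (length(shared)) {
        nf <- netFluxTable(se, net, shared, lowCondition = lowCond,
                           highCondition = highCond)
        conc <- concordance(nf, fc)
        utils::write.table(conc$table, file.path(outDir, "concordance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$concordance <- as.list(conc$counts)
      }
    })
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

## ----------------------------------------------------- input writers ----

#' Write pipeline input tables
#'
#' Plain-text writers matching the readers of the corresponding modules
#' (tab-separated for network-side tables, CSV for the omics tables).
#'
#' @param x the object to write (see the paired reader for the expected
#'   shape).
#' @param path output file path.
#' @return invisibly, `path`.
#' @name inputWriters
NULL

#' @rdname inputWriters
#' @export
writeConditions <- function(x, path) {
  .checkConditions(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname inputWriters
#' @export
writeHomologyHits <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname inputWriters
#' @export
writeReactionCatalog <- function(x, path) {
  cols <- c("catalog_id", "ec", "equation", "pathway")
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname inputWriters
#' @export
writeGroupTable <- function(x, path) {
  df <- data.frame(group_id = c("origin", names(x$contributions)),
                   contribution_kj_mol = c(x$origin, unname(x$contributions)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname inputWriters
#' @export
writeGroupDecomposition <- function(x, path) {
  df <- do.call(rbind, lapply(names(x), function(mid)
    data.frame(metabolite_id = mid, group_id = names(x[[mid]]),
               count = unname(x[[mid]]), stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes (network, homology hits,
#' reaction catalog, thermodynamic tables, condition table, qPCR Ct and
#' fluorescence tables, metabolite intensities), writes them under `dir`
#' together with a ready-to-run `config.yaml` and a `manifest.json`
#' holding all ground truth, and returns the paths and truths.
#'
#' @param dir output directory (created if needed).
#' @param seed master RNG seed; sub-generators derive their own seeds from
#'   it.
#' @param blueprint network blueprint; default [networkBlueprint()] with
#'   this seed.
#' @return list with `config` (path to config.yaml), `manifest` (list of
#'   ground truths), `dir`.
#' @export
writeSyntheticBundle <- function(dir, seed = 1,
                                 blueprint = networkBlueprint(seed = seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generateNetwork(blueprint)
  hom <- generateHomologyInputs(gen$network, seed = seed + 1L)
  th <- generateThermoInputs(gen$network, seed = seed + 2L)
  qp <- generateQpcr(seed = seed + 3L)
  ## measured analytes named after interior network species so the
  ## concordance stage has identifiers to reconcile
  analytes <- sort(unique(speciesName(grep("^(smet|pmet)",
                                           metaboliteIds(gen$network),
                                           value = TRUE))))
  fcs <- structure(rep(1, length(analytes)), names = analytes)
  fcs[1] <- 2.5
  fcs[2] <- 0.3
  mb <- generateMetabolites(seed = seed + 4L, nAnalytes = length(fcs),
                            foldChanges = fcs)

  p <- function(f) file.path(dir, f)
  writeNetwork(gen$network, p("network.tsv"))
  writeHomologyHits(hom$hits, p("hits.tsv"))
  writeReactionCatalog(hom$catalog, p("catalog.tsv"))
  writeGroupTable(th$table, p("group_contributions.tsv"))
  writeGroupDecomposition(th$decomposition, p("group_decomposition.tsv"))
  writeConditions(defaultConditions(), p("conditions.tsv"))
  utils::write.csv(qp$ct, p("qpcr_ct.csv"), row.names = FALSE)
  utils::write.csv(qp$curves, p("fluorescence.csv"), row.names = FALSE)
  utils::write.csv(mb$table, p("metabolites.csv"), row.names = FALSE)

  config <- list(
    base_network = "network.tsv",
    conditions = "conditions.tsv",
    homology_hits = "hits.tsv",
    reaction_catalog = "catalog.tsv",
    group_contributions = "group_contributions.tsv",
    group_decomposition = "group_decomposition.tsv",
    qpcr_ct = "qpcr_ct.csv",
    fluorescence = "fluorescence.csv",
    metabolites = "metabolites.csv",
    out_dir = "results",
    co2_exchange = "EX_co2", photon_exchange = "EX_photon",
    low_condition = "air", high_condition = "co2_10",
    thresholds = list(rho = 0.01, tau = 30, evalue = 1e-10, alpha = 0.05),
    seed = seed)
  yaml::write_yaml(config, p("config.yaml"))

  manifest <- list(network = gen$truth, complement = hom$manifest,
                   qpcr = qp$truth["genes"],
                   metabolites = list(foldChanges = mb$truth$foldChanges),
                   seed = seed)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  list(config = p("config.yaml"), manifest = manifest, dir = dir)
}
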