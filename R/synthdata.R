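## Seeded generators for every input the pipeline consumes, with ground
## truth recorded so downstream stages can be asserted without re-deriving
## it. All generators are pure functions of their blueprint and seed and
## leave the caller's RNG state untouched.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Blueprint for a synthetic CO2-responsive network
#'
#' Describes a small compartmentalized autotrophic network with a designed
#' optimum: a photosynthesis-like core (CO2 + photons -> fixed carbon)
#' feeding a linear biomass chain whose fluxes scale with the CO2 exchange
#' bound (the planted CO2-sensitive reactions), a pinned chain fed by a
#' fixed uptake whose fluxes are constant across conditions, an optional
#' set of orphan (dead-end) metabolites, and optional disconnected "decoy"
#' reaction pairs used by the complementation generators. Defaults give
#' 30-60 metabolites / 40-100 reactions class sizes scaled down to a few
#' dozen, with three compartments (cytosol, chloroplast, mitochondrion)
#' plus the extracellular space.
#'
#' @param nSensitive length of the planted CO2-sensitive interior chain.
#' @param nPinned length of the pinned (CO2-insensitive) chain.
#' @param nOrphans number of planted dead-end metabolites.
#' @param nDecoys number of disconnected decoy species (>= 2 or 0).
#' @param nCompartments number of intracellular compartments (2-10).
#' @param lightFlux fixed photon uptake, mE/gDW/h.
#' @param photonPerCarbon photons consumed per CO2 fixed.
#' @param seed RNG seed; the same blueprint and seed always generate the
#'   identical network.
#' @return a list of class `networkBlueprint`.
#' @export
networkBlueprint <- function(nSensitive = 5, nPinned = 6, nOrphans = 2,
                             nDecoys = 6, nCompartments = 3,
                             lightFlux = 57.54, photonPerCarbon = 2,
                             seed = 1) {
  stopifnot(nSensitive >= 1, nPinned >= 1, nOrphans >= 0,
            nDecoys == 0 || nDecoys >= 2,
            nCompartments >= 2, nCompartments <= 10,
            lightFlux > 0, photonPerCarbon >= 1)
  structure(list(nSensitive = nSensitive, nPinned = nPinned,
                 nOrphans = nOrphans, nDecoys = nDecoys,
                 nCompartments = nCompartments, lightFlux = lightFlux,
                 photonPerCarbon = photonPerCarbon, seed = seed),
            class = "networkBlueprint")
}

#' Generate a synthetic network with known CO2-sensitivity ground truth
#'
#' Builds the network described by a [networkBlueprint()]. The returned
#' truth manifest records `planted` (the interior sensitive chain),
#' `sensitive` (every reaction whose optimal flux varies with the CO2
#' bound: the planted chain plus the CO2 exchange/transport/fixation
#' scaffold, the biomass drain and the photon quench), `pinned` (constant
#' or zero flux), `orphans`, and the closed-form optimum: biomass flux
#' equals `min(co2_bound, lightFlux / photonPerCarbon)`.
#'
#' @param blueprint a [networkBlueprint()].
#' @return list with `network` ([MetabolicNetwork-class]), `truth` (list)
#'   and `blueprint`.
#' @examples
#' gen <- generateNetwork(networkBlueprint(seed = 7))
#' gen$network
#' gen$truth$sensitive
#' @export
generateNetwork <- function(blueprint) {
  stopifnot(inherits(blueprint, "networkBlueprint"))
  .withSeed(blueprint$seed, {
    bp <- blueprint
    comps <- names(defaultCompartments())[seq_len(bp$nCompartments)]
    sensPathways <- c("glycolysis/gluconeogenesis",
                      "glyoxylate and dicarboxylate metabolism",
                      "carbon fixation")
    pinPathways <- c("pentose phosphate pathway",
                     "starch and sucrose metabolism")
    rows <- list()
    addRxn <- function(id, stoich, lb = 0, ub = 1000, pathway = NA_character_,
                       name = id) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, name = name, lb = lb, ub = ub, ec = NA_character_,
        pathway = pathway, genes = "", stoich = I(list(stoich)),
        stringsAsFactors = FALSE)
    }

    ## autotrophic scaffold
    addRxn("EX_co2", c("co2[e]" = 1), lb = 0, ub = 10, pathway = "exchange")
    addRxn("T_co2", c("co2[e]" = -1, "co2[h]" = 1), pathway = "transport")
    addRxn("EX_photon", c("photon[h]" = 1), lb = bp$lightFlux,
           ub = bp$lightFlux, pathway = "exchange")
    addRxn("PS", c("co2[h]" = -1,
                   "photon[h]" = -bp$photonPerCarbon, "fixc[h]" = 1),
           pathway = "carbon fixation", name = "carbon fixation core")
    addRxn("NPQ", c("photon[h]" = -1), pathway = "photon quench",
           name = "non-photochemical quench")

    ## planted CO2-sensitive chain: fixc -> ... -> biomass precursor
    prev <- "fixc[h]"
    sns <- character(bp$nSensitive)
    for (i in seq_len(bp$nSensitive)) {
      comp <- sample(comps, 1)
      met <- sprintf("smet%02d[%s]", i, comp)
      sns[i] <- sprintf("SNS_%02d", i)
      addRxn(sns[i], structure(c(-1, 1), names = c(prev, met)),
             pathway = sample(sensPathways, 1))
      prev <- met
    }
    addRxn("BIO", structure(-1, names = prev), pathway = "biomass",
           name = "biomass drain")

    ## pinned chain: fixed uptake, constant flux at every condition
    addRxn("EX_ac", c("ac[e]" = 1), lb = 1, ub = 1, pathway = "exchange")
    addRxn("T_ac", c("ac[e]" = -1, "ac[c]" = 1), pathway = "transport")
    prev <- "ac[c]"
    pinFlux <- 1
    for (i in seq_len(bp$nPinned)) {
      comp <- sample(comps, 1)
      met <- sprintf("pmet%02d[%s]", i, comp)
      coef <- sample(c(1, 1, 2), 1)
      addRxn(sprintf("PIN_%02d", i),
             structure(c(-coef, 1), names = c(prev, met)),
             pathway = sample(pinPathways, 1))
      pinFlux <- pinFlux / coef
      prev <- met
    }
    addRxn("SK_pin", structure(-1, names = prev), pathway = "exchange",
           name = "pinned chain sink")

    ## planted orphan (dead-end) metabolites
    orphans <- character(bp$nOrphans)
    for (i in seq_len(bp$nOrphans)) {
      orphans[i] <- sprintf("omet%02d[h]", i)
      addRxn(sprintf("ORPH_%02d", i),
             structure(c(-1, 1), names = c("fixc[h]", orphans[i])),
             pathway = "unconnected")
    }

    ## disconnected decoy cycles (zero flux under parsimonious optima)
    if (bp$nDecoys >= 2) {
      for (k in seq_len(bp$nDecoys - 1L)) {
        a <- sprintf("dmet%02d[c]", k); b <- sprintf("dmet%02d[c]", k + 1L)
        addRxn(sprintf("DECF_%02d", k), structure(c(-1, 1), names = c(a, b)),
               pathway = "decoy")
        addRxn(sprintf("DECB_%02d", k), structure(c(1, -1), names = c(a, b)),
               pathway = "decoy")
      }
    }

    rxns <- do.call(rbind, rows)
    ids <- unique(unlist(lapply(rxns$stoich, names)))
    mets <- data.frame(id = ids, name = .nameOfId(ids),
                       compartment = vapply(ids, .compartmentOfId,
                                            character(1)),
                       formula = NA_character_, stringsAsFactors = FALSE)
    net <- MetabolicNetwork(mets, rxns, objectiveId = "BIO",
                            compartments = union(comps, "e"))
    sensitive <- c("EX_co2", "T_co2", "PS", sns, "BIO", "NPQ")
    truth <- list(
      planted = sns,
      sensitive = sensitive,
      pinned = setdiff(rxns$id, sensitive),
      orphans = orphans,
      decoySpecies = if (bp$nDecoys >= 2)
        sprintf("dmet%02d", seq_len(bp$nDecoys)) else character(),
      pinnedTerminalFlux = pinFlux,
      objectiveCap = bp$lightFlux / bp$photonPerCarbon,
      nMetabolites = nrow(mets), nReactions = nrow(rxns))
    list(network = net, truth = truth, blueprint = bp)
  })
}

#' Generate a reaction catalog and homology-hit table with known verdicts
#'
#' Builds inputs for the complementation pipeline against a synthetic base
#' network (one from [generateNetwork()], whose decoy species and planted
#' orphans are exploited so that none of the added reactions can carry
#' flux or perturb the base network's designed optimum). The catalog
#' contains, by construction: duplicates of base reactions (removed by
#' deduplication), candidates with a novel species (rejected by the
#' reactant filter), genuinely new reactions between decoy species
#' (accepted and placed), producers feeding the planted orphans (accepted,
#' then requiring gap fill), boundary "closer" reactions for a subset of
#' orphans that only the gap filler can reach (their ECs have no hits),
#' plus a weak-evalue hit and a hit EC absent from the catalog. The
#' manifest records the intended verdict of every candidate and the
#' expected count after each pipeline stage.
#'
#' @param base network from [generateNetwork()] (decoys and orphans
#'   required for the corresponding candidate classes).
#' @param seed RNG seed.
#' @param nDuplicates,nNovel,nNew,nOrphanProducers class sizes;
#'   `nOrphanProducers` defaults to every planted orphan, and closers are
#'   supplied for roughly half of them (the rest exercise the sink
#'   fallback).
#' @return list with `catalog`, `hits`, `manifest` (expected verdict per
#'   catalog id and per-stage counts) .
#' @export
generateHomologyInputs <- function(base, seed = 1, nDuplicates = 3,
                                   nNovel = 2, nNew = 3,
                                   nOrphanProducers = NULL) {
  stopifnot(is(base, "MetabolicNetwork"))
  .withSeed(seed, {
    rxn <- base@reactions
    decoys <- sort(unique(speciesName(
      grep("^dmet", base@metabolites$id, value = TRUE))))
    orphanIds <- findDeadEnds(base)
    if (is.null(nOrphanProducers)) nOrphanProducers <- length(orphanIds)
    orphanIds <- orphanIds[seq_len(min(nOrphanProducers, length(orphanIds)))]
    if (nDuplicates > 0 && length(decoys) < 2 && nNew > 0)
      stop("base network needs decoy species for new-reaction candidates")

    cat_rows <- list(); hit_rows <- list(); verdicts <- list()
    ecOf <- function(k) sprintf("%d.%d.%d.%d", 1 + k %% 6, 1 + k %% 9,
                                1 + k %% 7, k)
    addCat <- function(id, ec, equation, pathway, expected, hit = TRUE,
                       evalue = 1e-50) {
      cat_rows[[length(cat_rows) + 1L]] <<- data.frame(
        catalog_id = id, ec = ec, equation = equation, pathway = pathway,
        stringsAsFactors = FALSE)
      verdicts[[length(verdicts) + 1L]] <<- data.frame(
        catalog_id = id, expected = expected, stringsAsFactors = FALSE)
      if (hit)
        hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
          protein_id = paste0("P_", id), ec = ec, evalue = evalue,
          bitscore = 200, stringsAsFactors = FALSE)
    }

    k <- 0L
    ## duplicates of existing internal reactions (generic equations)
    internal <- which(lengths(rxn$stoich) > 1L &
                        vapply(rxn$stoich, function(st)
                          length(unique(speciesName(names(st)))) > 1L,
                          logical(1)))
    for (i in utils::head(internal, nDuplicates)) {
      k <- k + 1L
      st <- rxn$stoich[[i]]
      gen <- tapply(st, speciesName(names(st)), sum)
      gen <- structure(as.numeric(gen), names = names(gen))
      addCat(sprintf("CDUP%02d", k), ecOf(k), formatEquation(gen),
             "duplicated pathway", "duplicate")
    }
    ## candidates with one novel species
    for (j in seq_len(nNovel)) {
      k <- k + 1L
      src <- if (length(decoys)) decoys[1] else
        speciesName(base@metabolites$id[1])
      addCat(sprintf("CNOV%02d", j), ecOf(k),
             paste(src, "->", sprintf("novel_species_%02d", j)),
             "novel pathway", "novel_species")
    }
    ## genuinely new reactions between non-adjacent decoy species
    nNewEff <- 0L
    if (length(decoys) >= 3) {
      pairs <- utils::combn(seq_along(decoys), 2)
      pairs <- pairs[, abs(pairs[1, ] - pairs[2, ]) > 1, drop = FALSE]
      for (j in seq_len(min(nNew, ncol(pairs)))) {
        k <- k + 1L; nNewEff <- nNewEff + 1L
        addCat(sprintf("CNEW%02d", j), ecOf(k),
               paste(decoys[pairs[1, j]], "->", decoys[pairs[2, j]]),
               "decoy metabolism", "added")
      }
    }
    ## producers feeding planted orphans (trigger gap fill), and boundary
    ## closers for about half of them (no hits: reachable only by gap fill)
    nClosers <- 0L
    for (j in seq_along(orphanIds)) {
      k <- k + 1L
      sp <- speciesName(orphanIds[j])
      addCat(sprintf("CORP%02d", j), ecOf(k), paste("photon ->", sp),
             "orphan feed", "added")
      if (j %% 2L == 1L) {
        k <- k + 1L; nClosers <- nClosers + 1L
        addCat(sprintf("CCLO%02d", j), ecOf(k), paste(sp, "->"),
               "boundary", "gap_fill_only", hit = FALSE)
      }
    }
    ## a weak hit (fails the e-value threshold) and an unmatched hit EC
    k <- k + 1L
    addCat("CWEAK01", ecOf(k), paste(decoys[1], "->", decoys[2]),
           "weak evidence", "not_associated", hit = TRUE, evalue = 1e-3)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      protein_id = "P_unmatched", ec = "9.9.9.9", evalue = 1e-80,
      bitscore = 300, stringsAsFactors = FALSE)
    ## a second hit onto the first catalog entry (exercises hit dedup)
    first <- cat_rows[[1]]
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      protein_id = "P_second_hit", ec = first$ec, evalue = 1e-30,
      bitscore = 150, stringsAsFactors = FALSE)

    catalog <- do.call(rbind, cat_rows)
    parsed <- lapply(catalog$equation, parseEquation)
    catalog$stoich <- lapply(parsed, `[[`, "stoich")
    catalog$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
    catalog <- catalog[order(catalog$catalog_id), , drop = FALSE]
    rownames(catalog) <- NULL
    hits <- do.call(rbind, hit_rows)
    verdictTab <- do.call(rbind, verdicts)

    nAssoc <- nDuplicates + nNovel + nNewEff + length(orphanIds)
    manifest <- list(
      verdicts = verdictTab,
      counts = c(associated = as.integer(nAssoc),
                 deduplicated = as.integer(nAssoc - nDuplicates),
                 reactant_filtered = as.integer(nAssoc - nDuplicates -
                                                  nNovel),
                 compartmentalized = as.integer(nNewEff +
                                                  length(orphanIds)),
                 gap_filled = as.integer(nClosers),
                 exchanges_added = as.integer(length(orphanIds) -
                                                nClosers)),
      unmatchedEC = "9.9.9.9")
    list(catalog = catalog, hits = hits, manifest = manifest)
  })
}

#' Generate synthetic thermodynamic inputs
#'
#' A toy group-contribution table and a decomposition covering the decoy
#' species of a synthetic base network (so that directionality calls only
#' touch reactions that cannot carry flux in the designed optimum).
#'
#' @param base network from [generateNetwork()].
#' @param seed RNG seed.
#' @return list with `table` (a [groupContributionTable()]) and
#'   `decomposition` (named list of group counts per metabolite id).
#' @export
generateThermoInputs <- function(base, seed = 1) {
  .withSeed(seed, {
    groups <- structure(round(stats::runif(6, -40, 40), 1),
                        names = sprintf("g%d", 1:6))
    tab <- groupContributionTable(groups, origin = round(stats::runif(1, -10, 10), 1))
    decoyIds <- grep("^dmet", base@metabolites$id, value = TRUE)
    dec <- lapply(decoyIds, function(id) {
      n <- sample(1:3, 1)
      structure(sample(1:3, n, replace = TRUE),
                names = sample(names(groups), n))
    })
    names(dec) <- decoyIds
    list(table = tab, decomposition = dec)
  })
}

#' Generate qPCR fluorescence curves and Ct tables with known truth
#'
#' Simulates SYBR-style amplification: fluorescence
#' `F(c) = baseline + F0 E^c / (1 + F0 E^c / plateau)` with optional
#' multiplicative read noise, and Ct derived from the fixed-threshold
#' crossing of each replicate's curve. Target Ct values are placed so that
#' the efficiency-corrected expression ratio between low and high CO2
#' equals the blueprint's true ratio, with the reference gene flat across
#' conditions. Replicate Ct scatter is Gaussian (default sd 0.15 cycles).
#'
#' @param seed RNG seed.
#' @param genes data.frame with columns `gene`, `true_ratio` (low vs high
#'   CO2), `efficiency` in (1, 2.2].
#' @param reference data.frame with columns `gene`, `efficiency` for the
#'   reference gene(s); default actin at E = 2.
#' @param nReplicates biological replicates per condition.
#' @param ctLow target-gene Ct at low CO2.
#' @param noiseSd Gaussian sd of replicate Ct scatter, cycles.
#' @param curveNoiseCv multiplicative CV of fluorescence readings.
#' @param cycles number of PCR cycles.
#' @param threshold,baseline,plateau curve parameters (arbitrary units).
#' @param meltFailGenes genes receiving one extra replicate flagged as a
#'   melt-curve failure (exercises the discard rule).
#' @return list with `ct` (data.frame: `gene`, `condition`, `replicate`,
#'   `ct`, `efficiency`, `melt_ok`), `curves` (long data.frame: `well`,
#'   `gene`, `condition`, `replicate`, `cycle`, `fluorescence`) and
#'   `truth`.
#' @export
generateQpcr <- function(seed = 1,
                         genes = data.frame(
                           gene = c("CAH1", "CAH5", "LCIA", "GLYK", "GPM2"),
                           true_ratio = c(4, 3, 2.5, 1.8, 0.7),
                           efficiency = c(2, 1.9, 1.8, 2, 1.95),
                           stringsAsFactors = FALSE),
                         reference = data.frame(gene = "ACT", efficiency = 2,
                                                stringsAsFactors = FALSE),
                         nReplicates = 3, ctLow = 20, noiseSd = 0.15,
                         curveNoiseCv = 0, cycles = 40, threshold = 1000,
                         baseline = 100, plateau = 1e5,
                         meltFailGenes = character()) {
  stopifnot(all(genes$efficiency > 1), all(genes$efficiency <= 2.2),
            all(genes$true_ratio > 0))
  .withSeed(seed, {
    thresholdEff <- threshold / (1 - threshold / plateau)
    ctRows <- list(); curveRows <- list()
    emit <- function(gene, E, condition, replicate, ctTrue, meltOk = TRUE) {
      ct <- ctTrue + stats::rnorm(1, 0, noiseSd)
      f0 <- thresholdEff / E^ct
      cyc <- seq_len(cycles)
      f <- baseline + (f0 * E^cyc) / (1 + f0 * E^cyc / plateau)
      if (curveNoiseCv > 0)
        f <- f * exp(stats::rnorm(cycles, 0,
                                  sqrt(log(1 + curveNoiseCv^2))))
      well <- paste(gene, condition, replicate, sep = "_")
      ## Ct reported from the actual threshold crossing of this curve
      above <- which(f - baseline >= threshold)
      ctObs <- if (length(above)) {
        i <- above[1]
        if (i == 1L) cyc[1] else {
          y0 <- log10(f[i - 1L] - baseline); y1 <- log10(f[i] - baseline)
          cyc[i - 1L] + (log10(threshold) - y0) / (y1 - y0)
        }
      } else NA_real_
      ctRows[[length(ctRows) + 1L]] <<- data.frame(
        gene = gene, condition = condition, replicate = replicate,
        ct = ctObs, efficiency = E, melt_ok = meltOk,
        stringsAsFactors = FALSE)
      curveRows[[length(curveRows) + 1L]] <<- data.frame(
        well = well, gene = gene, condition = condition,
        replicate = replicate, cycle = cyc, fluorescence = f,
        stringsAsFactors = FALSE)
    }
    for (g in seq_len(nrow(genes))) {
      E <- genes$efficiency[g]
      ctHigh <- ctLow + log(genes$true_ratio[g]) / log(E)
      for (r in seq_len(nReplicates)) {
        emit(genes$gene[g], E, "low", r, ctLow)
        emit(genes$gene[g], E, "high", r, ctHigh)
      }
      if (genes$gene[g] %in% meltFailGenes)
        emit(genes$gene[g], E, "low", nReplicates + 1L, ctLow,
             meltOk = FALSE)
    }
    for (g in seq_len(nrow(reference))) {
      for (r in seq_len(nReplicates)) {
        emit(reference$gene[g], reference$efficiency[g], "low", r, ctLow)
        emit(reference$gene[g], reference$efficiency[g], "high", r, ctLow)
      }
    }
    list(ct = do.call(rbind, ctRows),
         curves = do.call(rbind, curveRows),
         truth = list(genes = genes, reference = reference,
                      ctLow = ctLow, threshold = threshold,
                      baseline = baseline, plateau = plateau))
  })
}

#' Generate a metabolite intensity table with planted fold changes
#'
#' Emulates a relative-quantification metabolomics experiment: three
#' biological replicates at low CO2 (0.04%) and two at high CO2 (10%),
#' raw intensities proportional to cell count with multiplicative
#' log-normal noise, and planted high-vs-low fold changes including (by
#' default) a more than five-fold accumulating sugar. Planted analytes are
#' given small baseline abundance so that total-ion-content normalization
#' leaves their fold changes nearly intact.
#'
#' @param seed RNG seed.
#' @param nAnalytes total analytes (planted ones included).
#' @param foldChanges named vector of true high/low fold changes; all
#'   other analytes are null (fold change 1).
#' @param cv multiplicative coefficient of variation of intensities.
#' @param nLow,nHigh biological replicates per condition.
#' @param equalCellCounts use identical cell counts in every sample
#'   (making the cell-count step a no-op).
#' @return list with `table` (data.frame: `sample`, `condition`,
#'   `cell_count`, one column per analyte) and `truth`.
#' @export
generateMetabolites <- function(seed = 1, nAnalytes = 20,
                                foldChanges = c(xylose = 5.5, sucrose = 0.4,
                                                glycerate = 2),
                                cv = 0.1, nLow = 3, nHigh = 2,
                                equalCellCounts = FALSE) {
  stopifnot(nAnalytes >= length(foldChanges), nLow >= 2, nHigh >= 2)
  .withSeed(seed, {
    nNull <- nAnalytes - length(foldChanges)
    analytes <- c(names(foldChanges),
                  sprintf("analyte%02d", seq_len(nNull)))
    fc <- c(foldChanges, structure(rep(1, nNull),
                                   names = sprintf("analyte%02d",
                                                   seq_len(nNull))))
    base <- stats::rlnorm(nAnalytes, log(1000), 0.5)
    base[seq_along(foldChanges)] <- base[seq_along(foldChanges)] * 0.2
    names(base) <- analytes
    samples <- c(paste0("low_", seq_len(nLow)),
                 paste0("high_", seq_len(nHigh)))
    condition <- c(rep("low", nLow), rep("high", nHigh))
    cellCount <- if (equalCellCounts) rep(1.5e6, length(samples))
                 else round(stats::runif(length(samples), 1e6, 2e6))
    sdlog <- sqrt(log(1 + cv^2))
    X <- sapply(analytes, function(a) {
      mu <- base[[a]] * ifelse(condition == "high", fc[[a]], 1)
      mu * cellCount / 1.5e6 * stats::rlnorm(length(samples), 0, sdlog)
    })
    tab <- data.frame(sample = samples, condition = condition,
                      cell_count = cellCount, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(X))
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(foldChanges = fc, baseline = base, cv = cv))
  })
}

#' Generate a net-flux vs metabolomics concordance scenario
#'
#' Thirteen metabolites with model-predicted net-flux directions and
#' measured intensities generated so that ten agree in direction and three
#' (glycine, isocitrate and sucrose) disagree, mirroring a reconciliation
#' in which most, but not all, quantified metabolites behave as the flux
#' model predicts. Predictions are synthetic net-flux records; the
#' measurements run through the full normalization and fold-change
#' machinery.
#'
#' @param seed RNG seed.
#' @param cv intensity noise CV (small, so planted directions survive).
#' @return list with `netflux` (as from [netFluxTable()]),
#'   `measurements` (metabolite table), `truth` (expected concordance
#'   counts).
#' @export
synthConcordanceScenario <- function(seed = 1, cv = 0.05) {
  .withSeed(seed, {
    mets <- c("alanine", "glycerate", "xylose", "serine", "proline",
              "asparagine", "lysine", "phenylalanine", "valine", "malate",
              "glycine", "isocitrate", "sucrose")
    discordant <- c("glycine", "isocitrate", "sucrose")
    predUp <- stats::runif(length(mets)) < 0.5      # model: high > low
    names(predUp) <- mets
    measuredUp <- ifelse(mets %in% discordant, !predUp, predUp)
    fcTrue <- structure(ifelse(measuredUp, 2^1.5, 2^-1.5), names = mets)
    gen <- generateMetabolites(seed = seed + 1000L,
                               nAnalytes = length(mets) + 7L,
                               foldChanges = fcTrue, cv = cv)
    netflux <- data.frame(
      metabolite_id = paste0(mets, "[c]"),
      net_flux_low = 1,
      net_flux_high = ifelse(predUp, 2, 0.5),
      stringsAsFactors = FALSE)
    netflux$ratio <- netflux$net_flux_low / netflux$net_flux_high
    netflux$defined <- TRUE
    list(netflux = netflux, measurements = gen$table,
         truth = list(concordant = length(mets) - length(discordant),
                      discordant = length(discordant),
                      predUp = predUp, foldChanges = fcTrue))
  })
}
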