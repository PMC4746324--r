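test_that("the flux variation coefficient matches hand arithmetic", {
  ## sd(1,1,1,1,3) = 0.894427, mean 1.4 -> rho = 0.638876
  expect_equal(fluxVariationCoefficient(c(1, 1, 1, 1, 3)), 0.6389,
               tolerance = 1e-4)
  expect_equal(fluxVariationCoefficient(rep(2, 5)), 0)
  expect_equal(fluxVariationCoefficient(rep(0, 5)), 0)   # eps guard
  expect_error(fluxVariationCoefficient(3), "at least two")
  ## scale invariance: rho(k x) = rho(x) for k != 0 (|mean| denominator)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(5, mean = runif(1, -5, 5), sd = runif(1, 0, 2))
    k <- runif(1, 0.1, 100) * sample(c(-1, 1), 1)
    expect_equal(fluxVariationCoefficient(k * x),
                 fluxVariationCoefficient(x), tolerance = 1e-12)
  }
  expect_gte(fluxVariationCoefficient(rnorm(5)), 0)
})

test_that("sensitivity classification applies an inclusive threshold", {
  flux <- rbind(varying = c(1, 1, 1, 1, 3),
                constant = rep(2, 5),
                silent = rep(0, 5))
  colnames(flux) <- paste0("cond", 1:5)
  se <- makeScanSE(flux)
  rd <- SummarizedExperiment::rowData(se)
  expect_equal(unname(rd$sensitive), c(TRUE, FALSE, FALSE))
  ## threshold equal to an attained rho still flags the row: >= is inclusive
  rhoAttained <- rd["varying", "rho"]
  se2 <- classifySensitive(se, rhoThreshold = rhoAttained)
  expect_true(SummarizedExperiment::rowData(se2)["varying", "sensitive"])
  ## just above the attained value it is no longer flagged
  se3 <- classifySensitive(se, rhoThreshold = rhoAttained + 1e-12)
  expect_false(SummarizedExperiment::rowData(se3)["varying", "sensitive"])
  ## a rho below 0.01 is not sensitive at the default threshold
  flux2 <- rbind(faint = c(1, 1, 1, 1, 1 + 0.02))  # rho ~ 0.0089
  colnames(flux2) <- paste0("cond", 1:5)
  se4 <- makeScanSE(flux2)
  expect_false(SummarizedExperiment::rowData(se4)$sensitive[1])
  expect_lt(SummarizedExperiment::rowData(se4)$rho[1], 0.01)
})

test_that("condition scans recover the planted sensitive set", {
  gen <- generateNetwork(networkBlueprint(seed = 13))
  se <- scanConditions(gen$network, defaultConditions())
  expect_setequal(sensitiveReactions(se), gen$truth$sensitive)
  ## objectives proportional to the CO2 bound (the designed bottleneck)
  obj <- unname(S4Vectors::metadata(se)$objectives)
  expect_equal(obj, defaultConditions()$co2_flux_ub, tolerance = 1e-8)
  ## duplicate condition names rejected
  dup <- defaultConditions()[c(1, 1, 2), ]
  expect_error(scanConditions(gen$network, dup), "duplicate")
  expect_error(scanConditions(gen$network, defaultConditions()[1, ]),
               "at least two")
})

test_that("an infeasible condition aborts naming the condition", {
  ## no photon quench: fixed light cannot be consumed at low CO2
  gen <- generateNetwork(networkBlueprint(seed = 2))
  net <- gen$network
  net@reactions <- net@reactions[net@reactions$id != "NPQ", ]
  expect_error(scanConditions(net, defaultConditions()), "air")
})

test_that("aggregation counts sensitive reactions with full percentages", {
  flux <- rbind(r1 = c(1, 2, 3), r2 = c(2, 4, 6), r3 = c(5, 5, 5),
                r4 = c(1, 3, 9))
  colnames(flux) <- paste0("cond", 1:3)
  se <- makeScanSE(flux,
                   pathway = c("glycolysis", "glycolysis", "tca", NA),
                   compartment = c("m", "m", "c", "h"))
  agg <- aggregateSensitivity(se)
  ## r3 is constant: 3 sensitive reactions, 2 mitochondrial
  expect_equal(agg$compartment$n[agg$compartment$label == "m"], 2L)
  expect_equal(sum(agg$compartment$n), 3L)
  expect_equal(sum(agg$compartment$percent), 100, tolerance = 0.01)
  expect_equal(sum(agg$pathway$percent), 100, tolerance = 0.01)
  ## no sensitive reactions -> empty summaries
  fluxNone <- rbind(r1 = rep(1, 3), r2 = rep(2, 3))
  colnames(fluxNone) <- paste0("cond", 1:3)
  expect_equal(nrow(aggregateSensitivity(makeScanSE(fluxNone))$pathway), 0)
  ## planted pathway bookkeeping from the generator
  gen <- generateNetwork(networkBlueprint(seed = 21))
  se2 <- scanConditions(gen$network, defaultConditions())
  agg2 <- aggregateSensitivity(se2)
  planted <- gen$network@reactions$pathway[
    gen$network@reactions$id %in% gen$truth$sensitive]
  planted[is.na(planted)] <- "unannotated"
  expect_equal(sum(agg2$pathway$n), length(planted))
  for (lb in unique(planted))
    expect_equal(agg2$pathway$n[agg2$pathway$label == lb],
                 sum(planted == lb))
})

test_that("net metabolite flux is the sensitive-row dot product", {
  ## one sensitive producer at flux 3, one sensitive consumer at flux 1
  mets <- data.frame(id = c("X[c]", "M[c]", "Y[c]"), compartment = "c")
  rxns <- data.frame(id = c("Rprod", "Rcons", "Rother"), lb = 0, ub = 10)
  rxns$stoich <- list(c("X[c]" = -1, "M[c]" = 1),
                      c("M[c]" = -1, "Y[c]" = 1),
                      c("X[c]" = -1, "Y[c]" = 1))
  net <- MetabolicNetwork(mets, rxns, objectiveId = "Rprod")
  flux <- rbind(Rprod = c(3, 6), Rcons = c(1, 2), Rother = c(4, 4))
  colnames(flux) <- c("low", "high")
  se <- makeScanSE(flux)   # Rprod, Rcons sensitive; Rother constant
  expect_equal(netMetaboliteFlux(se, net, "M[c]", "low"), 3 - 1)
  expect_equal(netMetaboliteFlux(se, net, "M[c]", "high"), 6 - 2)
  ## mixed coefficients: hand dot product
  rxns$stoich[[1]] <- c("X[c]" = -1, "M[c]" = 2)
  net2 <- MetabolicNetwork(mets, rxns, objectiveId = "Rprod")
  expect_equal(netMetaboliteFlux(se, net2, "M[c]", "low"), 2 * 3 - 1)
  ## metabolite untouched by sensitive reactions -> 0 (all constant)
  fx0 <- rbind(Rprod = c(1, 1), Rcons = c(1, 1), Rother = c(1, 1))
  colnames(fx0) <- c("low", "high")
  seNone <- makeScanSE(fx0)
  expect_equal(netMetaboliteFlux(seNone, net, "M[c]", "low"), 0)
  expect_error(netMetaboliteFlux(se, net, "nope[c]", "low"), "unknown")
  ## total over metabolites equals column sums of S times v (algebraic)
  S <- as.matrix(stoichiometricMatrix(net))
  sens <- sensitiveReactions(se)
  total <- sum(vapply(mets$id, function(m)
    netMetaboliteFlux(se, net, m, "low"), numeric(1)))
  expect_equal(total, sum(colSums(S[, sens]) * flux[sens, "low"]))
})

test_that("low/high flux ratios flag undefined denominators", {
  expect_equal(fluxRatioLowHigh(2, 4)$ratio, 0.5)
  expect_equal(fluxRatioLowHigh(-1, 2)$ratio, -0.5)
  r <- fluxRatioLowHigh(2, 0)
  expect_false(r$defined)
  expect_true(is.na(r$ratio))
  ## table over a scan
  gen <- generateNetwork(networkBlueprint(seed = 9))
  se <- scanConditions(gen$network, defaultConditions())
  smet <- grep("^smet", metaboliteIds(gen$network), value = TRUE)[1]
  nf <- netFluxTable(se, gen$network, c(smet, "ac[c]"))
  expect_equal(nrow(nf), 2)
  ## chain metabolite: net flux zero through the (balanced) sensitive set?
  ## production equals consumption, so net is 0 and low/high both 0
  expect_true(all(c("net_flux_low", "net_flux_high", "ratio", "defined")
                  %in% names(nf)))
  ## ac[c] is untouched by sensitive reactions
  expect_equal(nf$net_flux_low[nf$metabolite_id == "ac[c]"], 0)
})
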