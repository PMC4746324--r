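test_that("equation strings parse and format consistently", {
  p <- parseEquation("2 A[c] + B[c] -> C[m]")
  expect_equal(sort(p$stoich), sort(c("A[c]" = -2, "B[c]" = -1, "C[m]" = 1)))
  expect_false(p$reversible)
  expect_true(parseEquation("A[c] <-> B[c]")$reversible)
  expect_equal(parseEquation("-> co2[e]")$stoich, c("co2[e]" = 1))
  expect_equal(parseEquation("co2[e] ->")$stoich, c("co2[e]" = -1))
  expect_equal(parseEquation("3/2 A[c] -> B[c]")$stoich[["A[c]"]], -1.5)
  expect_error(parseEquation("A[c] B[c]"), "arrow")
  expect_error(parseEquation("->"), "species")
  ## format is inverse of parse (up to species order)
  for (eq in c("2 A[c] + B[c] -> C[m]", "A[c] <-> B[c]", "co2[e] ->")) {
    p <- parseEquation(eq)
    q <- parseEquation(formatEquation(p$stoich, p$reversible))
    expect_equal(sort(p$stoich), sort(q$stoich))
  }
})

test_that("TSV round trip is the identity on valid networks", {
  for (net in list(toyNetwork(), fixtureNetwork45(),
                   generateNetwork(networkBlueprint(seed = 3))$network)) {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeNetwork(net, f)
    net2 <- readNetwork(f)
    expect_equal(net2@metabolites, net@metabolites)
    expect_equal(net2@reactions, net@reactions)
    expect_equal(net2@objectiveId, net@objectiveId)
    expect_setequal(net2@compartments, net@compartments)
  }
})

test_that("reversibility is preserved on disk purely through bounds", {
  net <- fixtureNetwork45()   # T1 is reversible (lb < 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, f)
  lines <- readLines(f)
  expect_true(any(grepl("<->", lines[grepl("^T1\t", lines)])))
  net2 <- readNetwork(f)
  expect_lt(getBounds(net2, "T1")["lb"], 0)
  expect_equal(unname(isReversible(net2)), unname(isReversible(net)))
})

test_that("SBML round trip preserves the network", {
  net <- fixtureNetwork45()
  f <- withr::local_tempfile(fileext = ".xml")
  writeNetwork(net, f)
  net2 <- readNetwork(f)
  expect_equal(net2@reactions$stoich, net@reactions$stoich)
  expect_equal(net2@reactions$lb, net@reactions$lb)
  expect_equal(net2@reactions$ub, net@reactions$ub)
  expect_equal(net2@objectiveId, net@objectiveId)
  expect_equal(net2@metabolites$id, net@metabolites$id)
})

test_that("malformed and inconsistent network files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#! objective\tR1",
               "id\tname\tequation\tlb\tub\tec\tpathway\tgenes",
               "R1\tr1\tA[c] >> B[c]\t0\t10\t\t\t"), f)
  expect_error(readNetwork(f), "parse error")
  writeLines(c("#! objective\tR1",
               "#! met\tA[c]\tA\t",
               "id\tname\tequation\tlb\tub\tec\tpathway\tgenes",
               "R1\tr1\tA[c] -> x_q[c]\t0\t10\t\t\t"), f)
  expect_error(readNetwork(f), "x_q")
  expect_error(readNetwork(tempfile()), "not found")
})

test_that("invalid networks are refused by the validity method", {
  expect_error(MetabolicNetwork(
    data.frame(id = "A[c]", compartment = "c"),
    data.frame(id = character(), stoich = I(list())),
    objectiveId = "BIO"), "no reactions")
  rxns <- data.frame(id = "R1")
  rxns$stoich <- list(c("A[c]" = -1, "ghost[c]" = 1))
  expect_error(MetabolicNetwork(
    data.frame(id = "A[c]", compartment = "c"), rxns,
    objectiveId = "R1"), "ghost")
  rxns2 <- data.frame(id = "R1", lb = 5, ub = 1)
  rxns2$stoich <- list(c("A[c]" = -1))
  expect_error(MetabolicNetwork(
    data.frame(id = "A[c]", compartment = "c"), rxns2,
    objectiveId = "R1"), "lb > ub")
})

test_that("stoichiometric matrix matches a hand transcription", {
  S <- stoichiometricMatrix(fixtureNetwork45())
  expect_equal(as.matrix(S), stoichMatrix45())
  ## nonzero count equals the summed stoichiometry sizes
  net <- generateNetwork(networkBlueprint(seed = 11))$network
  S2 <- stoichiometricMatrix(net)
  expect_equal(Matrix::nnzero(S2), sum(lengths(net@reactions$stoich)))
  ## single-metabolite exchange -> single nonzero column
  expect_equal(Matrix::nnzero(stoichiometricMatrix(toyNetwork())[, "EX_A"]),
               1)
})

test_that("dead-end detection accounts for reversibility and bounds", {
  mets <- data.frame(id = c("A[c]", "B[c]"), compartment = "c")
  rxns <- data.frame(id = c("EX_A", "R1"), lb = 0, ub = 10)
  rxns$stoich <- list(c("A[c]" = 1), c("A[c]" = -1, "B[c]" = 1))
  net <- MetabolicNetwork(mets, rxns, objectiveId = "R1")
  expect_equal(findDeadEnds(net), "B[c]")
  ## a reversible conversion supplies both roles
  rxns$lb <- c(-10, -10)
  net2 <- MetabolicNetwork(mets, rxns, objectiveId = "R1")
  expect_equal(findDeadEnds(net2), character(0))
  ## planted orphans are recovered exactly, sorted
  gen <- generateNetwork(networkBlueprint(nOrphans = 2, seed = 5))
  expect_equal(findDeadEnds(gen$network), sort(gen$truth$orphans))
  ## fully connected networks have none
  expect_equal(findDeadEnds(toyNetwork()), character(0))
})

test_that("condition bounds pin light and cap CO2 uptake only", {
  gen <- generateNetwork(networkBlueprint(seed = 2))
  cond <- defaultConditions()[1, ]
  net <- setConditionBounds(gen$network, cond)
  expect_equal(unname(getBounds(net, "EX_photon")), c(57.54, 57.54))
  expect_equal(unname(getBounds(net, "EX_co2")["ub"]), 0.04)
  ## everything else untouched
  changed <- net@reactions$lb != gen$network@reactions$lb |
    net@reactions$ub != gen$network@reactions$ub
  expect_lte(sum(changed), 2)
  ## idempotent
  expect_equal(setConditionBounds(net, cond), net)
  ## zero CO2 forces zero uptake
  cond0 <- cond; cond0$co2_flux_ub <- 0
  expect_equal(unname(getBounds(setConditionBounds(net, cond0),
                                "EX_co2")["ub"]), 0)
  expect_error(setConditionBounds(toyNetwork(), cond), "configuration")
})

test_that("default conditions follow the five-level CO2 design", {
  cond <- defaultConditions()
  expect_equal(cond$co2_percent, c(0.04, 2.5, 5, 8, 10))
  expect_equal(cond$light_flux, rep(57.54, 5))
  expect_equal(cond$name[1], "air")
  expect_error(suppressWarnings(readConditions(tempfile())))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeConditions(cond, f)
  expect_equal(readConditions(f), cond)
})
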