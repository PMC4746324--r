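## small hand-written catalog: one EC with two reactions (a kinase acting
## on two acceptors), plus assorted candidates
handCatalog <- function() {
  cat <- data.frame(
    catalog_id = c("K001", "K002", "N001", "D001"),
    ec = c("2.7.1.31", "2.7.1.31", "1.1.1.1", "4.1.2.13"),
    equation = c("glycerate + atp -> pga + adp",
                 "glycerate + gtp -> pga + gdp",
                 "ethanol -> acetaldehyde",
                 "fdp -> dhap + g3p"),
    pathway = c("glyoxylate metabolism", "glyoxylate metabolism",
                "pyruvate metabolism", "glycolysis"),
    stringsAsFactors = FALSE)
  parsed <- lapply(cat$equation, parseEquation)
  cat$stoich <- lapply(parsed, `[[`, "stoich")
  cat$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  cat
}

test_that("homology hits pull every catalog reaction under their EC", {
  hits <- data.frame(protein_id = "GLYK", ec = "2.7.1.31",
                     evalue = 1e-60, bitscore = 400)
  cands <- associateReactions(hits, handCatalog())
  expect_equal(cands$catalog_id, c("K001", "K002"))  # 2 reactions, one EC
  expect_true(all(vapply(cands$verdicts, function(v)
    v[["associate"]] == "pass", logical(1))))
  ## two hits on the same reaction collapse to one candidate
  hits2 <- rbind(hits, data.frame(protein_id = "GLYK2", ec = "2.7.1.31",
                                  evalue = 1e-30, bitscore = 200))
  expect_equal(nrow(associateReactions(hits2, handCatalog())), 2)
  expect_equal(associateReactions(hits2, handCatalog())$genes[1],
               "GLYK;GLYK2")
  ## empty hit list, weak hits, unmatched ECs
  expect_equal(nrow(associateReactions(hits[0, ], handCatalog())), 0)
  weak <- transform(hits, evalue = 1e-3)
  expect_equal(nrow(associateReactions(weak, handCatalog())), 0)
  odd <- data.frame(protein_id = "X", ec = "9.9.9.9", evalue = 0,
                    bitscore = 1)
  expect_equal(attr(associateReactions(odd, handCatalog()), "unmatchedEC"),
               "9.9.9.9")
})

test_that("EC dash wildcards match on either side", {
  hits <- data.frame(protein_id = "P1", ec = "2.7.1.-", evalue = 0,
                     bitscore = 1)
  expect_equal(associateReactions(hits, handCatalog())$catalog_id,
               c("K001", "K002"))
  expect_error(readHomologyHits(withr::local_tempfile(
    lines = "protein_id\tec\nP1\tnot-an-ec")), "malformed EC")
})

test_that("deduplication is orientation-insensitive for reversibles", {
  mets <- data.frame(id = c("A[c]", "B[c]", "C[c]"), compartment = "c")
  rxns <- data.frame(id = c("R1", "R2"), lb = c(0, -10), ub = 10)
  rxns$stoich <- list(c("A[c]" = -1, "B[c]" = 1),
                      c("B[c]" = -1, "C[c]" = 1))   # R2 reversible
  base <- MetabolicNetwork(mets, rxns, objectiveId = "R1")
  cat <- data.frame(catalog_id = c("C1", "C2", "C3"),
                    ec = "1.1.1.1", pathway = "p",
                    equation = c("A -> B",      # duplicate of R1
                                 "C -> B",      # reverse of reversible R2
                                 "2 A -> B"))   # coefficient differs: kept
  parsed <- lapply(cat$equation, parseEquation)
  cat$stoich <- lapply(parsed, `[[`, "stoich")
  cat$reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  cat$genes <- ""
  cat$verdicts <- rep(list(c(associate = "pass")), 3)
  out <- dedupeAgainstBase(cat, base)
  expect_equal(out$catalog_id, "C3")
  removed <- attr(out, "removed")
  expect_setequal(removed$catalog_id, c("C1", "C2"))
})

test_that("the reactant filter names the offending species", {
  base <- toyNetwork()   # species A, B
  cat <- data.frame(catalog_id = c("C1", "C2", "C3"),
                    ec = "1.1.1.1", pathway = "p",
                    equation = c("A -> B", "A -> mystery", "ghost -> wraith"))
  parsed <- lapply(cat$equation, parseEquation)
  cat$stoich <- lapply(parsed, `[[`, "stoich")
  cat$reversible <- FALSE
  cat$genes <- ""
  cat$verdicts <- rep(list(c(associate = "pass")), 3)
  out <- filterKnownReactants(cat, base)
  expect_equal(out$catalog_id, "C1")
  removed <- attr(out, "removed")
  expect_match(removed$verdicts[[1]][["reactants"]], "mystery")
  expect_match(removed$verdicts[[2]][["reactants"]], "ghost")
  ## generic-name blacklist fails candidates outright
  out2 <- filterKnownReactants(cat[1, ], base, genericBlacklist = "A")
  expect_equal(nrow(out2), 0)
})

test_that("compartment placement emits one reaction per viable compartment", {
  mets <- data.frame(id = c("A[c]", "B[c]", "A[h]", "B[h]", "C[m]"),
                     compartment = c("c", "c", "h", "h", "m"))
  rxns <- data.frame(id = "R0", lb = 0, ub = 10)
  rxns$stoich <- list(c("A[c]" = -1, "B[c]" = 1))
  base <- MetabolicNetwork(mets, rxns, objectiveId = "R0")
  cat <- data.frame(catalog_id = c("P1", "P2", "P3"), ec = "1.1.1.1",
                    pathway = "p",
                    equation = c("A -> B",    # viable in c and h
                                 "C -> C",    # only m (degenerate but legal)
                                 "A + C -> B"))  # split: no common one
  cat$stoich <- list(c(A = -1, B = 1), c(C = -1, C2 = 1)[1],
                     c(A = -1, C = -1, B = 1))
  cat$stoich[[2]] <- c(C = -1)
  cat$reversible <- FALSE
  cat$genes <- ""
  cat$verdicts <- rep(list(c(associate = "pass")), 3)
  placed <- compartmentalize(cat, base)
  expect_setequal(placed$reactions$id[placed$reactions$catalog_id == "P1"],
                  c("P1_c", "P1_h"))
  expect_equal(placed$reactions$id[placed$reactions$catalog_id == "P2"],
               "P2_m")
  expect_match(placed$candidates$verdicts[[3]][["compartmentalize"]],
               "no viable compartment")
  ## species get the compartment tag of their placement
  st <- placed$reactions$stoich[[which(placed$reactions$id == "P1_h")]]
  expect_setequal(names(st), c("A[h]", "B[h]"))
})

test_that("gap filling prefers a shortest catalog path over a sink", {
  ## orphan product B; the catalog holds a one-step consumer B -> C
  mets <- data.frame(id = c("A[c]", "B[c]", "C[c]"), compartment = "c")
  rxns <- data.frame(id = c("EX_A", "R1", "R2"), lb = 0, ub = 10)
  rxns$stoich <- list(c("A[c]" = 1), c("A[c]" = -1, "B[c]" = 1),
                      c("C[c]" = -1))
  net <- MetabolicNetwork(mets, rxns, objectiveId = "R1")
  expect_equal(findDeadEnds(net), c("B[c]", "C[c]"))
  cat <- data.frame(catalog_id = c("G1", "G2"), ec = "1.1.1.1",
                    pathway = "p",
                    equation = c("B -> C", "B -> unknown_species"))
  parsed <- lapply(cat$equation, parseEquation)
  cat$stoich <- lapply(parsed, `[[`, "stoich")
  cat$reversible <- FALSE
  gf <- gapFill(net, cat)
  expect_equal(gf$added$source, "G1")
  expect_equal(findDeadEnds(gf$network), character(0))
  ## without a viable consumer, sinks are the guaranteed fallback
  ## (C, produced by nothing once G1 is unavailable, gets a source too)
  gf2 <- gapFill(net, cat[2, ])
  expect_true(all(gf2$added$source == "sink"))
  expect_setequal(gf2$added$id, c("SK_B[c]", "SK_C[c]"))
  expect_equal(findDeadEnds(gf2$network), character(0))
  ## no dead ends: untouched network
  gf3 <- gapFill(toyNetwork(), cat)
  expect_equal(nrow(gf3$added), 0)
  expect_equal(gf3$network@reactions, toyNetwork()@reactions)
})

test_that("full complementation reproduces the generator manifest", {
  for (seed in c(7, 19, 42)) {
    gen <- generateNetwork(networkBlueprint(seed = seed))
    hom <- generateHomologyInputs(gen$network, seed = seed + 1)
    rep <- complementNetwork(gen$network, hom$hits, hom$catalog)
    expect_equal(rep$counts, hom$manifest$counts,
                 info = paste("seed", seed))
    expect_equal(rep$unmatchedEC, hom$manifest$unmatchedEC)
    ## stage counts are non-increasing through dedup and reactant filter
    expect_true(rep$counts["associated"] >= rep$counts["deduplicated"])
    expect_true(rep$counts["deduplicated"] >=
                  rep$counts["reactant_filtered"])
    ## no dead ends among species touched by added reactions
    addedStoich <- rep$network@reactions$stoich[
      rep$network@reactions$id %in% rep$added$id]
    touched <- unique(unlist(lapply(addedStoich, names)))
    expect_length(intersect(findDeadEnds(rep$network), touched), 0)
    ## every added reaction traces to a catalog id or a synthetic sink
    expect_true(all(rep$added$source %in%
                      c(hom$catalog$catalog_id, "sink")))
  }
})

test_that("complementation is deterministic", {
  gen <- generateNetwork(networkBlueprint(seed = 3))
  hom <- generateHomologyInputs(gen$network, seed = 4)
  r1 <- complementNetwork(gen$network, hom$hits, hom$catalog)
  r2 <- complementNetwork(gen$network, hom$hits, hom$catalog)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(r1$network, f1); writeNetwork(r2$network, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pathway blacklist rejects implausible routes", {
  hits <- data.frame(protein_id = "P", ec = "4.1.2.13", evalue = 0,
                     bitscore = 10)
  base <- toyNetwork()
  rep <- complementNetwork(base, hits, handCatalog(),
                           pathwayBlacklist = "glycolysis")
  expect_equal(unname(rep$counts["associated"]), 1L)
  expect_equal(unname(rep$counts["deduplicated"]), 0L)
})
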