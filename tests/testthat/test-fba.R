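test_that("LP assembly mirrors the network", {
  net <- fixtureNetwork45()
  lp <- assembleLP(net)
  expect_equal(as.matrix(lp@S), stoichMatrix45())
  expect_equal(sum(lp@objective != 0), 1)
  expect_equal(which(lp@objective == 1), 5L)   # biomass column
  expect_equal(lp@lower, net@reactions$lb)
  expect_equal(lp@upper, net@reactions$ub)
  ## reversible reactions are exactly the negative lower bounds
  expect_equal(sum(lp@lower < 0), sum(isReversible(net)))
  badNet <- net
  expect_error({objectiveId(badNet) <- "nope"}, "not in the network")
})

test_that("single-bottleneck chains solve to their closed form", {
  expect_equal(objectiveValue(solveFBA(assembleLP(toyNetwork(ub = 10)))), 10,
               tolerance = 1e-9)
  expect_equal(objectiveValue(solveFBA(assembleLP(toyNetwork(ub = 0)))), 0,
               tolerance = 1e-12)
  ## fixture: 10 A -> 5 B -> 5 C -> 15 D -> biomass 15
  sol <- solveFBA(assembleLP(fixtureNetwork45()))
  expect_equal(objectiveValue(sol), 15, tolerance = 1e-9)
  expect_equal(max(abs(as.vector(
    stoichiometricMatrix(fixtureNetwork45()) %*% fluxes(sol)))), 0,
    tolerance = 1e-6)
})

test_that("solver agrees with exhaustive vertex enumeration", {
  for (seed in 1:30) {
    lp <- randomSmallLP(seed)
    oracle <- bruteForceLP(lp)
    sol <- solveFBA(lp)
    expect_equal(solutionStatus(sol), "optimal", info = paste("seed", seed))
    expect_equal(objectiveValue(sol), oracle$value, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
  ## infeasible problems are reported, never silently solved
  for (seed in 1:5) {
    lp <- randomSmallLP(seed, forceInfeasible = TRUE)
    oracle <- bruteForceLP(lp)
    sol <- solveFBA(lp)
    expect_equal(solutionStatus(sol) == "optimal", oracle$feasible,
                 info = paste("seed", seed))
  }
})

test_that("solver agrees with an independent LP implementation", {
  skip_if_not_installed("pracma")
  for (seed in c(2, 9, 17, 23)) {
    lp <- randomSmallLP(seed)
    n <- ncol(lp@S)
    ## shifted variables x = v - lb >= 0 for the external solver
    ref <- pracma::linprog(cc = lp@objective, A = diag(n),
                           b = lp@upper - lp@lower,
                           Aeq = as.matrix(lp@S),
                           beq = -as.vector(as.matrix(lp@S) %*% lp@lower),
                           maximize = TRUE, maxiter = 10000)
    if (ref$errno != 1) next
    sol <- solveFBA(lp)
    expect_equal(objectiveValue(sol),
                 ref$fval + sum(lp@objective * lp@lower),
                 tolerance = 1e-7, info = paste("seed", seed))
  }
})

test_that("parsimonious stage minimizes total absolute flux among optima", {
  ## two equivalent parallel routes: flux concentrates on one of them
  lp <- assembleLP(parallelRoutesNetwork())
  sol <- solveParsimonious(lp)
  expect_equal(objectiveValue(sol), 4, tolerance = 1e-9)
  v <- fluxes(sol)
  expect_equal(sum(abs(v)), 12, tolerance = 1e-9)  # 4 + 4 + 0 + 4
  expect_equal(min(v[c("Ra", "Rb")]), 0, tolerance = 1e-9)
  ## matches the enumeration-over-optima oracle on random instances
  for (seed in c(1, 4, 7, 12, 19)) {
    lp <- randomSmallLP(seed)
    oracle <- bruteForceParsimonious(lp)
    sol <- solveParsimonious(lp)
    expect_equal(sum(abs(fluxes(sol))), oracle$minTotalFlux,
                 tolerance = 1e-7, info = paste("seed", seed))
    expect_equal(objectiveValue(sol), oracle$value, tolerance = 1e-9)
  }
  ## non-degenerate problems: both stages give the same vector
  lpChain <- assembleLP(fixtureNetwork45())
  expect_equal(fluxes(solveParsimonious(lpChain)),
               fluxes(solveFBA(lpChain)), tolerance = 1e-8)
  ## the all-zero optimum survives unchanged
  lp0 <- assembleLP(toyNetwork(ub = 0))
  expect_equal(unname(fluxes(solveParsimonious(lp0))), rep(0, 3),
               tolerance = 1e-12)
})

test_that("duplicating a reaction column never changes the optimum", {
  for (seed in c(3, 8, 21)) {
    gen <- generateNetwork(networkBlueprint(seed = seed))
    net <- gen$network
    base <- objectiveValue(solveFBA(assembleLP(net)))
    pick <- net@reactions[match("PS", net@reactions$id), ]
    pick$id <- "PS_copy"
    net2 <- addReactions(net, pick)
    expect_equal(objectiveValue(solveFBA(assembleLP(net2))), base,
                 tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("biomass is non-decreasing and concave in the CO2 bound", {
  gen <- generateNetwork(networkBlueprint(seed = 6))
  grid <- seq(0, 40, length.out = 20)
  obj <- vapply(grid, function(u) {
    net <- setBounds(gen$network, "EX_co2", ub = u)
    objectiveValue(solveFBA(assembleLP(net)))
  }, numeric(1))
  expect_true(all(diff(obj) >= -1e-9))
  ## concave piecewise-linear: increments non-increasing
  expect_true(all(diff(diff(obj)) <= 1e-7))
  ## saturates at the light-limited cap
  expect_equal(max(obj), gen$truth$objectiveCap, tolerance = 1e-6)
})

test_that("infeasible and degenerate-bound networks are reported", {
  ## pinned uptake with no outlet cannot reach steady state
  mets <- data.frame(id = c("A[c]", "B[c]"), compartment = "c")
  rxns <- data.frame(id = c("EX_A", "R1", "BIO"),
                     lb = c(2, 0, 0), ub = c(2, 10, 0))
  rxns$stoich <- list(c("A[c]" = 1), c("A[c]" = -1, "B[c]" = 1),
                      c("B[c]" = -1))
  net <- MetabolicNetwork(mets, rxns, objectiveId = "BIO")
  expect_equal(solutionStatus(solveFBA(assembleLP(net))), "infeasible")
})
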