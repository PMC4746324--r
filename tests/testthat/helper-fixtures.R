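## Shared fixtures and independent oracles, built in code.

## 4 metabolites x 5 reactions, transcribed by hand below in stoichMatrix45
fixtureNetwork45 <- function() {
  mets <- data.frame(
    id = c("A[c]", "B[c]", "C[h]", "D[h]"),
    compartment = c("c", "c", "h", "h"))
  rxns <- data.frame(id = c("EX_A", "R1", "T1", "R2", "BIO"),
                     lb = c(0, 0, -1000, 0, 0),
                     ub = c(10, 1000, 1000, 1000, 1000))
  rxns$stoich <- list(
    c("A[c]" = 1),
    c("A[c]" = -2, "B[c]" = 1),
    c("B[c]" = -1, "C[h]" = 1),
    c("C[h]" = -1, "D[h]" = 3),
    c("D[h]" = -1))
  MetabolicNetwork(mets, rxns, objectiveId = "BIO")
}

## hand transcription of the fixture above
stoichMatrix45 <- function() {
  m <- matrix(0, 4, 5,
              dimnames = list(c("A[c]", "B[c]", "C[h]", "D[h]"),
                              c("EX_A", "R1", "T1", "R2", "BIO")))
  m["A[c]", "EX_A"] <- 1
  m["A[c]", "R1"] <- -2; m["B[c]", "R1"] <- 1
  m["B[c]", "T1"] <- -1; m["C[h]", "T1"] <- 1
  m["C[h]", "R2"] <- -1; m["D[h]", "R2"] <- 3
  m["D[h]", "BIO"] <- -1
  m
}

## two equivalent parallel routes A -> B; parsimonious optimum uses one
parallelRoutesNetwork <- function() {
  mets <- data.frame(id = c("A[c]", "B[c]"), compartment = "c")
  rxns <- data.frame(id = c("EX_A", "Ra", "Rb", "BIO"),
                     lb = 0, ub = c(4, 1000, 1000, 1000))
  rxns$stoich <- list(c("A[c]" = 1),
                      c("A[c]" = -1, "B[c]" = 1),
                      c("A[c]" = -1, "B[c]" = 1),
                      c("B[c]" = -1))
  MetabolicNetwork(mets, rxns, objectiveId = "BIO")
}

## random small LP over a random stoichiometric matrix; always feasible at
## v = 0 unless forceInfeasible plants a strictly positive lower bound on a
## reaction that cannot carry flux
randomSmallLP <- function(seed, forceInfeasible = FALSE) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(2:4, 1)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    k <- sample(1:min(2, m), 1)
    rows <- sample(m, k)
    S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  lb <- ifelse(runif(n) < 0.3, -round(runif(n, 1, 10), 1), 0)
  ub <- round(runif(n, 1, 10), 1)
  if (forceInfeasible) {
    j <- sample(n, 1)
    S[, j] <- 0; S[1, j] <- 1          # sole producer of metabolite 1
    S[1, -j][S[1, -j] > 0] <- 0        # nobody else produces it
    keep <- S[1, ] < 0
    S[1, keep] <- 0                    # ... and nobody consumes it
    lb[j] <- 1; ub[j] <- max(ub[j], 2) # yet it must run
  }
  obj <- numeric(n)
  obj[sample(n, 1)] <- 1
  dimnames(S) <- list(paste0("m", seq_len(m)), paste0("r", seq_len(n)))
  new("LPProblem", S = Matrix::Matrix(S, sparse = TRUE), objective = obj,
      lower = lb, upper = ub)
}

## minimal total |v| over the optimal face, by exhaustive enumeration.
## The minimizer of a piecewise-linear objective can sit on a sign-change
## plane (v_j = 0) rather than an original vertex, so nonbasic variables
## take values from {lb, 0, ub} and the biomass row is fixed at its
## optimum.
bruteForceParsimonious <- function(lp, tol = 1e-7) {
  first <- bruteForceLP(lp)
  if (!first$feasible) return(NULL)
  zstar <- first$value
  A <- rbind(as.matrix(lp@S), lp@objective)
  b <- c(rep(0, nrow(lp@S)), zstar)
  n <- ncol(A)
  r <- qr(A)$rank
  lb <- lp@lower; ub <- lp@upper
  best <- Inf; bestx <- NULL
  subsets <- if (r == 0L) list(integer()) else combn(n, r, simplify = FALSE)
  for (J in subsets) {
    AJ <- A[, J, drop = FALSE]
    if (r > 0L && qr(AJ)$rank < r) next
    N <- setdiff(seq_len(n), J)
    vals <- lapply(N, function(j)
      unique(c(lb[j], ub[j], if (lb[j] < 0 && ub[j] > 0) 0)))
    grid <- if (length(N)) expand.grid(vals) else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(N)) x[N] <- as.numeric(grid[g, ])
      xJ <- tryCatch(qr.solve(AJ, b - A[, N, drop = FALSE] %*% x[N]),
                     error = function(e) NULL)
      if (is.null(xJ)) next
      x[J] <- xJ
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      tot <- sum(abs(x))
      if (tot < best) { best <- tot; bestx <- x }
    }
  }
  list(value = zstar, minTotalFlux = best, x = bestx)
}

## build a sensitivity SummarizedExperiment directly from a flux matrix
makeScanSE <- function(flux, pathway = NULL, compartment = NULL,
                       rhoThreshold = 0.01) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(flux = flux),
    rowData = S4Vectors::DataFrame(
      pathway = pathway %||% rep("unannotated", nrow(flux)),
      compartment = compartment %||% rep("c", nrow(flux)),
      row.names = rownames(flux)))
  classifySensitive(se, rhoThreshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
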