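#' Assemble the flux balance linear program
#'
#' Builds the LP `max c'v  s.t.  S v = 0, LB <= v <= UB` from a network:
#' `S` is the stoichiometric matrix, the objective vector is all zeros with
#' a single 1 at the biomass (objective) reaction, and the bound vectors
#' come straight from the reaction table.
#'
#' @param net a [MetabolicNetwork-class] with a valid objective reaction.
#' @return an [LPProblem-class].
#' @examples
#' lp <- assembleLP(toyNetwork())
#' lp
#' @export
assembleLP <- function(net) {
  stopifnot(is(net, "MetabolicNetwork"))
  validObject(net)
  S <- stoichiometricMatrix(net)
  obj <- as.numeric(colnames(S) == net@objectiveId)
  if (sum(obj) != 1L)
    stop("objective reaction '", net@objectiveId, "' not found")
  new("LPProblem", S = S, objective = obj,
      lower = net@reactions$lb, upper = net@reactions$ub)
}

setMethod("show", "LPProblem", function(object) {
  cat("LPProblem:", nrow(object@S), "mass-balance rows x", ncol(object@S),
      "reactions; objective at",
      colnames(object@S)[object@objective != 0], "\n")
})

#' Solve the flux balance LP
#'
#' `solveFBA` maximizes the biomass flux subject to steady-state mass
#' balance and flux bounds. `solveParsimonious` resolves degeneracy: among
#' the alternate optima of the biomass LP it returns the flux vector of
#' minimal total absolute flux (sum of |v|) with the biomass flux pinned at
#' its maximum. Because alternate optima are ubiquitous in genome-scale
#' models, all downstream sensitivity statistics use the parsimonious
#' vector, which is unique up to solver determinism and makes repeated runs
#' bit-identical.
#'
#' Solutions satisfy `max |S v| <= 1e-6` and `LB - 1e-9 <= v <= UB + 1e-9`;
#' infeasibility and unboundedness are reported through the `status` slot,
#' never silently.
#'
#' @param lp an [LPProblem-class] (see [assembleLP()]).
#' @param tol pivot tolerance of the simplex solver.
#' @return a [FluxSolution-class].
#' @examples
#' sol <- solveFBA(assembleLP(toyNetwork()))
#' objectiveValue(sol)
#' @seealso [solveNetwork()] for the one-call convenience wrapper.
#' @export
solveFBA <- function(lp, tol = 1e-9) {
  stopifnot(is(lp, "LPProblem"))
  res <- .boundedSimplex(lp@objective, as.matrix(lp@S),
                         b = rep(0, nrow(lp@S)),
                         lb = lp@lower, ub = lp@upper,
                         maximize = TRUE, tol = tol)
  .asFluxSolution(res, lp)
}

.asFluxSolution <- function(res, lp) {
  if (res$status != "optimal")
    return(new("FluxSolution", fluxes = numeric(), objective = NA_real_,
               status = res$status))
  v <- structure(res$x, names = colnames(lp@S))
  resid <- max(abs(as.vector(lp@S %*% v)))
  if (resid > 1e-6)
    stop("flux solution violates steady state: max |Sv| = ", resid)
  if (any(v < lp@lower - 1e-9) || any(v > lp@upper + 1e-9))
    stop("flux solution violates bounds")
  new("FluxSolution", fluxes = v, objective = res$value, status = "optimal")
}

#' @rdname solveFBA
#' @param solution optional [FluxSolution-class] from `solveFBA(lp)`; when
#'   omitted the first stage is solved internally.
#' @export
solveParsimonious <- function(lp, solution = NULL, tol = 1e-9) {
  stopifnot(is(lp, "LPProblem"))
  if (is.null(solution)) solution <- solveFBA(lp, tol = tol)
  if (solution@status != "optimal") return(solution)
  zstar <- solution@objective

  S <- as.matrix(lp@S)
  m <- nrow(S); n <- ncol(S)
  lb <- lp@lower; ub <- lp@upper
  rev <- which(lb < 0)
  fwd <- setdiff(seq_len(n), rev)

  ## v_j = p_j - q_j for reversible columns; |v| = p + q at the optimum
  A <- cbind(S[, fwd, drop = FALSE], S[, rev, drop = FALSE],
             -S[, rev, drop = FALSE])
  A <- rbind(A, c(lp@objective[fwd], lp@objective[rev], -lp@objective[rev]))
  b <- c(rep(0, m), zstar)
  lbx <- c(lb[fwd], pmax(lb[rev], 0), pmax(-ub[rev], 0))
  ubx <- c(ub[fwd], pmax(ub[rev], 0), pmax(-lb[rev], 0))
  cost <- rep(1, length(lbx))

  res <- .boundedSimplex(cost, A, b, lbx, ubx, maximize = FALSE, tol = tol)
  if (res$status != "optimal")
    stop("parsimonious stage failed with status ", res$status)
  v <- numeric(n)
  v[fwd] <- res$x[seq_along(fwd)]
  nf <- length(fwd); nr <- length(rev)
  v[rev] <- res$x[nf + seq_len(nr)] - res$x[nf + nr + seq_len(nr)]
  .asFluxSolution(list(status = "optimal", x = v, value = zstar), lp)
}

#' Solve a network's FBA problem in one call
#'
#' Assembles the LP and solves it; by default the parsimonious
#' (minimal-total-flux) optimum is returned, which is the vector the
#' sensitivity scan consumes.
#'
#' @param net a [MetabolicNetwork-class].
#' @param parsimonious return the minimal-total-flux optimum (default) or
#'   the raw first-stage vertex.
#' @return a [FluxSolution-class].
#' @examples
#' solveNetwork(toyNetwork())
#' @export
solveNetwork <- function(net, parsimonious = TRUE) {
  lp <- assembleLP(net)
  sol <- solveFBA(lp)
  if (parsimonious && sol@status == "optimal") solveParsimonious(lp, sol)
  else sol
}

#' @rdname FluxSolution-class
#' @export
setMethod("fluxes", "FluxSolution", function(x) x@fluxes)

#' @rdname FluxSolution-class
#' @export
setMethod("objectiveValue", "FluxSolution", function(x) x@objective)

#' @rdname FluxSolution-class
#' @export
setMethod("solutionStatus", "FluxSolution", function(x) x@status)

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@status, ")", sep = "")
  if (object@status == "optimal")
    cat(": objective =", format(object@objective, digits = 6),
        "; ", sum(abs(object@fluxes) > 1e-9), "of", length(object@fluxes),
        "reactions carry flux")
  cat("\n")
})

#' Exhaustive reference solution of a small flux LP
#'
#' Enumerates every basic feasible solution (vertex) of the LP by choosing
#' all column subsets that can form a basis and placing the remaining
#' variables at each combination of their bounds. Intended as an
#' independent reference for problems with at most ~10 reactions; cost
#' grows combinatorially.
#'
#' @param lp an [LPProblem-class].
#' @param tol feasibility tolerance.
#' @return list with `value` (maximal objective, `-Inf` if infeasible),
#'   `x` (an optimal vertex) and `feasible`.
#' @examples
#' bruteForceLP(assembleLP(toyNetwork()))$value
#' @export
bruteForceLP <- function(lp, tol = 1e-7) {
  stopifnot(is(lp, "LPProblem"))
  A <- as.matrix(lp@S)
  n <- ncol(A)
  if (n > 12L) stop("bruteForceLP is for small problems (<= 12 reactions)")
  lb <- lp@lower; ub <- lp@upper; obj <- lp@objective
  r <- qr(A)$rank
  best <- -Inf; bestx <- NULL; feasible <- FALSE
  subsets <- if (r == 0L) list(integer()) else
    utils::combn(n, r, simplify = FALSE)
  for (J in subsets) {
    AJ <- A[, J, drop = FALSE]
    if (r > 0L && qr(AJ)$rank < r) next
    N <- setdiff(seq_len(n), J)
    grid <- if (length(N)) expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
            else data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(N)) {
        atUb <- as.logical(grid[g, ])
        x[N] <- ifelse(atUb, ub[N], lb[N])
        if (any(!is.finite(x[N]))) next
      }
      rhs <- -A[, N, drop = FALSE] %*% x[N]
      xJ <- tryCatch(qr.solve(AJ, rhs), error = function(e) NULL)
      if (is.null(xJ)) next
      x[J] <- xJ
      if (max(abs(A %*% x)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      feasible <- TRUE
      val <- sum(obj * x)
      if (val > best) { best <- val; bestx <- x }
    }
  }
  list(value = best, x = bestx, feasible = feasible)
}
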