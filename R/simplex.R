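## Dense bounded-variable two-phase primal simplex.
##
## Solves   max  c'x   s.t.  A x = b,  lb <= x <= ub
## with finite or infinite bounds. Deterministic: Dantzig pricing with ties
## broken at the smallest column index, switching permanently to Bland's
## rule after a run of degenerate (non-improving) iterations, so the solver
## cannot cycle and identical inputs give identical vertices.
##
## Written in-package rather than taken from an external LP package: the
## flux balance program is the core computation here, so a solver whose
## pivoting policy and tolerances are under our control (and cross-checked
## against exhaustive vertex enumeration in the test suite) is preferred.

.boundedSimplex <- function(obj, A, b, lb, ub, maximize = TRUE,
                            tol = 1e-9, maxIter = 100000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m, all(lb <= ub))
  if (!maximize) obj <- -obj

  ## start nonbasic variables at the finite bound closest to zero
  x0 <- ifelse(is.finite(lb) & (!is.finite(ub) | abs(lb) <= abs(ub)), lb,
               ifelse(is.finite(ub), ub, 0))
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)

  ## artificial columns e_i * sign(r_i), basic at |r_i|
  Afull <- cbind(A, diag(sgn, m))
  lbF <- c(lb, rep(0, m))
  ubF <- c(ub, rep(Inf, m))
  xval <- c(x0, abs(r))
  stat <- c(ifelse(x0 == lb, 1L, 2L), rep(0L, m))  # 1 at lb, 2 at ub, 0 basic
  basis <- n + seq_len(m)

  phase1 <- c(rep(0, n), rep(-1, m))
  st <- .simplexCore(Afull, b, lbF, ubF, xval, stat, basis, phase1,
                     enterable = seq_len(n + m), tol = tol, maxIter = maxIter)
  if (st$status != "optimal")
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  infeas <- sum(st$xval[n + seq_len(m)])
  if (infeas > 1e-7 * max(1, max(abs(b), 0)))
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  ## phase 2: pin artificials to zero, restore true costs
  ubF <- c(ub, rep(0, m))
  xval <- st$xval
  xval[n + seq_len(m)] <- 0
  phase2 <- c(obj, rep(0, m))
  st <- .simplexCore(Afull, b, lbF, ubF, xval, st$stat, st$basis, phase2,
                     enterable = seq_len(n), tol = tol, maxIter = maxIter)
  if (st$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  x <- st$xval[seq_len(n)]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = if (maximize) val else -val)
}

.simplexCore <- function(A, b, lb, ub, xval, stat, basis, cvec, enterable,
                         tol, maxIter) {
  m <- nrow(A)
  blandMode <- FALSE
  stall <- 0L
  lastZ <- sum(cvec * xval)
  movable <- (ub - lb) > tol   # fixed variables can never enter
  for (iter in seq_len(maxIter)) {
    B <- A[, basis, drop = FALSE]
    if (iter %% 100L == 0L) {
      ## periodic refresh of basic values against accumulated drift
      nb <- setdiff(seq_len(ncol(A)), basis)
      xval[basis] <- solve(B, b - A[, nb, drop = FALSE] %*% xval[nb])
    }
    y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
    if (is.null(y)) stop("simplex: singular basis")
    d <- cvec - as.vector(crossprod(A, y))
    cand <- enterable[stat[enterable] != 0L & movable[enterable] &
                        ((stat[enterable] == 1L & d[enterable] > tol) |
                         (stat[enterable] == 2L & d[enterable] < -tol))]
    if (length(cand) == 0L)
      return(list(status = "optimal", xval = xval, stat = stat, basis = basis))
    e <- if (blandMode) min(cand)
         else cand[which.max(abs(d[cand]))]  # first max -> smallest index ties
    sigma <- if (stat[e] == 1L) 1 else -1
    w <- solve(B, A[, e])
    delta <- sigma * w                       # x_B changes by -t * delta
    lim <- rep(Inf, m)
    up <- delta > tol
    dn <- delta < -tol
    lim[up] <- (xval[basis[up]] - lb[basis[up]]) / delta[up]
    lim[dn] <- (ub[basis[dn]] - xval[basis[dn]]) / (-delta[dn])
    minLim <- min(lim)
    range_e <- ub[e] - lb[e]
    tstar <- min(minLim, range_e)
    if (!is.finite(tstar))
      return(list(status = "unbounded", xval = xval, stat = stat,
                  basis = basis))
    tstar <- max(tstar, 0)
    if (range_e <= minLim) {
      ## bound flip: entering variable runs to its other bound
      xval[basis] <- xval[basis] - range_e * delta
      xval[e] <- if (stat[e] == 1L) ub[e] else lb[e]
      stat[e] <- if (stat[e] == 1L) 2L else 1L
    } else {
      blockers <- which(lim <= tstar + tol * max(1, abs(tstar)))
      rpos <- blockers[which.min(basis[blockers])]  # Bland-style leaving
      leave <- basis[rpos]
      xval[basis] <- xval[basis] - tstar * delta
      xval[e] <- xval[e] + sigma * tstar
      stat[leave] <- if (delta[rpos] > 0) 1L else 2L
      xval[leave] <- if (delta[rpos] > 0) lb[leave] else ub[leave]
      basis[rpos] <- e
      stat[e] <- 0L
    }
    z <- sum(cvec * xval)
    stall <- if (z <= lastZ + tol) stall + 1L else 0L
    lastZ <- z
    if (stall >= 100L) blandMode <- TRUE
  }
  stop("simplex: iteration limit (", maxIter, ") exceeded")
}
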