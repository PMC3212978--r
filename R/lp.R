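## Linear-programming backend. All FBA problems in the package are
## bounded-variable LPs
##     optimize  c'x   s.t.  Aeq x = beq,  Ageq x >= bgeq,  lb <= x <= ub
## solved through a single internal entry point so the backend can be
## swapped. The backend is a dense two-phase primal simplex with
## Bland's anti-cycling rule, written for the small, highly degenerate
## programs that flux minimization produces (tens of variables). It is
## deterministic: identical inputs take the identical pivot path.

.lpState <- new.env(parent = emptyenv())
.lpState$count <- 0L

#' Number of LP solves performed so far
#'
#' Monotone counter over all linear programs solved in the session;
#' used to verify caching contracts ("warm cache performs zero LP
#' solves").
#'
#' @return integer count.
#' @export
lpSolveCount <- function() .lpState$count

# Infinite bounds are truncated at this magnitude; model conventions
# (+/-1000) stay far below it.
.LP_BIG <- 1e6

## Two-phase simplex for  min c'x  s.t.  A x = b (b >= 0), x >= 0.
## Bland's rule throughout (smallest eligible index), so termination is
## guaranteed despite degeneracy. Returns list(status, x).
.simplexCore <- function(cost, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L)
    return(list(status = "optimal", x = rep(0, n)))
  ## tableau with artificial variables appended
  Tm <- cbind(A, diag(m))
  rhs <- b
  basis <- n + seq_len(m)
  nTot <- n + m

  pivot <- function(prow, pcol) {
    pv <- Tm[prow, pcol]
    Tm[prow, ] <<- Tm[prow, ] / pv
    rhs[prow] <<- rhs[prow] / pv
    for (i in seq_len(m)) {
      if (i == prow) next
      f <- Tm[i, pcol]
      if (f != 0) {
        Tm[i, ] <<- Tm[i, ] - f * Tm[prow, ]
        rhs[i] <<- rhs[i] - f * rhs[prow]
      }
    }
    ## keep canonical form exact on the pivot column
    Tm[, pcol] <<- 0; Tm[prow, pcol] <<- 1
    rhs[rhs < 0 & rhs > -tol] <<- 0
    basis[prow] <<- pcol
  }

  runPhase <- function(cvec, allowed) {
    maxIter <- 2000L + 200L * nTot
    for (iter in seq_len(maxIter)) {
      cb <- cvec[basis]
      red <- cvec - as.numeric(crossprod(Tm, cb))
      enter <- 0L
      for (j in allowed) {            # Bland: first eligible index
        if (!(j %in% basis) && red[j] < -tol) { enter <- j; break }
      }
      if (enter == 0L) return("optimal")
      col <- Tm[, enter]
      elig <- which(col > tol)
      if (!length(elig)) return("unbounded")
      ratio <- rhs[elig] / col[elig]
      best <- min(ratio)
      cand <- elig[ratio <= best + tol]
      prow <- cand[which.min(basis[cand])]  # Bland leaving rule
      pivot(prow, enter)
    }
    stop("LP solver iteration limit exceeded; retriable solver error")
  }

  ## phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  st <- runPhase(c1, seq_len(nTot))
  phase1 <- sum(rhs[basis > n])
  if (st != "optimal" || phase1 > 1e-7)
    return(list(status = "infeasible", x = NULL))
  ## pivot remaining artificials out of the basis where possible
  for (i in which(basis > n)) {
    j <- which(abs(Tm[i, seq_len(n)]) > tol)[1L]
    if (!is.na(j)) pivot(i, j)
  }
  ## phase 2 on the original costs, artificials barred from entering
  c2 <- c(cost, rep(0, m))
  st <- runPhase(c2, seq_len(n))
  if (st == "unbounded") return(list(status = "unbounded", x = NULL))
  x <- rep(0, n)
  inb <- basis <= n
  x[basis[inb]] <- rhs[inb]
  list(status = "optimal", x = x)
}

.solveBoundedLP <- function(obj, Aeq = NULL, beq = NULL,
                            Ageq = NULL, bgeq = NULL,
                            lb, ub, maximize = TRUE) {
  .lpState$count <- .lpState$count + 1L
  n <- length(obj)
  lb <- pmax(lb, -.LP_BIG)
  ub <- pmin(ub, .LP_BIG)
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL))

  ## shift z = x - lb >= 0; assemble equality system with slack and
  ## surplus columns, then flip rows to non-negative rhs
  rng <- ub - lb
  rows <- list(); rhs <- numeric(); slackSign <- numeric()
  if (!is.null(Aeq)) {
    Aeq <- as.matrix(Aeq)
    for (i in seq_len(nrow(Aeq))) {
      rows[[length(rows) + 1L]] <- Aeq[i, ]
      rhs <- c(rhs, beq[i] - sum(Aeq[i, ] * lb))
      slackSign <- c(slackSign, 0)
    }
  }
  if (!is.null(Ageq)) {
    Ageq <- as.matrix(Ageq)
    for (i in seq_len(nrow(Ageq))) {
      rows[[length(rows) + 1L]] <- Ageq[i, ]
      rhs <- c(rhs, bgeq[i] - sum(Ageq[i, ] * lb))
      slackSign <- c(slackSign, -1)   # surplus
    }
  }
  bnd <- which(rng < .LP_BIG * 2)     # upper-bound rows z_j <= rng_j
  for (j in bnd) {
    e <- rep(0, n); e[j] <- 1
    rows[[length(rows) + 1L]] <- e
    rhs <- c(rhs, rng[j])
    slackSign <- c(slackSign, 1)      # slack
  }
  m <- length(rows)
  nSlack <- sum(slackSign != 0)
  A <- matrix(0, m, n + nSlack)
  k <- 0L
  for (i in seq_len(m)) {
    A[i, seq_len(n)] <- rows[[i]]
    if (slackSign[i] != 0) {
      k <- k + 1L
      A[i, n + k] <- slackSign[i]
    }
  }
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
  }
  cost <- c(if (maximize) -obj else obj, rep(0, nSlack))
  res <- .simplexCore(cost, A, rhs)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL))
  x <- res$x[seq_len(n)] + lb
  list(status = "optimal", x = x, objective = sum(obj * x))
}
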