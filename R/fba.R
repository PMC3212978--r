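#' Maximize growth rate by flux balance analysis
#'
#' Solves the canonical FBA linear program: maximize the biomass flux
#' (the growth rate, 1/h) subject to the intracellular steady-state
#' constraint S v = 0 and the flux bounds of the model, with the supplied
#' uptake bounds overriding the lower bounds of exchange reactions.
#'
#' Uptake bounds tighten but never loosen the model's own bounds
#' (\code{lb_used = max(model lb, supplied lb)}), so a reaction closed
#' by a knockout stays closed.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param uptakeBounds named numeric vector of lower bounds
#'   (mmol/gDW/h, negative = uptake allowed) for exchange reaction ids.
#' @return a \linkS4class{FluxSolution}; infeasible models come back
#'   with \code{status = "infeasible"} and \code{mu = 0}.
#' @seealso \code{\link{minimizeTotalFlux}}
#' @export
maximizeGrowth <- function(model, uptakeBounds = numeric()) {
  bounds <- .applyUptakeBounds(model, uptakeBounds)
  S <- as.matrix(model@stoichiometry)
  obj <- as.numeric(colnames(S) == model@biomassReaction)
  res <- .solveBoundedLP(obj, Aeq = S, beq = rep(0, nrow(S)),
                         lb = bounds$lb, ub = bounds$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(methods::new("FluxSolution", mu = 0,
                        fluxes = stats::setNames(rep(NA_real_, ncol(S)),
                                                 colnames(S)),
                        status = "infeasible"))
  mu <- max(0, res$x[which(obj == 1)])
  methods::new("FluxSolution", mu = mu,
               fluxes = stats::setNames(res$x, colnames(S)),
               status = "optimal")
}

#' Minimize total absolute flux at fixed growth rate
#'
#' Secondary objective applied after growth maximization: among all
#' flux distributions achieving the maximal growth rate (within
#' relative tolerance \code{eps}), find one minimizing the total
#' enzymatic cost \eqn{\sum_j |v_j|}. The absolute values are handled
#' by auxiliary variables \eqn{t_j \ge |v_j|} inside the LP; the stored
#' model is never reaction-split.
#'
#' This makes the secreted by-product fluxes read from the solution as
#' reproducible as possible; remaining alternate optima are broken
#' deterministically by the solver.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param uptakeBounds as in \code{\link{maximizeGrowth}}.
#' @param mu the growth rate to hold (from a preceding
#'   \code{maximizeGrowth} call).
#' @param eps relative slack when fixing the growth rate (default
#'   1e-9).
#' @return a \linkS4class{FluxSolution} with \code{mu} within
#'   \code{eps} of the requested rate.
#' @export
minimizeTotalFlux <- function(model, uptakeBounds = numeric(), mu,
                              eps = 1e-9) {
  bounds <- .applyUptakeBounds(model, uptakeBounds)
  S <- as.matrix(model@stoichiometry)
  n <- ncol(S)
  bio <- match(model@biomassReaction, colnames(S))
  lb <- bounds$lb; ub <- bounds$ub
  ## fix growth within relative tolerance
  lb[bio] <- max(lb[bio], mu * (1 - eps) - 1e-12)
  ub[bio] <- min(ub[bio], mu)
  if (lb[bio] > ub[bio]) lb[bio] <- ub[bio]
  ## variables: (v, t); t_j >= |v_j|
  tmax <- pmax(abs(lb), abs(ub))
  obj <- c(rep(0, n), rep(1, n))
  Aeq <- cbind(S, matrix(0, nrow(S), n))
  In <- diag(n)
  Ageq <- rbind(cbind(-In, In),   # t - v >= 0
                cbind(In, In))    # t + v >= 0
  res <- .solveBoundedLP(obj, Aeq = Aeq, beq = rep(0, nrow(S)),
                         Ageq = Ageq, bgeq = rep(0, 2 * n),
                         lb = c(lb, rep(0, n)), ub = c(ub, tmax),
                         maximize = FALSE)
  if (res$status != "optimal")
    stop("flux minimization infeasible at mu = ", mu,
         "; a larger eps may be needed")
  v <- res$x[seq_len(n)]
  methods::new("FluxSolution", mu = max(0, v[bio]),
               fluxes = stats::setNames(v, colnames(S)),
               status = "optimal")
}

## Merge per-step uptake bounds into the model bounds. The supplied map
## defines the environment completely: exchange reactions without an
## entry get their uptake closed (lb = 0); entries tighten but never
## loosen the model's own lower bound (a knocked-out exchange stays
## closed). Secretion (upper) bounds are untouched.
.applyUptakeBounds <- function(model, uptakeBounds) {
  lb <- model@lowerBounds
  ub <- model@upperBounds
  bad <- setdiff(names(uptakeBounds), names(model@exchangeMap))
  if (length(bad))
    stop("uptake bounds for non-exchange reaction(s): ",
         paste(bad, collapse = ", "))
  for (ex in names(model@exchangeMap)) {
    want <- if (ex %in% names(uptakeBounds)) uptakeBounds[[ex]] else 0
    lb[[ex]] <- min(max(lb[[ex]], want), ub[[ex]])
  }
  list(lb = lb, ub = ub)
}

#' Two-stage FBA solve
#'
#' Convenience wrapper running \code{\link{maximizeGrowth}} and, when
#' the model grows and \code{minimizeFlux} is on, the total-flux
#' minimization at the attained rate.
#'
#' @inheritParams maximizeGrowth
#' @param minimizeFlux apply the secondary L1 objective (default TRUE).
#' @return a \linkS4class{FluxSolution}.
#' @export
solveFBA <- function(model, uptakeBounds = numeric(),
                     minimizeFlux = TRUE) {
  sol <- maximizeGrowth(model, uptakeBounds)
  if (sol@status != "optimal" || !minimizeFlux || sol@mu <= 0)
    return(sol)
  minimizeTotalFlux(model, uptakeBounds, mu = sol@mu)
}
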