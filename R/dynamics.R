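#' Per-step uptake bounds from substrate availability
#'
#' Computes the lower (uptake) bound of every exchange reaction from
#' the current medium state and the total population biomass: a tracked
#' metabolite at concentration C can at most be consumed at rate
#' C / (total biomass x dt) per gram dry weight, further capped by the
#' per-metabolite maximal uptake rate. Every competitor receives the
#' same per-gDW bound computed from the total biomass (the model's
#' fairness assumption); in-excess metabolites are bounded by their cap
#' only; metabolites absent from the medium cannot be taken up.
#'
#' @param medium named numeric vector of tracked concentrations
#'   (mmol/L).
#' @param totalBiomass total population biomass (gDW/L), > 0.
#' @param dt time step (h).
#' @param condition a \linkS4class{GrowthCondition} (supplies caps and
#'   the in-excess set).
#' @param exchangeMap named character, exchange reaction -> external
#'   metabolite (see \code{\link{listExchanges}}).
#' @return named numeric vector of lower bounds (<= 0) per exchange
#'   reaction.
#' @export
stepUptakeBounds <- function(medium, totalBiomass, dt, condition,
                             exchangeMap) {
  if (totalBiomass <= 0)
    stop("population extinct: total biomass must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  caps <- condition@uptakeCaps
  capOf <- function(m) if (m %in% names(caps)) caps[[m]] else
    condition@defaultCap
  out <- numeric(length(exchangeMap))
  names(out) <- names(exchangeMap)
  for (k in seq_along(exchangeMap)) {
    m <- exchangeMap[[k]]
    if (m %in% condition@inExcess) {
      out[k] <- -capOf(m)
    } else if (m %in% names(medium) && medium[[m]] > 0) {
      out[k] <- -min(medium[[m]] / (totalBiomass * dt), capOf(m))
    } else {
      out[k] <- 0
    }
  }
  out
}

#' Exponential biomass update
#'
#' One step of exponential growth: \eqn{b(t) = b(t - dt) e^{\mu dt}}.
#'
#' @param b biomass (gDW/L), >= 0.
#' @param mu growth rate (1/h), >= 0.
#' @param dt time step (h).
#' @return updated biomass.
#' @export
updateBiomass <- function(b, mu, dt) {
  stopifnot(b >= 0, mu >= -1e-12)
  b * exp(max(mu, 0) * dt)
}

## Net amount (mmol/L) a strain adds to the medium over one step:
## integral of vex * b0 * e^{mu s} ds over [0, dt]
## = vex * b0 * (e^{mu dt} - 1) / mu, with the linear limit vex*b0*dt
## below the mu threshold (the printed formula is 0/0 at mu = 0, but
## non-growing strains may still exchange at steady state).
.exchangeIntegral <- function(vex, b, mu, dt, muEps = 1e-9) {
  if (mu < muEps) vex * b * dt else vex * b * (exp(mu * dt) - 1) / mu
}

#' Update medium concentrations after one time step
#'
#' Applies the exact exponential-integral substrate update for every
#' strain: each strain exchanging at specific rate vex while growing
#' exponentially at rate mu from biomass b moves
#' \eqn{vex\, b\, (e^{\mu dt} - 1)/\mu} mmol/L into (positive) or out
#' of (negative) the medium. Metabolites secreted for the first time
#' enter the tracked pool; concentrations driven below zero are clamped
#' to zero and the clamped mass is returned (a logged event, not an
#' error).
#'
#' @param medium named numeric vector of tracked concentrations.
#' @param strains list with one entry per strain, each a list with
#'   elements \code{vex} (named numeric, exchange fluxes per external
#'   metabolite, positive = secretion), \code{b} (biomass at the start
#'   of the step) and \code{mu}.
#' @param dt time step (h).
#' @param exclude metabolites never tracked (the in-excess set).
#' @return list with \code{medium} (updated named vector) and
#'   \code{clamped} (total clamped mass, mmol/L).
#' @export
updateMedium <- function(medium, strains, dt, exclude = character()) {
  delta <- numeric(0)
  for (s in strains) {
    if (s$b <= 0) next
    act <- s$vex[s$vex != 0]
    for (m in names(act)) {
      if (m %in% exclude) next
      inc <- .exchangeIntegral(act[[m]], s$b, s$mu, dt)
      delta[m] <- (if (m %in% names(delta)) delta[[m]] else 0) + inc
    }
  }
  for (m in names(delta)) {
    cur <- if (m %in% names(medium)) medium[[m]] else 0
    medium[m] <- cur + delta[[m]]
  }
  clamped <- 0
  neg <- names(medium)[medium < 0]
  if (length(neg)) {
    clamped <- sum(-medium[neg])
    medium[neg] <- 0
  }
  list(medium = medium, clamped = clamped)
}

#' Simulate a batch co-culture of independent strain competitors
#'
#' Time-stepped dynamic FBA over a shared medium: in every interval
#' each strain independently solves its own growth-maximization LP
#' (followed by total-flux minimization) against uptake bounds computed
#' from the common substrate pool and the total population biomass,
#' then biomass grows exponentially and the medium is updated with the
#' exact exponential-integral terms. Secreted metabolites join the
#' shared pool and become consumable by every strain in later steps,
#' which is what lets cross-feeding emerge. The run terminates when no
#' strain can grow (all growth rates below \code{muTol}) or at the time
#' horizon.
#'
#' A co-culture of identical strains reduces exactly to the monoculture
#' of their summed biomass.
#'
#' @param models named list of \linkS4class{StoichiometricModel}, one
#'   per strain (names are the strain ids); build them with
#'   \code{\link{applyKnockout}}.
#' @param initialBiomasses numeric vector (recycled names from
#'   \code{models}), gDW/L; >= 0, sum > 0.
#' @param condition a \linkS4class{GrowthCondition}.
#' @param minimizeFlux apply the secondary total-flux minimization at
#'   every step (default TRUE).
#' @return a \linkS4class{BatchTrajectory}.
#' @seealso \code{\link{simulateMonoculture}}
#' @export
simulateCoculture <- function(models, initialBiomasses, condition,
                              minimizeFlux = TRUE) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- paste0("strain", seq_along(models))
  strains <- names(models)
  nS <- length(strains)
  b <- rep_len(as.numeric(initialBiomasses), nS)
  names(b) <- strains
  if (any(b < 0) || sum(b) <= 0)
    stop("initial biomasses must be >= 0 with positive total")
  dt <- condition@timeStep
  muTol <- condition@muTol

  exMaps <- lapply(models, listExchanges)
  extMets <- sort(unique(unlist(exMaps, use.names = FALSE)))

  medium <- stats::setNames(condition@initialConcentration,
                            condition@carbonSource)

  times <- numeric(); bHist <- list(); mHist <- list()
  muHist <- list(); vexHist <- list()
  clampedTotal <- 0
  t <- 0
  reason <- "max-time"

  repeat {
    btot <- sum(b)
    mus <- numeric(nS); names(mus) <- strains
    vexs <- vector("list", nS); names(vexs) <- strains
    for (i in seq_len(nS)) {
      if (b[[i]] <= 0) {        # extinct competitor: no mass, no fluxes
        vexs[[i]] <- stats::setNames(rep(0, length(extMets)), extMets)
        next
      }
      ub <- stepUptakeBounds(medium, btot, dt, condition, exMaps[[i]])
      sol <- tryCatch(
        solveFBA(models[[i]], ub, minimizeFlux = minimizeFlux),
        error = function(e)
          stop("solver failure for strain '", strains[i], "' at t = ",
               t, " h: ", conditionMessage(e)))
      vex <- stats::setNames(rep(0, length(extMets)), extMets)
      if (sol@status == "optimal") {
        mus[i] <- if (sol@mu > muTol) sol@mu else 0
        vex[unname(exMaps[[i]])] <- sol@fluxes[names(exMaps[[i]])]
      }
      vexs[[i]] <- vex
    }

    times <- c(times, t)
    bHist[[length(bHist) + 1L]] <- b
    mHist[[length(mHist) + 1L]] <- medium
    muHist[[length(muHist) + 1L]] <- mus
    vexHist[[length(vexHist) + 1L]] <- vexs

    if (all(mus < muTol)) { reason <- "stalled"; break }
    if (t + dt > condition@maxTime + 1e-9) { reason <- "max-time"; break }

    upd <- updateMedium(medium,
      lapply(seq_len(nS), function(i)
        list(vex = vexs[[i]], b = b[[i]], mu = mus[[i]])),
      dt, exclude = condition@inExcess)
    medium <- upd$medium
    clampedTotal <- clampedTotal + upd$clamped
    for (i in seq_len(nS)) b[[i]] <- updateBiomass(b[[i]], mus[[i]], dt)
    t <- t + dt
  }

  nt <- length(times)
  allMets <- sort(unique(unlist(lapply(mHist, names))))
  mediumMat <- matrix(0, length(allMets), nt,
                      dimnames = list(allMets, NULL))
  for (k in seq_len(nt))
    mediumMat[names(mHist[[k]]), k] <- mHist[[k]]
  bMat <- do.call(cbind, bHist)
  muMat <- do.call(cbind, muHist)
  rownames(bMat) <- rownames(muMat) <- strains
  fluxList <- lapply(seq_len(nS), function(i) {
    m <- vapply(seq_len(nt), function(k) vexHist[[k]][[i]],
                numeric(length(extMets)))
    m <- matrix(m, nrow = length(extMets), dimnames = list(extMets, NULL))
    m
  })
  names(fluxList) <- strains

  methods::new("BatchTrajectory",
    times = times, biomass = bMat, growthRates = muMat,
    medium = mediumMat, exchangeFluxes = fluxList,
    strains = strains, conditionID = condition@conditionID,
    carbonSource = condition@carbonSource,
    terminationReason = reason, clampedMass = clampedTotal)
}

#' Simulate a batch monoculture
#'
#' Single-strain wrapper around \code{\link{simulateCoculture}}: the
#' classic dynamic FBA batch scheme with quasi-steady-state LP solves
#' between substrate/biomass updates.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param condition a \linkS4class{GrowthCondition}; its
#'   \code{initialBiomass} seeds the culture.
#' @param strainID id recorded in the trajectory (default the model
#'   id).
#' @param minimizeFlux apply the secondary total-flux minimization
#'   (default TRUE).
#' @return a \linkS4class{BatchTrajectory} with one strain.
#' @examples
#' toy <- makeCrossfeedModel(toyCrossfeedSpec())
#' traj <- simulateMonoculture(toy, growthCondition("src_e"))
#' growthPerformance(traj)
#' @export
simulateMonoculture <- function(model, condition,
                                strainID = model@modelID,
                                minimizeFlux = TRUE) {
  models <- stats::setNames(list(model), strainID)
  simulateCoculture(models, condition@initialBiomass, condition,
                    minimizeFlux = minimizeFlux)
}

#' Endpoint biomass of a finished trajectory
#'
#' The growth performance of a culture: the total biomass concentration
#' at termination (for a co-culture, the sum over member strains).
#'
#' @param traj a \linkS4class{BatchTrajectory}.
#' @return numeric, gDW/L.
#' @export
growthPerformance <- function(traj) {
  sum(traj@biomass[, ncol(traj@biomass)])
}
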