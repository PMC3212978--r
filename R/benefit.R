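#' Growth benefit of a community relative to monocultures
#'
#' \deqn{benefit = (g - \max_i m_i) / \max_i m_i}
#' where g is the endpoint biomass of the co-culture and the m_i are
#' endpoint biomasses of reference monocultures under the same initial
#' conditions. With the m_i ranging over the community members this is
#' the relative benefit (is the group better than any member alone?);
#' over all strains of the diversity graph it is the absolute benefit.
#' Negative values mean the co-culture grew no better than the best
#' monoculture.
#'
#' @param g endpoint group biomass (gDW/L).
#' @param monos numeric vector of monoculture endpoint biomasses.
#' @return dimensionless benefit.
#' @export
benefit <- function(g, monos) {
  if (!length(monos)) stop("no monoculture endpoints supplied")
  m <- max(monos)
  if (m <= 0) stop("benefit undefined: best monoculture endpoint is 0")
  (g - m) / m
}

#' Simulate a community and compute its growth benefits
#'
#' Runs one batch co-culture of the community members (equal initial
#' biomass split by default), measures the endpoint group biomass, and
#' computes the relative benefit (against the member monocultures) and,
#' when endpoints for all graph strains are supplied, the absolute
#' benefit. Cross-feeding interactions are detected from the exchange
#' flux time profiles. Communities that hit the time horizon before
#' stalling are flagged non-comparable.
#'
#' @param community a \linkS4class{Community} or character vector of
#'   member strain ids.
#' @param models named list of \linkS4class{StoichiometricModel}
#'   covering (at least) the members.
#' @param condition a \linkS4class{GrowthCondition}; its
#'   \code{initialBiomass} is the total initial biomass of the
#'   co-culture.
#' @param monoEndpoints named numeric, monoculture endpoint biomass per
#'   member (same condition).
#' @param allEndpoints optional named numeric over all strains of the
#'   diversity graph, enabling the absolute benefit.
#' @param split optional named numeric initial biomass per member
#'   (default: equal split of \code{condition@initialBiomass}).
#' @param minimizeFlux forwarded to the simulator.
#' @return a \linkS4class{CommunityResult}.
#' @export
communityBenefit <- function(community, models, condition,
                             monoEndpoints, allEndpoints = NULL,
                             split = NULL, minimizeFlux = TRUE) {
  if (is.character(community))
    community <- methods::new("Community", members = community,
                              conditionID = condition@conditionID)
  mem <- community@members
  missM <- setdiff(mem, names(models))
  if (length(missM))
    stop("no model supplied for member(s): ", paste(missM, collapse = ", "))
  missE <- setdiff(mem, names(monoEndpoints))
  if (length(missE))
    stop("missing monoculture endpoint(s) for: ",
         paste(missE, collapse = ", "))
  if (is.null(split)) {
    split <- stats::setNames(rep(condition@initialBiomass / length(mem),
                                 length(mem)), mem)
  } else {
    stopifnot(identical(sort(names(split)), sort(mem)))
    split <- split[mem]
  }
  traj <- simulateCoculture(models[mem], split, condition,
                            minimizeFlux = minimizeFlux)
  g <- growthPerformance(traj)
  rel <- benefit(g, monoEndpoints[mem])
  abs_ <- if (!is.null(allEndpoints)) benefit(g, allEndpoints) else NA_real_
  methods::new("CommunityResult",
    community = community, split = split, groupEndpoint = g,
    monoEndpoints = monoEndpoints[mem], relativeBenefit = rel,
    absoluteBenefit = abs_,
    interactions = detectInteractions(traj),
    truncated = traj@terminationReason == "max-time")
}

#' Benefit of a strain pair across initial composition ratios
#'
#' Simulates the pair co-culture once per initial biomass ratio (total
#' initial biomass held fixed) and reports the benefit curve with its
#' argmax. The default grid is ninths, 1:9 up to 9:1.
#'
#' @param models named list of exactly two
#'   \linkS4class{StoichiometricModel}.
#' @param condition a \linkS4class{GrowthCondition}.
#' @param monoEndpoints named numeric endpoints for both strains.
#' @param ratios fractions of the total initial biomass given to the
#'   first strain (default 0.1 ... 0.9).
#' @param allEndpoints optional, enables absolute benefit.
#' @param minimizeFlux forwarded to the simulator.
#' @return data.frame with columns \code{ratio}, \code{groupEndpoint},
#'   \code{relativeBenefit}, \code{absoluteBenefit}; the row index of
#'   the best ratio is in \code{attr(, "argmax")}.
#' @export
ratioScan <- function(models, condition, monoEndpoints,
                      ratios = seq(0.1, 0.9, by = 0.1),
                      allEndpoints = NULL, minimizeFlux = TRUE) {
  stopifnot(length(models) == 2L, !is.null(names(models)))
  stopifnot(all(ratios > 0 & ratios < 1))
  mem <- names(models)
  rows <- lapply(ratios, function(r) {
    split <- stats::setNames(
      condition@initialBiomass * c(r, 1 - r), mem)
    res <- communityBenefit(mem, models, condition, monoEndpoints,
                            allEndpoints = allEndpoints, split = split,
                            minimizeFlux = minimizeFlux)
    data.frame(ratio = r, groupEndpoint = res@groupEndpoint,
               relativeBenefit = res@relativeBenefit,
               absoluteBenefit = res@absoluteBenefit)
  })
  out <- do.call(rbind, rows)
  attr(out, "argmax") <- which.max(out$relativeBenefit)
  out
}

#' Detect cross-feeding interactions in a co-culture trajectory
#'
#' Scans the exchange flux time profiles: for every non-primal
#' metabolite, every (producer, consumer) strain pair where the
#' producer secreted it (flux above \code{tol} for at least one step)
#' and the consumer took it up (flux below \code{-tol}), with
#' production starting no later than the consumption window ends.
#' Consumption may trail production (sequential use after source
#' exhaustion) or overlap it (parallel use).
#'
#' @param traj a co-culture \linkS4class{BatchTrajectory} (a
#'   monoculture yields an empty record).
#' @param tol flux threshold suppressing LP noise (default 1e-6
#'   mmol/gDW/h).
#' @return data.frame with columns \code{metabolite}, \code{producer},
#'   \code{consumer}, \code{producerStart}, \code{producerEnd},
#'   \code{consumerStart}, \code{consumerEnd} (hours).
#' @export
detectInteractions <- function(traj, tol = 1e-6) {
  empty <- data.frame(metabolite = character(), producer = character(),
                      consumer = character(),
                      producerStart = numeric(), producerEnd = numeric(),
                      consumerStart = numeric(), consumerEnd = numeric())
  strains <- traj@strains
  if (length(strains) < 2L) return(empty)
  mets <- setdiff(rownames(traj@exchangeFluxes[[1L]]),
                  traj@carbonSource)
  rows <- list()
  for (m in mets) {
    for (p in strains) for (q in strains) {
      if (p == q) next
      fp <- traj@exchangeFluxes[[p]][m, ]
      fq <- traj@exchangeFluxes[[q]][m, ]
      prodIdx <- which(!is.na(fp) & fp > tol)
      consIdx <- which(!is.na(fq) & fq < -tol)
      if (!length(prodIdx) || !length(consIdx)) next
      pS <- traj@times[min(prodIdx)]; pE <- traj@times[max(prodIdx)]
      cS <- traj@times[min(consIdx)]; cE <- traj@times[max(consIdx)]
      if (pS > cE) next  # consumption entirely before any production
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, producer = p, consumer = q,
        producerStart = pS, producerEnd = pE,
        consumerStart = cS, consumerEnd = cE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Classify pairwise interaction links
#'
#' Summarizes an interaction record into one row per unordered strain
#' pair: \code{"bidirectional"} when metabolites flow in both
#' directions, \code{"unidirectional"} when one strain is a mere
#' provider (altruist), \code{"none"} otherwise.
#'
#' @param record output of \code{\link{detectInteractions}}.
#' @param strains the strains of the co-culture.
#' @return data.frame with columns \code{strainA}, \code{strainB},
#'   \code{type}.
#' @export
interactionTypes <- function(record, strains) {
  pairs <- utils::combn(sort(strains), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ab <- any(record$producer == a & record$consumer == b)
    ba <- any(record$producer == b & record$consumer == a)
    type <- if (ab && ba) "bidirectional"
      else if (ab || ba) "unidirectional" else "none"
    data.frame(strainA = a, strainB = b, type = type)
  })
  do.call(rbind, rows)
}

#' Predict community growth from its constituent pairs
#'
#' The growth performance of a strain community linearly follows the
#' mean of the growth performances of its constituent pairs, as long as
#' every pair interacts; the prediction is that mean, and the flag
#' records whether the all-pairs-interact precondition holds (only
#' flagged communities enter the correlation analysis).
#'
#' @param community a \linkS4class{Community} or character member
#'   vector.
#' @param pairResults list of \linkS4class{CommunityResult}, one per
#'   constituent pair (any order).
#' @return list with \code{prediction} (gDW/L), \code{allPairsInteract}
#'   (logical) and \code{pairs} (bookkeeping data.frame).
#' @export
pairMeanPrediction <- function(community, pairResults) {
  mem <- if (is.character(community)) community else community@members
  need <- utils::combn(sort(mem), 2L)
  keys <- apply(need, 2L, paste, collapse = "|")
  have <- vapply(pairResults, function(r)
    paste(sort(members(r)), collapse = "|"), character(1))
  missing <- setdiff(keys, have)
  if (length(missing))
    stop("missing pair simulation(s): ", paste(missing, collapse = ", "))
  sel <- pairResults[match(keys, have)]
  perf <- vapply(sel, function(r) r@groupEndpoint, numeric(1))
  inter <- vapply(sel, function(r) nrow(r@interactions) > 0, logical(1))
  list(prediction = mean(perf),
       allPairsInteract = all(inter),
       pairs = data.frame(pair = keys, performance = perf,
                          interacting = inter))
}

#' Correlation between pair-mean predictions and simulated growth
#'
#' Pearson correlation over (prediction, simulation) pairs, restricted
#' to communities whose constituent pairs all interact.
#'
#' @param predicted,simulated numeric vectors.
#' @param allPairsInteract logical vector of the same length.
#' @return Pearson correlation coefficient.
#' @export
pairMeanCorrelation <- function(predicted, simulated, allPairsInteract) {
  keep <- which(allPairsInteract)
  if (length(keep) < 3L)
    stop("need at least 3 fully interacting communities")
  stats::cor(predicted[keep], simulated[keep])
}
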