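#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Stoichiometric metabolic model
#'
#' Container for a constraint-based metabolic model: the stoichiometric
#' matrix (metabolites x reactions), per-reaction flux bounds,
#' gene-protein-reaction (GPR) rules, the biomass reaction and the map
#' from exchange reactions to the external metabolites they transport.
#'
#' Flux units are mmol/gDW/h; the biomass reaction flux is the specific
#' growth rate in 1/h. The sign convention for exchange fluxes is fixed
#' package-wide: positive flux = secretion into the medium, negative
#' flux = uptake.
#'
#' @slot modelID single identifier string.
#' @slot stoichiometry sparse \code{dgCMatrix}, metabolites in rows,
#'   reactions in columns, both dimnames set.
#' @slot lowerBounds,upperBounds named numeric vectors of per-reaction
#'   flux limits (names = reaction ids).
#' @slot gpr named character vector of boolean GPR expressions over gene
#'   ids (\code{""} = no rule, reaction always available).
#' @slot genes character vector, the gene universe of the model.
#' @slot biomassReaction id of the unique biomass reaction.
#' @slot exchangeMap named character vector mapping exchange reaction id
#'   to the external metabolite it transports.
#' @slot metComp named character vector giving the compartment of every
#'   metabolite.
#' @slot externalCompartment compartment id treated as the medium
#'   (default \code{"e"}).
#'
#' @exportClass StoichiometricModel
setClass("StoichiometricModel",
  representation(
    modelID = "character",
    stoichiometry = "dgCMatrix",
    lowerBounds = "numeric",
    upperBounds = "numeric",
    gpr = "character",
    genes = "character",
    biomassReaction = "character",
    exchangeMap = "character",
    metComp = "character",
    externalCompartment = "character"
  )
)

setValidity("StoichiometricModel", function(object) {
  msg <- character()
  S <- object@stoichiometry
  rxns <- colnames(S)
  mets <- rownames(S)
  if (is.null(rxns) || is.null(mets))
    return("stoichiometry must have metabolite row names and reaction column names")
  if (anyDuplicated(rxns)) msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(mets)) msg <- c(msg, "duplicated metabolite ids")
  for (nm in c("lowerBounds", "upperBounds", "gpr")) {
    v <- slot(object, nm)
    if (length(v) != length(rxns) || !identical(names(v), rxns))
      msg <- c(msg, sprintf("%s must be named by the reaction ids, in order", nm))
  }
  bad <- which(object@lowerBounds > object@upperBounds)
  if (length(bad))
    msg <- c(msg, sprintf("lower bound exceeds upper bound for reaction(s): %s",
                          paste(rxns[bad], collapse = ", ")))
  if (length(object@biomassReaction) != 1L ||
      !(object@biomassReaction %in% rxns))
    msg <- c(msg, "biomassReaction must name exactly one existing reaction")
  if (length(object@exchangeMap)) {
    if (is.null(names(object@exchangeMap)) ||
        !all(names(object@exchangeMap) %in% rxns))
      msg <- c(msg, "exchangeMap names must be reaction ids")
    if (!all(object@exchangeMap %in% mets))
      msg <- c(msg, "exchangeMap values must be metabolite ids")
  }
  if (length(object@metComp) != length(mets) ||
      !identical(names(object@metComp), mets))
    msg <- c(msg, "metComp must be named by the metabolite ids, in order")
  # every non-exchange column must have >= 1 nonzero entry
  nnz <- diff(S@p)
  empty <- rxns[nnz == 0L & !(rxns %in% names(object@exchangeMap))]
  if (length(empty))
    msg <- c(msg, sprintf("reaction(s) with empty stoichiometry: %s",
                          paste(empty, collapse = ", ")))
  # every exchange reaction touches exactly one metabolite, and it is external
  for (ex in names(object@exchangeMap)) {
    touched <- mets[S[, ex] != 0]
    if (length(touched) != 1L) {
      msg <- c(msg, sprintf("exchange reaction %s touches %d metabolites (must be 1)",
                            ex, length(touched)))
    } else {
      if (!identical(touched, unname(object@exchangeMap[[ex]])))
        msg <- c(msg, sprintf("exchangeMap entry for %s disagrees with stoichiometry", ex))
      if (object@metComp[[touched]] != object@externalCompartment)
        msg <- c(msg, sprintf("exchange reaction %s transports a non-external metabolite", ex))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Batch growth condition
#'
#' A single-carbon-source batch growth scenario: the carbon source, its
#' initial concentration, the metabolites assumed to be in excess (never
#' depleted), per-metabolite maximal uptake rates, the initial biomass,
#' and the time discretization of the dynamic FBA scheme.
#'
#' @slot conditionID identifier (conventionally the carbon source name).
#' @slot carbonSource external metabolite id of the limiting source.
#' @slot initialConcentration mmol/L of the source at t = 0.
#' @slot inExcess external metabolite ids never depleted (oxygen and
#'   inorganics in genome-scale settings).
#' @slot uptakeCaps named numeric: maximal uptake rate (mmol/gDW/h) per
#'   external metabolite; metabolites without an entry are capped at
#'   \code{defaultCap}.
#' @slot defaultCap fallback uptake cap (may be \code{Inf}).
#' @slot initialBiomass gDW/L at t = 0.
#' @slot timeStep time resolution delta-t in hours.
#' @slot maxTime simulation horizon in hours.
#' @slot muTol growth-rate threshold (1/h) below which a strain counts
#'   as non-growing.
#'
#' @exportClass GrowthCondition
setClass("GrowthCondition",
  representation(
    conditionID = "character",
    carbonSource = "character",
    initialConcentration = "numeric",
    inExcess = "character",
    uptakeCaps = "numeric",
    defaultCap = "numeric",
    initialBiomass = "numeric",
    timeStep = "numeric",
    maxTime = "numeric",
    muTol = "numeric"
  ),
  prototype(
    inExcess = character(),
    uptakeCaps = numeric(),
    defaultCap = Inf,
    initialBiomass = 0.003,
    timeStep = 0.1,
    maxTime = 100,
    muTol = 1e-6
  )
)

setValidity("GrowthCondition", function(object) {
  msg <- character()
  if (length(object@carbonSource) != 1L)
    msg <- c(msg, "carbonSource must be a single metabolite id")
  if (object@initialConcentration <= 0)
    msg <- c(msg, "initialConcentration must be > 0")
  if (object@timeStep <= 0) msg <- c(msg, "timeStep must be > 0")
  if (object@maxTime <= 0) msg <- c(msg, "maxTime must be > 0")
  if (object@initialBiomass <= 0) msg <- c(msg, "initialBiomass must be > 0")
  if (object@carbonSource %in% object@inExcess)
    msg <- c(msg, "the carbon source cannot be in the in-excess set")
  if (length(object@uptakeCaps) && is.null(names(object@uptakeCaps)))
    msg <- c(msg, "uptakeCaps must be named by metabolite ids")
  if (length(msg)) msg else TRUE
})

#' Strain specification
#'
#' A strain is the wild-type model with a (possibly empty) set of
#' knocked-out genes; by convention a single-knockout strain is named
#' after its deleted gene.
#'
#' @slot strainID identifier.
#' @slot knockouts character vector of knocked-out gene ids (empty =
#'   wild-type).
#'
#' @exportClass StrainSpec
setClass("StrainSpec",
  representation(strainID = "character", knockouts = "character"),
  prototype(knockouts = character())
)

setValidity("StrainSpec", function(object) {
  if (length(object@strainID) != 1L || !nzchar(object@strainID))
    "strainID must be a non-empty string" else TRUE
})

#' Flux solution of one FBA problem
#'
#' @slot mu optimal growth rate (1/h); 0 for infeasible problems.
#' @slot fluxes named numeric flux vector (mmol/gDW/h).
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#'
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(mu = "numeric", fluxes = "numeric", status = "character")
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  if (object@status == "optimal" && object@mu < -1e-9)
    return("optimal growth rate must be non-negative")
  TRUE
})

#' Batch culture trajectory
#'
#' Time course of a batch monoculture or co-culture: per-strain biomass,
#' medium concentrations, per-strain growth rates and per-strain
#' exchange fluxes on a regular time grid.
#'
#' Columns of \code{biomass} and \code{medium} are states at
#' \code{times}; column k of \code{growthRates} and of each element of
#' \code{exchangeFluxes} is the flux solution computed at
#' \code{times[k]} and used to advance the state to \code{times[k+1]}
#' (the final column is the solve that triggered termination, \code{NA}
#' when the horizon was hit first).
#'
#' @slot times hours, strictly increasing, constant step.
#' @slot biomass strains x times matrix, gDW/L.
#' @slot growthRates strains x times matrix, 1/h.
#' @slot medium external metabolites x times matrix, mmol/L.
#' @slot exchangeFluxes named list (one entry per strain) of external
#'   metabolites x times flux matrices, mmol/gDW/h, positive = secretion.
#' @slot strains strain ids.
#' @slot conditionID source growth condition id.
#' @slot carbonSource the primal source metabolite id.
#' @slot terminationReason \code{"stalled"} (no strain can grow) or
#'   \code{"max-time"}.
#' @slot clampedMass total mmol/L of negative-concentration overdraw
#'   clamped to zero over the run.
#'
#' @exportClass BatchTrajectory
setClass("BatchTrajectory",
  representation(
    times = "numeric",
    biomass = "matrix",
    growthRates = "matrix",
    medium = "matrix",
    exchangeFluxes = "list",
    strains = "character",
    conditionID = "character",
    carbonSource = "character",
    terminationReason = "character",
    clampedMass = "numeric"
  )
)

setValidity("BatchTrajectory", function(object) {
  msg <- character()
  nt <- length(object@times)
  if (nt > 1) {
    dts <- diff(object@times)
    if (any(dts <= 0)) msg <- c(msg, "times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-9) msg <- c(msg, "time step must be constant")
  }
  if (ncol(object@biomass) != nt || ncol(object@medium) != nt)
    msg <- c(msg, "biomass and medium must have one column per time point")
  if (any(object@medium < -1e-9))
    msg <- c(msg, "medium concentrations must be non-negative")
  if (!object@terminationReason %in% c("stalled", "max-time"))
    msg <- c(msg, "terminationReason must be 'stalled' or 'max-time'")
  if (length(msg)) msg else TRUE
})

#' By-product secretion profile of a strain
#'
#' The metabolic blueprint of a strain in a given condition: for every
#' secreted metabolite, the maximum concentration it reached during the
#' strain's batch monoculture (the primal carbon source is excluded).
#'
#' @slot strainID strain id.
#' @slot conditionID growth condition id.
#' @slot cmax named numeric, mmol/L (or by-production efficiencies for
#'   the single-step FBA construction, which enter the edge-weight ratio
#'   identically).
#'
#' @exportClass ByproductProfile
setClass("ByproductProfile",
  representation(strainID = "character", conditionID = "character",
                 cmax = "numeric")
)

setValidity("ByproductProfile", function(object) {
  if (length(object@cmax) && any(object@cmax < 0))
    "cmax values must be non-negative" else TRUE
})

#' Diversity graph over viable strains
#'
#' Weighted, undirected graph whose nodes are the viable strains of one
#' growth condition and whose edge weights in [0, 1] are the maximal
#' relative difference in maximum secreted by-product concentration
#' between the two strains. A weight of 0 means identical by-production;
#' a weight of 1 means at least one strain secretes a by-product novel
#' to the other.
#'
#' @slot conditionID growth condition id.
#' @slot nodes strain ids.
#' @slot weights symmetric numeric matrix with zero diagonal; entries in
#'   [0, 1] (binary graphs hold 0/1).
#' @slot attributes optional named numeric node attributes (e.g. a
#'   per-gene conservation score for the deleted gene).
#' @slot binary TRUE after thresholding.
#' @slot threshold the binarization threshold used (NA for weighted
#'   graphs).
#'
#' @exportClass DiversityGraph
setClass("DiversityGraph",
  representation(
    conditionID = "character",
    nodes = "character",
    weights = "matrix",
    attributes = "numeric",
    binary = "logical",
    threshold = "numeric"
  ),
  prototype(attributes = numeric(), binary = FALSE, threshold = NA_real_)
)

setValidity("DiversityGraph", function(object) {
  msg <- character()
  W <- object@weights
  n <- length(object@nodes)
  if (!identical(dim(W), c(n, n)))
    msg <- c(msg, "weights must be an n x n matrix over the nodes")
  else if (n > 0L) {
    if (max(abs(W - t(W))) > 0) msg <- c(msg, "weights must be symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "no self-edges allowed")
    if (any(W < 0) || any(W > 1)) msg <- c(msg, "weights must lie in [0, 1]")
    if (object@binary && !all(W %in% c(0, 1)))
      msg <- c(msg, "binary graph weights must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' Structurally compressed diversity graph
#'
#' Quotient of a binary diversity graph under structural equivalence:
#' strains with identical binary neighborhoods (and therefore mutually
#' non-adjacent) are merged into one supernode. Cliques of the quotient
#' correspond one-to-one to cliques of the original graph with one
#' representative per supernode.
#'
#' @slot membership named character: node -> supernode id.
#' @slot supernodes named list: supernode id -> member node ids.
#' @slot quotient logical adjacency matrix over supernodes.
#' @slot conditionID growth condition id.
#'
#' @exportClass CompressedGraph
setClass("CompressedGraph",
  representation(membership = "character", supernodes = "list",
                 quotient = "matrix", conditionID = "character")
)

setValidity("CompressedGraph", function(object) {
  msg <- character()
  members <- unlist(object@supernodes, use.names = FALSE)
  if (anyDuplicated(members))
    msg <- c(msg, "each node must belong to exactly one supernode")
  if (!setequal(names(object@membership), members))
    msg <- c(msg, "membership and supernodes disagree")
  q <- object@quotient
  if (!identical(rownames(q), names(object@supernodes)))
    msg <- c(msg, "quotient matrix must be indexed by supernode ids")
  if (length(msg)) msg else TRUE
})

#' Candidate strain community
#'
#' A set of at least two pairwise metabolically different strains, i.e.
#' a clique of the binarized diversity graph.
#'
#' @slot members strain ids, pairwise adjacent in the source graph.
#' @slot conditionID growth condition the community was identified in.
#' @slot provenance free-form list (e.g. supernode representatives).
#'
#' @exportClass Community
setClass("Community",
  representation(members = "character", conditionID = "character",
                 provenance = "list"),
  prototype(provenance = list())
)

setValidity("Community", function(object) {
  if (anyDuplicated(object@members)) "duplicate community members" else TRUE
})

#' Simulated growth outcome of a strain community
#'
#' @slot community the \linkS4class{Community} simulated.
#' @slot split named numeric, initial biomass per member (gDW/L).
#' @slot groupEndpoint total endpoint biomass of the co-culture (gDW/L).
#' @slot monoEndpoints named numeric, endpoint biomasses of the
#'   reference monocultures.
#' @slot relativeBenefit (g - max member monoculture) / max member
#'   monoculture.
#' @slot absoluteBenefit same with the max over all strains of the
#'   diversity graph (NA when those endpoints were not supplied).
#' @slot interactions data.frame of detected cross-feeding events
#'   (metabolite, producer, consumer, time windows).
#' @slot truncated TRUE if the co-culture hit the time horizon before
#'   stalling (endpoint not comparable).
#'
#' @exportClass CommunityResult
setClass("CommunityResult",
  representation(
    community = "Community",
    split = "numeric",
    groupEndpoint = "numeric",
    monoEndpoints = "numeric",
    relativeBenefit = "numeric",
    absoluteBenefit = "numeric",
    interactions = "data.frame",
    truncated = "logical"
  ),
  prototype(absoluteBenefit = NA_real_, truncated = FALSE)
)

#' Specification of a toy cross-feeding model
#'
#' Parameters of the small analytically tractable stoichiometric models
#' used as desk-scale stand-ins for a genome-scale network: one external
#' carbon source, one or more catabolic routes (each with a biomass
#' yield and an optional secreted by-product), optional per-by-product
#' catabolism, and an optional coupled two-by-product catabolic
#' reaction. Gene gating on the routes makes single knockouts produce
#' provider and consumer strains with closed-form endpoint biomasses.
#'
#' @slot sourceID external source metabolite id (without compartment
#'   suffix).
#' @slot routes data.frame with columns \code{id}, \code{gene},
#'   \code{yield} (gDW biomass per mmol source), \code{byproduct}
#'   (metabolite id or NA), \code{secretion} (mmol by-product per mmol
#'   source).
#' @slot catabolism data.frame with columns \code{byproduct},
#'   \code{gene}, \code{yield} (gDW per mmol by-product).
#' @slot pairCatabolism empty list, or
#'   \code{list(byproducts = c(id1, id2), gene =, yield =)} for a
#'   reaction that consumes both by-products in 1:1 proportion.
#' @slot modelID id given to the generated model.
#'
#' @exportClass ToyModelSpec
setClass("ToyModelSpec",
  representation(
    sourceID = "character",
    routes = "data.frame",
    catabolism = "data.frame",
    pairCatabolism = "list",
    modelID = "character"
  )
)

setValidity("ToyModelSpec", function(object) {
  msg <- character()
  r <- object@routes
  need <- c("id", "gene", "yield", "byproduct", "secretion")
  if (!all(need %in% names(r)))
    msg <- c(msg, "routes must have columns id, gene, yield, byproduct, secretion")
  else {
    if (nrow(r) < 1L) msg <- c(msg, "at least one catabolic route is required")
    if (any(r$yield <= 0)) msg <- c(msg, "route yields must be > 0")
    if (any(!is.na(r$byproduct) & r$secretion <= 0))
      msg <- c(msg, "by-product secretion coefficients must be > 0")
  }
  if (nrow(object@catabolism) &&
      any(object@catabolism$yield <= 0))
    msg <- c(msg, "catabolism yields must be > 0")
  if (length(object@pairCatabolism) &&
      !all(c("byproducts", "gene", "yield") %in% names(object@pairCatabolism)))
    msg <- c(msg, "pairCatabolism must have byproducts, gene, yield")
  if (length(msg)) msg else TRUE
})
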