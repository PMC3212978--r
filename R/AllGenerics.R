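#' Accessor generics
#'
#' Small read accessors for the core classes, so user code never touches
#' slots directly.
#'
#' @param object an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("fluxBounds", function(object) standardGeneric("fluxBounds"))

#' @rdname accessors
#' @export
setGeneric("biomassReaction", function(object) standardGeneric("biomassReaction"))

#' @rdname accessors
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

setMethod("reactionIds", "StoichiometricModel",
          function(object) colnames(object@stoichiometry))
setMethod("metaboliteIds", "StoichiometricModel",
          function(object) rownames(object@stoichiometry))
setMethod("geneIds", "StoichiometricModel", function(object) object@genes)
setMethod("fluxBounds", "StoichiometricModel", function(object)
  data.frame(reaction = reactionIds(object),
             lower = unname(object@lowerBounds),
             upper = unname(object@upperBounds)))
setMethod("biomassReaction", "StoichiometricModel",
          function(object) object@biomassReaction)
setMethod("gprRules", "StoichiometricModel", function(object) object@gpr)

setMethod("nodeIds", "DiversityGraph", function(object) object@nodes)
setMethod("edgeWeights", "DiversityGraph", function(object) object@weights)
setMethod("members", "Community", function(object) object@members)
setMethod("members", "CommunityResult",
          function(object) object@community@members)

setMethod("growthRate", "FluxSolution", function(object) object@mu)
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

setMethod("show", "StoichiometricModel", function(object) {
  S <- object@stoichiometry
  cat("StoichiometricModel '", object@modelID, "'\n", sep = "")
  cat("  ", nrow(S), " metabolites, ", ncol(S), " reactions, ",
      length(object@genes), " genes\n", sep = "")
  cat("  biomass: ", object@biomassReaction,
      "; exchanges: ", length(object@exchangeMap), "\n", sep = "")
})

setMethod("show", "GrowthCondition", function(object) {
  cat("GrowthCondition '", object@conditionID, "': ",
      object@initialConcentration, " mmol/L ", object@carbonSource,
      ", b0 = ", object@initialBiomass, " gDW/L, dt = ", object@timeStep,
      " h\n", sep = "")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution: status = ", object@status,
      ", mu = ", format(object@mu, digits = 6), " 1/h\n", sep = "")
})

setMethod("show", "BatchTrajectory", function(object) {
  cat("BatchTrajectory (", length(object@strains), " strain(s), ",
      length(object@times), " time points, ",
      object@terminationReason, ")\n", sep = "")
  b <- object@biomass[, ncol(object@biomass), drop = TRUE]
  cat("  endpoint biomass: ",
      paste(sprintf("%s = %.4g", object@strains, b), collapse = ", "),
      " gDW/L\n", sep = "")
})

setMethod("show", "DiversityGraph", function(object) {
  n <- length(object@nodes)
  ne <- sum(object@weights[upper.tri(object@weights)] > 0)
  cat(if (object@binary) "Binary" else "Weighted",
      " DiversityGraph '", object@conditionID, "': ", n, " nodes, ",
      ne, " edges", sep = "")
  if (object@binary) cat(" (threshold ", object@threshold, ")", sep = "")
  cat("\n")
})

setMethod("show", "CompressedGraph", function(object) {
  sizes <- lengths(object@supernodes)
  cat("CompressedGraph: ", length(sizes), " supernodes over ",
      sum(sizes), " nodes (largest: ", max(sizes), ")\n", sep = "")
})

setMethod("show", "Community", function(object) {
  cat("Community (", length(object@members), "): ",
      paste(object@members, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CommunityResult", function(object) {
  cat("CommunityResult {", paste(members(object), collapse = ", "),
      "}\n  group endpoint: ", format(object@groupEndpoint, digits = 6),
      " gDW/L\n  relative benefit: ",
      format(object@relativeBenefit, digits = 4), sep = "")
  if (!is.na(object@absoluteBenefit))
    cat("; absolute benefit: ", format(object@absoluteBenefit, digits = 4),
        sep = "")
  cat("\n  interactions: ", nrow(object@interactions), "\n", sep = "")
})
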