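#' Construct a stoichiometric model from parts
#'
#' Low-level constructor used by the readers and the fixture
#' generators. Exchange reactions may be supplied explicitly; when
#' \code{exchangeMap = NULL} they are auto-detected as the columns that
#' touch exactly one metabolite, that metabolite lying in the external
#' compartment.
#'
#' @param modelID identifier string.
#' @param stoichiometry matrix or sparse Matrix (metabolites x
#'   reactions) with dimnames.
#' @param lowerBounds,upperBounds numeric vectors (recycled if length
#'   1), in reaction order or named by reaction.
#' @param gpr character vector of GPR rules ("" = none), in reaction
#'   order or named.
#' @param genes gene universe; defaults to the union of genes in
#'   \code{gpr}.
#' @param biomassReaction id of the biomass reaction.
#' @param metComp compartment per metabolite; defaults to "e" for
#'   metabolites whose id ends in "_e" and "c" otherwise.
#' @param exchangeMap named character (exchange reaction -> external
#'   metabolite), or NULL to auto-detect.
#' @param externalCompartment id of the medium compartment.
#' @return a validated \linkS4class{StoichiometricModel}.
#' @export
stoichiometricModel <- function(modelID, stoichiometry,
                                lowerBounds, upperBounds,
                                gpr = "", genes = NULL,
                                biomassReaction,
                                metComp = NULL,
                                exchangeMap = NULL,
                                externalCompartment = "e") {
  S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  rxns <- colnames(S)
  mets <- rownames(S)
  fix <- function(v, default) {
    if (length(v) == 1L && is.null(names(v))) v <- rep(v, length(rxns))
    if (!is.null(names(v))) {
      out <- rep(default, length(rxns))
      names(out) <- rxns
      out[names(v)] <- v
      out
    } else stats::setNames(v, rxns)
  }
  lb <- fix(lowerBounds, 0)
  ub <- fix(upperBounds, 0)
  gpr <- fix(gpr, "")
  storage.mode(lb) <- storage.mode(ub) <- "double"
  if (is.null(metComp)) {
    metComp <- ifelse(grepl("_e$", mets), externalCompartment, "c")
    names(metComp) <- mets
  }
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(gpr, function(g)
      gprGenes(parseGPR(g))))))
  if (is.null(exchangeMap)) {
    nTouch <- Matrix::colSums(S != 0)
    cand <- rxns[nTouch == 1L]
    exchangeMap <- character()
    for (rx in cand) {
      met <- mets[S[, rx] != 0]
      if (metComp[[met]] == externalCompartment)
        exchangeMap[[rx]] <- met
    }
    ## boundary-looking reactions touching several external
    ## metabolites cannot be exchanges (one metabolite each)
    multi <- rxns[nTouch > 1L]
    for (rx in multi) {
      touched <- mets[S[, rx] != 0]
      if (all(metComp[touched] == externalCompartment))
        warning("reaction '", rx, "' touches ", length(touched),
                " external metabolites; not treated as an exchange")
    }
  }
  methods::new("StoichiometricModel",
    modelID = modelID, stoichiometry = S,
    lowerBounds = lb, upperBounds = ub, gpr = gpr,
    genes = as.character(genes), biomassReaction = biomassReaction,
    exchangeMap = exchangeMap, metComp = metComp,
    externalCompartment = externalCompartment)
}

#' Read a stoichiometric model from file
#'
#' Supports BiGG-style JSON and SBML Level 3 with the flux-bounds (fbc)
#' package. The biomass reaction is taken from the declared objective
#' (JSON: \code{objective_coefficient}; SBML: \code{fbc:listOfObjectives});
#' exchange reactions are auto-detected as single-metabolite boundary
#' reactions of the external compartment when not annotated.
#'
#' @param path file path.
#' @param format "json", "sbml", or "auto" (by file extension).
#' @param externalCompartment compartment id of the medium.
#' @return a \linkS4class{StoichiometricModel}.
#' @seealso \code{\link{writeStoichiometricModel}}
#' @export
readStoichiometricModel <- function(path, format = c("auto", "json", "sbml"),
                                    externalCompartment = "e") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("model file does not exist: ", path)
  switch(format,
    json = .readModelJSON(path, externalCompartment),
    sbml = .readModelSBML(path, externalCompartment))
}

.readModelJSON <- function(path, externalCompartment) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  for (fld in c("metabolites", "reactions"))
    if (is.null(doc[[fld]]))
      stop("format error: missing '", fld, "' element in ", path)
  mets <- vapply(doc$metabolites, function(m) m$id, character(1))
  metComp <- vapply(doc$metabolites, function(m)
    if (!is.null(m$compartment)) m$compartment
    else sub("^.*_", "", m$id), character(1))
  names(metComp) <- mets
  rxns <- vapply(doc$reactions, function(r) r$id, character(1))
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    if (length(r$metabolites)) {
      idx <- match(names(r$metabolites), mets)
      if (anyNA(idx))
        stop("format error: reaction '", r$id,
             "' references unknown metabolite '",
             names(r$metabolites)[which(is.na(idx))[1]], "'")
      ii <- c(ii, idx)
      jj <- c(jj, rep(j, length(idx)))
      xx <- c(xx, as.numeric(unlist(r$metabolites)))
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  lb <- vapply(doc$reactions, function(r) num(r$lower_bound, -1000), numeric(1))
  ub <- vapply(doc$reactions, function(r) num(r$upper_bound, 1000), numeric(1))
  gpr <- vapply(doc$reactions, function(r)
    if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
    character(1))
  obj <- vapply(doc$reactions, function(r)
    num(r$objective_coefficient, 0), numeric(1))
  biomass <- rxns[obj != 0]
  if (length(biomass) != 1L)
    stop("configuration error: model must declare exactly one biomass ",
         "(objective) reaction, found ", length(biomass))
  genes <- if (!is.null(doc$genes))
    vapply(doc$genes, function(g) g$id, character(1)) else NULL
  stoichiometricModel(
    modelID = if (!is.null(doc$id)) doc$id else basename(path),
    stoichiometry = S, lowerBounds = lb, upperBounds = ub, gpr = gpr,
    genes = genes, biomassReaction = biomass, metComp = metComp,
    externalCompartment = externalCompartment)
}

#' Write a stoichiometric model to file
#'
#' Emits BiGG-style JSON or SBML L3 + fbc. Round-trips through
#' \code{\link{readStoichiometricModel}} preserve stoichiometry, bounds
#' and GPR truth tables exactly.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param path output file path.
#' @param format "json" or "sbml".
#' @return \code{path}, invisibly.
#' @export
writeStoichiometricModel <- function(model, path,
                                     format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(.writeModelSBML(model, path))
  S <- model@stoichiometry
  mets <- rownames(S)
  rxns <- colnames(S)
  doc <- list(
    id = model@modelID,
    metabolites = lapply(mets, function(m)
      list(id = m, compartment = model@metComp[[m]])),
    genes = lapply(model@genes, function(g) list(id = g)),
    reactions = lapply(seq_along(rxns), function(j) {
      col <- S[, j]
      nz <- which(col != 0)
      list(id = rxns[j],
           metabolites = as.list(stats::setNames(col[nz], mets[nz])),
           lower_bound = unname(model@lowerBounds[j]),
           upper_bound = unname(model@upperBounds[j]),
           gene_reaction_rule = unname(model@gpr[j]),
           objective_coefficient =
             if (rxns[j] == model@biomassReaction) 1 else 0)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Apply a gene-knockout strain specification to a model
#'
#' Evaluates every GPR rule with the knocked-out genes set to FALSE and
#' sets both flux bounds of the disabled reactions to zero. The input
#' model is not modified. Gene ids absent from the model's gene universe
#' raise a warning and are ignored, so genome-wide sweeps tolerate
#' annotation drift.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @param spec a \linkS4class{StrainSpec} (or character vector of gene
#'   ids, taken as the knockout set).
#' @return a new \linkS4class{StoichiometricModel} with the disabled
#'   reactions closed.
#' @examples
#' toy <- makeCrossfeedModel(toyCrossfeedSpec())
#' provider <- applyKnockout(toy, strainSpec("cat1a", "cat1a"))
#' @export
applyKnockout <- function(model, spec) {
  if (is.character(spec))
    spec <- strainSpec(if (length(spec)) paste(spec, collapse = "+")
                       else "WT", spec)
  ko <- spec@knockouts
  unknown <- setdiff(ko, model@genes)
  if (length(unknown)) {
    warning("unknown gene id(s) ignored for strain '", spec@strainID,
            "': ", paste(unknown, collapse = ", "))
    ko <- setdiff(ko, unknown)
  }
  if (!length(ko)) return(model)
  out <- model
  for (j in which(nzchar(model@gpr))) {
    tree <- parseGPR(model@gpr[[j]])
    if (!evalGPR(tree, ko)) {
      out@lowerBounds[[j]] <- 0
      out@upperBounds[[j]] <- 0
    }
  }
  out
}

#' List the exchange reactions of a model
#'
#' Returns the exchange-reaction map (reaction id -> external
#' metabolite) in stable (reaction-id) order. Boundary reactions
#' touching more than one metabolite are excluded with a warning.
#'
#' @param model a \linkS4class{StoichiometricModel}.
#' @return named character vector.
#' @export
listExchanges <- function(model) {
  ex <- model@exchangeMap
  ex[order(names(ex))]
}

#' Construct a strain specification
#'
#' @param strainID strain name; single-gene knockout strains are
#'   conventionally named after the deleted gene.
#' @param knockouts character vector of knocked-out genes (default
#'   none, i.e. wild-type).
#' @return a \linkS4class{StrainSpec}.
#' @export
strainSpec <- function(strainID, knockouts = character()) {
  methods::new("StrainSpec", strainID = strainID,
               knockouts = as.character(knockouts))
}

#' Construct a growth condition
#'
#' Defaults reproduce the standard batch setting of the package:
#' initial biomass 0.003 gDW/L, 10 mmol/L of the single carbon source,
#' time step 0.1 h.
#'
#' @param carbonSource external metabolite id of the limiting source.
#' @param initialConcentration mmol/L at t = 0 (default 10).
#' @param conditionID identifier (defaults to the carbon source).
#' @param inExcess metabolites never depleted.
#' @param uptakeCaps named numeric, maximal uptake rates (mmol/gDW/h).
#' @param defaultCap cap for metabolites without an entry (default 10).
#' @param initialBiomass gDW/L (default 0.003).
#' @param timeStep hours (default 0.1).
#' @param maxTime hours (default 100).
#' @param muTol growth threshold 1/h (default 1e-6).
#' @return a \linkS4class{GrowthCondition}.
#' @export
growthCondition <- function(carbonSource, initialConcentration = 10,
                            conditionID = carbonSource,
                            inExcess = character(),
                            uptakeCaps = numeric(),
                            defaultCap = 10,
                            initialBiomass = 0.003,
                            timeStep = 0.1, maxTime = 100,
                            muTol = 1e-6) {
  methods::new("GrowthCondition",
    conditionID = conditionID, carbonSource = carbonSource,
    initialConcentration = initialConcentration, inExcess = inExcess,
    uptakeCaps = uptakeCaps, defaultCap = defaultCap,
    initialBiomass = initialBiomass, timeStep = timeStep,
    maxTime = maxTime, muTol = muTol)
}

#' Read a growth condition from a YAML config file
#'
#' The schema mirrors the arguments of \code{\link{growthCondition}};
#' see the example file shipped under
#' \code{system.file("extdata", "condition_glucose.yaml",
#' package = "CrossFeed")}.
#'
#' @param path YAML file path.
#' @return a \linkS4class{GrowthCondition}.
#' @export
readGrowthCondition <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$carbon_source)) stop("config must set carbon_source")
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  caps <- unlist(cfg$uptake_caps)
  caps <- if (is.null(caps)) numeric() else
    stats::setNames(as.numeric(caps), names(caps))
  growthCondition(
    carbonSource = cfg$carbon_source,
    initialConcentration = num(cfg$initial_concentration, 10),
    conditionID = cfg$condition_id %||% cfg$carbon_source,
    inExcess = as.character(cfg$in_excess %||% character()),
    uptakeCaps = caps,
    defaultCap = num(cfg$default_uptake_cap, 10),
    initialBiomass = num(cfg$initial_biomass, 0.003),
    timeStep = num(cfg$time_step, 0.1),
    maxTime = num(cfg$max_time, 100),
    muTol = num(cfg$mu_tol, 1e-6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
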