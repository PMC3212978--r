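#' Tidy table view of a trajectory
#'
#' Long-format table (time, strain, variable, value) of a
#' \linkS4class{BatchTrajectory}: per-strain biomass and growth rate,
#' medium concentrations (strain NA) and per-strain exchange fluxes
#' (variable \code{flux:<metabolite>}).
#'
#' @param traj a \linkS4class{BatchTrajectory}.
#' @return data.frame.
#' @export
trajectoryTable <- function(traj) {
  nt <- length(traj@times)
  rows <- list()
  for (s in traj@strains) {
    rows[[length(rows) + 1L]] <- data.frame(
      time = traj@times, strain = s, variable = "biomass",
      value = traj@biomass[s, ])
    rows[[length(rows) + 1L]] <- data.frame(
      time = traj@times, strain = s, variable = "growth_rate",
      value = traj@growthRates[s, ])
    fx <- traj@exchangeFluxes[[s]]
    for (m in rownames(fx))
      rows[[length(rows) + 1L]] <- data.frame(
        time = traj@times, strain = s,
        variable = paste0("flux:", m), value = fx[m, ])
  }
  for (m in rownames(traj@medium))
    rows[[length(rows) + 1L]] <- data.frame(
      time = traj@times, strain = NA_character_,
      variable = paste0("concentration:", m), value = traj@medium[m, ])
  do.call(rbind, rows)
}

#' Monoculture sweep over a knockout universe
#'
#' Simulates the batch monoculture of the wild-type and of every
#' single-gene knockout strain in \code{genes}, recording viability,
#' endpoint biomass and the by-product profile per strain. Results are
#' cached per strain (content-addressed on model, strain and
#' condition), so re-running with a warm cache performs zero LP solves;
#' solver failures are isolated to their strain and the sweep
#' continues.
#'
#' @param model wild-type \linkS4class{StoichiometricModel}.
#' @param condition a \linkS4class{GrowthCondition}.
#' @param genes knockout universe (default: all model genes).
#' @param includeWildType include the unperturbed strain as
#'   \code{"WT"} (default TRUE).
#' @param cacheDir optional directory for the per-strain cache.
#' @param exclude metabolites never counted as by-products.
#' @param minimizeFlux forwarded to the simulator.
#' @return list with \code{table} (data.frame: strain, viable,
#'   endpoint, nByproducts, error) and \code{profiles} (named list of
#'   \linkS4class{ByproductProfile} for viable strains).
#' @export
sweepKnockouts <- function(model, condition, genes = geneIds(model),
                           includeWildType = TRUE, cacheDir = NULL,
                           exclude = character(), minimizeFlux = TRUE) {
  specs <- lapply(genes, function(g) strainSpec(g, g))
  if (includeWildType) specs <- c(list(strainSpec("WT")), specs)
  if (!is.null(cacheDir) && !dir.exists(cacheDir))
    dir.create(cacheDir, recursive = TRUE)
  rows <- list(); profiles <- list()
  for (sp in specs) {
    key <- rlang::hash(list(model = model, ko = sort(sp@knockouts),
                            condition = condition,
                            exclude = exclude, mf = minimizeFlux))
    cacheFile <- if (!is.null(cacheDir))
      file.path(cacheDir, paste0(key, ".rds")) else NULL
    res <- NULL
    if (!is.null(cacheFile) && file.exists(cacheFile))
      res <- readRDS(cacheFile)
    if (is.null(res)) {
      res <- tryCatch({
        mdl <- applyKnockout(model, sp)
        traj <- simulateMonoculture(mdl, condition,
                                    strainID = sp@strainID,
                                    minimizeFlux = minimizeFlux)
        list(viable = length(traj@times) > 1L,
             endpoint = growthPerformance(traj),
             profile = byproductProfile(traj, sp@strainID, exclude),
             error = NA_character_)
      }, error = function(e)
        list(viable = NA, endpoint = NA_real_, profile = NULL,
             error = conditionMessage(e)))
      if (!is.null(cacheFile)) saveRDS(res, cacheFile)
    }
    rows[[sp@strainID]] <- data.frame(
      strain = sp@strainID, viable = res$viable,
      endpoint = res$endpoint,
      nByproducts = if (is.null(res$profile)) NA_integer_
        else length(res$profile@cmax),
      error = res$error)
    if (isTRUE(res$viable)) profiles[[sp@strainID]] <- res$profile
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       profiles = profiles)
}

#' End-to-end analysis pipeline
#'
#' Orchestrates the full workflow on one growth condition: knockout
#' sweep, diversity graph construction, graph statistics, structural
#' compression, clique-based community identification, and benefit
#' simulation of the leading communities. Artifacts are written as
#' plain-text tables (and GraphML) under \code{outDir} together with a
#' machine-readable manifest carrying the parameters; a stage failure
#' halts downstream stages and leaves a partial manifest.
#'
#' @param model wild-type \linkS4class{StoichiometricModel}.
#' @param condition a \linkS4class{GrowthCondition}.
#' @param outDir output directory (created if needed).
#' @param genes knockout universe (default: all model genes).
#' @param threshold binarization threshold (default 0.6).
#' @param minSize minimum community size (default 2).
#' @param maxCommunities number of communities to simulate for benefit
#'   (default 5).
#' @param attributes optional named numeric node attributes.
#' @param exclude metabolites never counted as by-products.
#' @param cacheDir optional sweep cache directory.
#' @return (invisibly) list with all stage results and the manifest
#'   data.frame.
#' @export
fullPipeline <- function(model, condition, outDir,
                         genes = geneIds(model), threshold = 0.6,
                         minSize = 2L, maxCommunities = 5L,
                         attributes = numeric(),
                         exclude = character(), cacheDir = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list()
  note <- function(stage, artifact, path)
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, artifact = artifact, path = path)
  results <- list()
  writeTSV <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  finish <- function(error = NULL) {
    mf <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(stage = character(), artifact = character(),
                 path = character())
    meta <- list(
      model = model@modelID, condition = condition@conditionID,
      threshold = threshold, minSize = minSize,
      maxCommunities = maxCommunities, muTol = condition@muTol,
      timeStep = condition@timeStep, maxTime = condition@maxTime)
    if (!is.null(error)) meta$error <- error
    jsonlite::write_json(
      list(parameters = meta, artifacts = mf),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    results$manifest <<- mf
  }

  run <- function(expr) tryCatch(list(ok = TRUE, value = expr),
                                 error = function(e)
                                   list(ok = FALSE, error = conditionMessage(e)))

  ## 1. knockout sweep
  st <- run({
    sw <- sweepKnockouts(model, condition, genes = genes,
                         exclude = exclude, cacheDir = cacheDir)
    note("sweep", "monoculture endpoints", writeTSV(sw$table, "sweep.tsv"))
    sw
  })
  if (!st$ok) { finish(st$error); return(invisible(results)) }
  results$sweep <- st$value

  ## 2. diversity graph
  st <- run({
    g <- buildDiversityGraph(results$sweep$profiles,
                             attributes = attributes,
                             conditionID = condition@conditionID)
    note("graph", "weighted diversity graph",
         { p <- file.path(outDir, "diversity.graphml")
           exportGraph(g, p, "graphml"); p })
    note("graph", "edge list", writeTSV({
      W <- edgeWeights(g)
      idx <- which(upper.tri(W), arr.ind = TRUE)
      data.frame(from = nodeIds(g)[idx[, 1]],
                 to = nodeIds(g)[idx[, 2]], weight = W[idx])
    }, "edges.tsv"))
    g
  })
  if (!st$ok) { finish(st$error); return(invisible(results)) }
  results$graph <- st$value

  ## 3. graph statistics
  st <- run({
    g <- results$graph
    bg <- binarize(g, threshold)
    stats <- data.frame(node = nodeIds(g),
                        strength = strengthCentrality(g),
                        clustering = clusteringCoefficient(bg)$local)
    note("stats", "node statistics", writeTSV(stats, "node_stats.tsv"))
    glob <- data.frame(
      statistic = c("centralization", "mean_clustering", "assortativity"),
      value = c(
        if (length(nodeIds(g)) >= 3) networkCentralization(g) else NA,
        clusteringCoefficient(bg)$mean,
        if (length(g@attributes) == length(nodeIds(g)))
          attributeAssortativity(g) else NA))
    note("stats", "network statistics", writeTSV(glob, "network_stats.tsv"))
    list(nodes = stats, network = glob, binary = bg)
  })
  if (!st$ok) { finish(st$error); return(invisible(results)) }
  results$stats <- st$value

  ## 4. compression
  st <- run({
    cg <- compressGraph(results$stats$binary)
    note("compress", "supernode membership", writeTSV(
      data.frame(node = names(cg@membership),
                 supernode = unname(cg@membership)),
      "supernodes.tsv"))
    cg
  })
  if (!st$ok) { finish(st$error); return(invisible(results)) }
  results$compressed <- st$value

  ## 5. communities
  st <- run({
    cms <- cliquesViaCompression(results$stats$binary, minSize = minSize)
    note("communities", "candidate communities", writeTSV(
      if (length(cms)) data.frame(
        community = seq_along(cms),
        size = vapply(cms, function(x) length(members(x)), integer(1)),
        members = vapply(cms, function(x)
          paste(members(x), collapse = ","), character(1)))
      else data.frame(community = integer(), size = integer(),
                      members = character()),
      "communities.tsv"))
    cms
  })
  if (!st$ok) { finish(st$error); return(invisible(results)) }
  results$communities <- st$value

  ## 6. benefits of the largest communities
  st <- run({
    cms <- results$communities
    if (length(cms)) {
      sizes <- vapply(cms, function(x) length(members(x)), integer(1))
      sel <- utils::head(order(-sizes), maxCommunities)
      endpoints <- stats::setNames(results$sweep$table$endpoint,
                                   results$sweep$table$strain)
      strains <- unique(unlist(lapply(cms[sel], members)))
      mdls <- stats::setNames(lapply(strains, function(s)
        applyKnockout(model, if (s == "WT") character() else s)),
        strains)
      bens <- lapply(cms[sel], function(cm)
        communityBenefit(cm, mdls, condition,
                         monoEndpoints = endpoints,
                         allEndpoints = endpoints[
                           names(endpoints) %in% nodeIds(results$graph)]))
      tab <- do.call(rbind, lapply(bens, function(r) data.frame(
        members = paste(members(r), collapse = ","),
        groupEndpoint = r@groupEndpoint,
        relativeBenefit = r@relativeBenefit,
        absoluteBenefit = r@absoluteBenefit,
        interactions = nrow(r@interactions),
        truncated = r@truncated)))
    } else {
      bens <- list()
      tab <- data.frame(members = character())
    }
    note("benefit", "community benefits", writeTSV(tab, "benefits.tsv"))
    bens
  })
  if (!st$ok) { finish(st$error); return(invisible(results)) }
  results$benefits <- st$value

  finish()
  invisible(results)
}
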