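#' By-product secretion profile of a monoculture
#'
#' Extracts the strain's metabolic blueprint from its batch monoculture
#' trajectory: for every secreted metabolite, the maximum concentration
#' it reached in the medium over the run. The primal carbon source and
#' any metabolite on the exclusion list (typically CO2, water, protons
#' for genome-scale models) are omitted, as are metabolites that never
#' appeared.
#'
#' @param traj a monoculture \linkS4class{BatchTrajectory}.
#' @param strainID id to record (defaults to the trajectory's strain).
#' @param exclude metabolite ids never counted as by-products.
#' @return a \linkS4class{ByproductProfile}.
#' @export
byproductProfile <- function(traj, strainID = traj@strains,
                             exclude = character()) {
  if (length(traj@strains) != 1L)
    stop("by-product profiles are monoculture blueprints; got a ",
         length(traj@strains), "-strain trajectory")
  cmax <- apply(traj@medium, 1L, max)
  drop <- c(traj@carbonSource, exclude)
  cmax <- cmax[setdiff(names(cmax), drop)]
  cmax <- cmax[cmax > 0]
  methods::new("ByproductProfile", strainID = strainID[[1L]],
               conditionID = traj@conditionID, cmax = cmax)
}

#' Metabolic-difference edge weight between two strains
#'
#' The maximal relative difference in by-production over the union of
#' the two strains' secreted metabolites:
#' \deqn{w_{ij} = \max_s \frac{|Cmax_i^s - Cmax_j^s|}{\max(Cmax_i^s, Cmax_j^s)}}
#' A metabolite secreted by neither strain contributes 0 (the strains
#' are identical with respect to it); strains with no secreted
#' metabolite at all get weight 0. The weight is 1 exactly when some
#' metabolite is secreted by only one of the two strains (a novel
#' by-product), and 0 exactly when the profiles coincide.
#'
#' @param p,q \linkS4class{ByproductProfile}s from the same growth
#'   condition.
#' @return numeric weight in [0, 1].
#' @examples
#' p <- new("ByproductProfile", strainID = "a", conditionID = "x",
#'          cmax = c(A = 2))
#' q <- new("ByproductProfile", strainID = "b", conditionID = "x",
#'          cmax = c(A = 1))
#' edgeWeight(p, q)  # 0.5
#' @export
edgeWeight <- function(p, q) {
  if (length(p@conditionID) && length(q@conditionID) &&
      !identical(p@conditionID, q@conditionID))
    stop("profiles come from different growth conditions: ",
         p@conditionID, " vs ", q@conditionID)
  mets <- union(names(p@cmax), names(q@cmax))
  if (!length(mets)) return(0)
  w <- 0
  for (m in mets) {
    a <- if (m %in% names(p@cmax)) p@cmax[[m]] else 0
    b <- if (m %in% names(q@cmax)) q@cmax[[m]] else 0
    hi <- max(a, b)
    if (hi > 0) w <- max(w, abs(a - b) / hi)
  }
  w
}

#' Build the diversity graph of a growth condition
#'
#' Complete weighted graph over the viable strains, with
#' \code{\link{edgeWeight}} on every pair. Because the edge weights are
#' ratios of by-production, the graph is independent of the initial
#' concentration of the primal carbon source, giving a unique
#' representation of the metabolic differences per condition.
#'
#' @param profiles named list of \linkS4class{ByproductProfile} (names
#'   = strain ids).
#' @param viability optional named logical; strains marked FALSE are
#'   dropped (default: all viable).
#' @param attributes optional named numeric node attributes (e.g. the
#'   conservation score of the deleted gene).
#' @param conditionID condition id (default: from the first profile).
#' @return a weighted \linkS4class{DiversityGraph}.
#' @export
buildDiversityGraph <- function(profiles, viability = NULL,
                                attributes = numeric(),
                                conditionID = NULL) {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, function(p) p@strainID,
                              character(1))
  if (!is.null(viability)) {
    keep <- names(profiles)[vapply(names(profiles), function(s)
      isTRUE(viability[[s]]), logical(1))]
    profiles <- profiles[keep]
  }
  n <- length(profiles)
  if (n < 2L)
    stop("a diversity graph needs at least 2 viable strains, got ", n)
  nodes <- names(profiles)
  if (is.null(conditionID)) conditionID <- profiles[[1L]]@conditionID
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    w <- edgeWeight(profiles[[i]], profiles[[j]])
    W[i, j] <- W[j, i] <- w
  }
  attrs <- attributes[names(attributes) %in% nodes]
  methods::new("DiversityGraph", conditionID = conditionID,
               nodes = nodes, weights = W, attributes = attrs,
               binary = FALSE, threshold = NA_real_)
}

#' Estimate the diversity graph from single-step FBA
#'
#' Fast construction that replaces the dynamic monoculture simulations
#' with one (flux-minimized) FBA solve per strain at the initial
#' condition: the by-production efficiency of each secreted metabolite
#' -- its secretion flux divided by the primal carbon uptake rate --
#' substitutes for the maximum concentration in the edge-weight ratio.
#' Strains with no growth (or no carbon uptake) are excluded as
#' inviable.
#'
#' @param models named list of \linkS4class{StoichiometricModel}, one
#'   per strain.
#' @param condition a \linkS4class{GrowthCondition}.
#' @param exclude metabolites never counted as by-products.
#' @param attributes optional named numeric node attributes.
#' @param fluxTol fluxes with |v| below this are treated as zero.
#' @return a weighted \linkS4class{DiversityGraph}.
#' @export
fastGraphFromFBA <- function(models, condition, exclude = character(),
                             attributes = numeric(), fluxTol = 1e-9) {
  stopifnot(!is.null(names(models)))
  medium0 <- stats::setNames(condition@initialConcentration,
                             condition@carbonSource)
  profiles <- list()
  for (s in names(models)) {
    mdl <- models[[s]]
    exMap <- listExchanges(mdl)
    ub <- stepUptakeBounds(medium0, condition@initialBiomass,
                           condition@timeStep, condition, exMap)
    sol <- solveFBA(mdl, ub, minimizeFlux = TRUE)
    if (sol@status != "optimal" || sol@mu <= condition@muTol) next
    vex <- stats::setNames(sol@fluxes[names(exMap)], unname(exMap))
    upt <- -vex[[condition@carbonSource]]
    if (is.na(upt) || upt <= fluxTol) next
    sec <- vex[vex > fluxTol]
    sec <- sec[setdiff(names(sec),
                       c(condition@carbonSource, exclude))]
    profiles[[s]] <- methods::new("ByproductProfile", strainID = s,
                                  conditionID = condition@conditionID,
                                  cmax = sec / upt)
  }
  buildDiversityGraph(profiles, attributes = attributes,
                      conditionID = condition@conditionID)
}

#' Threshold a weighted diversity graph
#'
#' Keeps an edge when its weight is at least \code{threshold}
#' (inclusive comparison, so the conventional threshold 0.6 keeps
#' weight-0.6 edges). Connected strains in the binary graph are
#' strains of relatively high metabolic difference.
#'
#' @param g a weighted \linkS4class{DiversityGraph}.
#' @param threshold in (0, 1], default 0.6.
#' @return a binary \linkS4class{DiversityGraph}.
#' @export
binarize <- function(g, threshold = 0.6) {
  stopifnot(threshold > 0, threshold <= 1)
  W <- ifelse(g@weights >= threshold, 1, 0)
  diag(W) <- 0
  dimnames(W) <- dimnames(g@weights)
  methods::new("DiversityGraph", conditionID = g@conditionID,
               nodes = g@nodes, weights = W, attributes = g@attributes,
               binary = TRUE, threshold = threshold)
}

## internal igraph view of a diversity graph
.asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(
    g@weights, mode = "undirected",
    weighted = if (g@binary) NULL else TRUE, diag = FALSE)
}

#' Normalized strength centrality
#'
#' Node strength (sum of incident edge weights) normalized by the
#' maximum attainable n - 1, so values lie in [0, 1]. In a diversity
#' graph a high-strength node is a strain of unique by-production; a
#' low-strength node is metabolically redundant.
#'
#' @param g a \linkS4class{DiversityGraph} (weighted or binary).
#' @return named numeric in [0, 1] per node.
#' @export
strengthCentrality <- function(g) {
  n <- length(g@nodes)
  if (n < 2L) stop("strength centrality needs at least 2 nodes")
  rowSums(g@weights) / (n - 1)
}

#' Freeman-style network centralization of strengths
#'
#' \eqn{\sum_i (c_{max} - c_i) / (n - 2)} over the normalized strength
#' centralities: 1 for a binary star (one maximally central node, all
#' others minimally), 0 for any regular graph.
#'
#' @param g a \linkS4class{DiversityGraph}.
#' @return numeric in [0, 1].
#' @export
networkCentralization <- function(g) {
  n <- length(g@nodes)
  if (n < 3L) stop("network centralization needs at least 3 nodes")
  cs <- strengthCentrality(g)
  sum(max(cs) - cs) / (n - 2)
}

#' Local clustering coefficients of a binary diversity graph
#'
#' Watts-Strogatz local coefficient (fraction of realized edges among a
#' node's neighbors); nodes with degree below 2 get 0. The network
#' value is the mean over nodes and reflects the cliquishness of
#' neighborhoods.
#'
#' @param bg a binary \linkS4class{DiversityGraph}.
#' @return list with \code{local} (named numeric) and \code{mean}.
#' @export
clusteringCoefficient <- function(bg) {
  stopifnot(bg@binary)
  loc <- igraph::transitivity(.asIgraph(bg), type = "local",
                              isolates = "zero")
  names(loc) <- bg@nodes
  loc[is.nan(loc)] <- 0
  list(local = loc, mean = mean(loc))
}

#' Attribute assortativity of a diversity graph
#'
#' Pearson correlation of a scalar node attribute over the endpoints of
#' every edge, each edge counted in both orientations; in the weighted
#' variant the edge weight acts as a multiplicity. Positive values mean
#' strains of similar attribute (e.g. gene conservation) are
#' preferentially connected; negative values mean dissimilar strains
#' connect.
#'
#' @param g a \linkS4class{DiversityGraph}.
#' @param attributes named numeric per node (default: the graph's own
#'   node attributes); must cover every non-isolated node.
#' @param weighted use edge weights as multiplicities (default: TRUE
#'   for weighted graphs).
#' @return correlation in [-1, 1]; NA with a warning when the
#'   attribute has zero variance over edge endpoints.
#' @export
attributeAssortativity <- function(g, attributes = NULL,
                                   weighted = !g@binary) {
  if (is.null(attributes)) attributes <- g@attributes
  W <- g@weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("assortativity needs at least one edge")
  ends <- unique(c(g@nodes[idx[, 1]], g@nodes[idx[, 2]]))
  miss <- setdiff(ends, names(attributes))
  if (length(miss))
    stop("attributes missing for node(s): ", paste(miss, collapse = ", "))
  x <- attributes[g@nodes[idx[, 1]]]
  y <- attributes[g@nodes[idx[, 2]]]
  wt <- if (weighted) W[idx] else rep(1, nrow(idx))
  ## both orientations
  xx <- c(x, y); yy <- c(y, x); ww <- c(wt, wt)
  mx <- sum(ww * xx) / sum(ww)
  my <- sum(ww * yy) / sum(ww)
  vx <- sum(ww * (xx - mx)^2)
  vy <- sum(ww * (yy - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("attribute variance over edge endpoints is zero; ",
            "assortativity undefined")
    return(NA_real_)
  }
  sum(ww * (xx - mx) * (yy - my)) / sqrt(vx * vy)
}

#' Conservation density along an ordered strain list
#'
#' Sliding summary used to relate centrality to gene conservation:
#' strains are taken in the given order (e.g. by frequency of
#' centrality across conditions), cut into non-overlapping windows of
#' \code{window} strains, and each window reports the percentage of
#' strains whose attribute exceeds \code{attrThreshold}. A trailing
#' partial window is reported with its actual size.
#'
#' @param orderedStrains character vector in presentation order.
#' @param attributes named numeric (e.g. per-gene conservation index).
#' @param window window size (default 10).
#' @param attrThreshold attribute cutoff (default 0.7, strict
#'   comparison).
#' @return data.frame with columns \code{window}, \code{from},
#'   \code{to}, \code{size}, \code{density} (percent).
#' @export
conservationDensity <- function(orderedStrains, attributes,
                                window = 10L, attrThreshold = 0.7) {
  stopifnot(window >= 1L)
  miss <- setdiff(orderedStrains, names(attributes))
  if (length(miss))
    stop("attributes missing for strain(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  n <- length(orderedStrains)
  starts <- seq.int(1L, n, by = window)
  rows <- lapply(seq_along(starts), function(k) {
    from <- starts[k]
    to <- min(from + window - 1L, n)
    vals <- attributes[orderedStrains[from:to]]
    data.frame(window = k, from = from, to = to, size = to - from + 1L,
               density = 100 * mean(vals > attrThreshold))
  })
  do.call(rbind, rows)
}

#' Export a diversity graph
#'
#' GraphML (weights and node attributes preserved) via igraph, or a
#' plain edge-list TSV.
#'
#' @param g a \linkS4class{DiversityGraph}.
#' @param path output file.
#' @param format "graphml" or "tsv".
#' @return \code{path}, invisibly.
#' @export
exportGraph <- function(g, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- .asIgraph(g)
    if (length(g@attributes))
      ig <- igraph::set_vertex_attr(ig, "attribute",
        value = unname(g@attributes[g@nodes]))
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    W <- g@weights
    idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    df <- data.frame(from = g@nodes[idx[, 1]], to = g@nodes[idx[, 2]],
                     weight = W[idx])
    df <- df[order(df$from, df$to), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Compress a binary diversity graph by structural equivalence
#'
#' Merges metabolically redundant strains: nodes with identical binary
#' neighborhoods (necessarily mutually non-adjacent) map onto one
#' supernode. The quotient adjacency is well defined because
#' equivalence classes connect all-or-none, and cliques of the quotient
#' correspond exactly to cliques of the original graph with one
#' representative per supernode.
#'
#' @param bg a binary \linkS4class{DiversityGraph}.
#' @return a \linkS4class{CompressedGraph}; supernodes are named
#'   \code{s_<lexicographically smallest member>}.
#' @export
compressGraph <- function(bg) {
  stopifnot(bg@binary)
  A <- bg@weights > 0
  nodes <- bg@nodes
  sig <- vapply(seq_along(nodes), function(i)
    paste(nodes[A[i, ]], collapse = "|"), character(1))
  classes <- split(nodes, sig)
  reps <- vapply(classes, function(m) min(m), character(1))
  ord <- order(reps)
  classes <- classes[ord]
  ids <- paste0("s_", reps[ord])
  names(classes) <- ids
  membership <- stats::setNames(rep(ids, lengths(classes)),
                                unlist(classes, use.names = FALSE))
  k <- length(classes)
  Q <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    Q[i, j] <- A[classes[[i]][1L], classes[[j]][1L]]
  }
  methods::new("CompressedGraph", membership = membership,
               supernodes = classes, quotient = Q,
               conditionID = bg@conditionID)
}
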