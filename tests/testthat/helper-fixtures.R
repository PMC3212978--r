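# Shared fixtures, memoized so expensive simulations run once per
# test session.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fxToy <- function() fxMemo("toy", makeCrossfeedModel(toyCrossfeedSpec()))
fxTriplet <- function() fxMemo("tri", makeCrossfeedModel(toyTripletSpec()))
fxBi <- function() fxMemo("bi", makeCrossfeedModel(toyBidirectionalSpec()))

fxCond <- function(C0 = 10, ...) growthCondition("src_e",
  initialConcentration = C0, conditionID = "src", ...)

fxKO <- function(model, genes, id = paste(genes, collapse = "+")) {
  if (!length(genes)) return(model)
  applyKnockout(model, strainSpec(id, genes))
}

# knockout strains of the provider/consumer model
fxProvider <- function() fxMemo("prov", fxKO(fxToy(), "cat1a"))
fxProvider2 <- function() fxMemo("prov2", fxKO(fxToy(), "cat1b"))
fxConsumer <- function() fxMemo("cons", fxKO(fxToy(), "srcA"))

fxTraj <- function(key, model, C0 = 10, id = key, ...) {
  fxMemo(paste0("traj_", key, "_", C0),
         simulateMonoculture(model, fxCond(C0, ...), strainID = id))
}
fxTrajWT <- function(C0 = 10) fxTraj("WT", fxToy(), C0)
fxTrajProv <- function(C0 = 10) fxTraj("prov", fxProvider(), C0)
fxTrajProv2 <- function(C0 = 10) fxTraj("prov2", fxProvider2(), C0)
fxTrajCons <- function(C0 = 10) fxTraj("cons", fxConsumer(), C0)

# the three-strain set used for graph fixtures: two bit-identical
# providers (different subunits of the same catabolic complex) plus
# the secretion-free consumer
fxGraphProfiles <- function(C0 = 10) fxMemo(paste0("gprof_", C0), {
  trajs <- list(p1 = fxTrajProv(C0), p2 = fxTrajProv2(C0),
                q = fxTrajCons(C0))
  lapply(names(trajs), function(s) {
    byproductProfile(trajs[[s]], s)
  }) |> stats::setNames(names(trajs))
})
fxGraph <- function(C0 = 10) fxMemo(paste0("graph_", C0),
  buildDiversityGraph(fxGraphProfiles(C0), conditionID = "src"))

# triplet strains (indirect benefit): two non-interacting producers and
# a scavenger needing both by-products
fxTripletModels <- function() fxMemo("trimods", list(
  A = fxKO(fxTriplet(), c("srcB", "catP"), "A"),
  B = fxKO(fxTriplet(), c("srcA", "catP"), "B"),
  C = fxKO(fxTriplet(), c("srcA", "srcB"), "C")))

fxTripletMonos <- function() fxMemo("trimono", {
  mods <- fxTripletModels()
  vapply(names(mods), function(s)
    growthPerformance(simulateMonoculture(mods[[s]], fxCond(), s)),
    numeric(1))
})

fxPairCoculture <- function() fxMemo("paircc", {
  cond <- fxCond()
  simulateCoculture(list(prov = fxProvider(), cons = fxConsumer()),
                    rep(cond@initialBiomass / 2, 2), cond)
})

# ---- independent clique oracle: exhaustive subset enumeration -------
# Dynamic program over all 2^n subsets encoded as bitmasks:
# a set S with lowest element v is a clique iff S \ {v} is a clique
# contained in the neighborhood of v.
bruteCliques <- function(W) {
  A <- W > 0
  n <- nrow(A)
  stopifnot(n <= 16)
  nodes <- rownames(A)
  adjMask <- vapply(seq_len(n), function(i)
    sum(bitwShiftL(1L, which(A[i, ]) - 1L)), numeric(1))
  total <- bitwShiftL(1L, n)
  isClique <- logical(total)
  isClique[1L] <- TRUE                     # empty set
  popcnt <- integer(total)
  for (S in seq_len(total - 1L)) {
    low <- bitwAnd(S, -S)
    v <- as.integer(round(log2(low))) + 1L
    Sp <- S - low
    isClique[S + 1L] <- isClique[Sp + 1L] &&
      bitwAnd(adjMask[v], Sp) == Sp
    popcnt[S + 1L] <- popcnt[Sp + 1L] + 1L
  }
  cliqueSets <- which(isClique) - 1L
  maxSize <- max(popcnt[cliqueSets + 1L])
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  maximal <- list()
  for (S in cliqueSets) {
    if (S == 0L) next
    isMax <- TRUE
    for (v in seq_len(n)) {
      if (bitwAnd(S, bits[v]) == 0L && isClique[bitwOr(S, bits[v]) + 1L]) {
        isMax <- FALSE
        break
      }
    }
    if (isMax)
      maximal[[length(maximal) + 1L]] <- sort(nodes[bitwAnd(S, bits) > 0L])
  }
  maximal <- maximal[order(vapply(maximal, paste, character(1),
                                  collapse = "|"))]
  list(maxSize = maxSize, maximal = maximal)
}
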