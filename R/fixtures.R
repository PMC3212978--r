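#' Specification for a toy cross-feeding model
#'
#' Builds the parameter object for \code{\link{makeCrossfeedModel}}.
#' The default spec generates the canonical provider/consumer fixture:
#' an efficient catabolic route (\code{srcA}, yield 0.1 gDW/mmol) that
#' obligately secretes 0.5 mmol of the by-product \code{bp1} per mmol
#' source, a clean but inefficient alternative route (\code{srcB},
#' yield 0.05), and by-product catabolism (yield 0.1) gated by the
#' two-subunit rule \code{"cat1a and cat1b"} -- so knocking out either
#' subunit gives a pure provider, knocking out \code{srcA} gives a
#' slower secretion-free strain that can still consume the by-product,
#' and the wild-type re-consumes its own by-product (diauxic-like
#' two-phase growth). Catabolism carries a flux capacity (\code{cap},
#' mmol/gDW/h): the overflow-metabolism abstraction that forces net
#' secretion while the source is plentiful instead of instantaneous
#' internal recycling.
#'
#' @param sourceID source metabolite base id (default "src"; the
#'   external species is \code{src_e}).
#' @param routes data.frame(id, gene, yield, byproduct, secretion);
#'   \code{gene} may be any GPR expression.
#' @param catabolism data.frame(byproduct, gene, yield, cap); \code{cap}
#'   is the maximal catabolic flux (overflow capacity).
#' @param pairCatabolism empty list or list(byproducts = c(a, b),
#'   gene =, yield =) for 1:1 coupled consumption of two by-products.
#' @param modelID id of the generated model.
#' @return a \linkS4class{ToyModelSpec}.
#' @export
toyCrossfeedSpec <- function(
    sourceID = "src",
    routes = data.frame(
      id = c("srcA", "srcB"),
      gene = c("srcA", "srcB"),
      yield = c(0.10, 0.05),
      byproduct = c("bp1", NA),
      secretion = c(0.5, 0),
      stringsAsFactors = FALSE),
    catabolism = data.frame(
      byproduct = "bp1",
      gene = "cat1a and cat1b",
      yield = 0.1,
      cap = 2,
      stringsAsFactors = FALSE),
    pairCatabolism = list(),
    modelID = "toy_crossfeed") {
  methods::new("ToyModelSpec", sourceID = sourceID, routes = routes,
               catabolism = catabolism, pairCatabolism = pairCatabolism,
               modelID = modelID)
}

#' Spec of the two-by-product fixture with coupled catabolism
#'
#' Two equally efficient source routes each secreting a different
#' by-product, and a coupled catabolic reaction that only runs on both
#' by-products together (1:1). Knockouts generate the indirect-benefit
#' triplet: two producers that do not interact with each other and a
#' scavenger that is inviable alone, non-beneficial with either
#' producer, but beneficial with both.
#'
#' @inheritParams toyCrossfeedSpec
#' @param pairYield biomass yield of the coupled catabolism (gDW per
#'   mmol of each by-product consumed).
#' @export
toyTripletSpec <- function(pairYield = 0.12, modelID = "toy_triplet") {
  toyCrossfeedSpec(
    routes = data.frame(
      id = c("srcA", "srcB"),
      gene = c("srcA", "srcB"),
      yield = c(0.10, 0.10),
      byproduct = c("bp1", "bp2"),
      secretion = c(0.5, 0.5),
      stringsAsFactors = FALSE),
    catabolism = data.frame(byproduct = character(), gene = character(),
                            yield = numeric(), cap = numeric(),
                            stringsAsFactors = FALSE),
    pairCatabolism = list(byproducts = c("bp1", "bp2"), gene = "catP",
                          yield = pairYield),
    modelID = modelID)
}

#' Spec of the bi-directional exchange fixture
#'
#' Two source routes secreting different by-products plus independent
#' catabolism of each, so the complementary double knockouts
#' (\code{srcB+cat1} vs \code{srcA+cat2}) exchange their by-products in
#' both directions.
#'
#' @inheritParams toyCrossfeedSpec
#' @export
toyBidirectionalSpec <- function(modelID = "toy_bidirectional") {
  toyCrossfeedSpec(
    routes = data.frame(
      id = c("srcA", "srcB"),
      gene = c("srcA", "srcB"),
      yield = c(0.10, 0.10),
      byproduct = c("bp1", "bp2"),
      secretion = c(0.5, 0.5),
      stringsAsFactors = FALSE),
    catabolism = data.frame(
      byproduct = c("bp1", "bp2"),
      gene = c("cat1", "cat2"),
      yield = c(0.1, 0.1),
      cap = c(1000, 1000),
      stringsAsFactors = FALSE),
    modelID = modelID)
}

#' Generate a toy cross-feeding stoichiometric model
#'
#' Builds the small stoichiometric network described by a
#' \linkS4class{ToyModelSpec}: source exchange and transport, gene-gated
#' catabolic routes producing biomass precursor and (directly secreted)
#' by-products, per-by-product uptake and catabolism, and a biomass
#' reaction. Endpoint biomasses of its knockout strains follow
#' closed-form mass balances (initial biomass + yield x substrate),
#' which is what makes the fixture analytically checkable.
#'
#' @param spec a \linkS4class{ToyModelSpec}.
#' @return a validated \linkS4class{StoichiometricModel} whose
#'   wild-type grows on the source (validation error otherwise).
#' @examples
#' toy <- makeCrossfeedModel(toyCrossfeedSpec())
#' reactionIds(toy)
#' @export
makeCrossfeedModel <- function(spec) {
  methods::validObject(spec)
  src_e <- paste0(spec@sourceID, "_e")
  src_c <- paste0(spec@sourceID, "_c")
  bps <- unique(stats::na.omit(c(spec@routes$byproduct,
                                 spec@catabolism$byproduct,
                                 if (length(spec@pairCatabolism))
                                   spec@pairCatabolism$byproducts)))
  mets <- c(src_e, src_c, "P_c",
            paste0(bps, "_e"), paste0(bps, "_c"))
  rxns <- character(); lb <- numeric(); ub <- numeric(); gpr <- character()
  tripl <- list()  # (met, rxn, coef)
  addRxn <- function(id, stoich, lower, upper, rule = "") {
    rxns <<- c(rxns, id); lb <<- c(lb, lower); ub <<- c(ub, upper)
    gpr <<- c(gpr, rule)
    for (m in names(stoich))
      tripl[[length(tripl) + 1L]] <<- list(m = m, r = id, x = stoich[[m]])
  }
  addRxn(paste0("EX_", src_e), stats::setNames(-1, src_e), -1000, 1000)
  addRxn(paste0("T_", spec@sourceID),
         stats::setNames(c(-1, 1), c(src_e, src_c)), 0, 1000)
  for (k in seq_len(nrow(spec@routes))) {
    r <- spec@routes[k, ]
    st <- stats::setNames(c(-1, r$yield), c(src_c, "P_c"))
    if (!is.na(r$byproduct))
      st[paste0(r$byproduct, "_e")] <- r$secretion
    addRxn(r$id, st, 0, 1000, r$gene)
  }
  for (b in bps) {
    addRxn(paste0("EX_", b, "_e"),
           stats::setNames(-1, paste0(b, "_e")), -1000, 1000)
    addRxn(paste0("U_", b),
           stats::setNames(c(-1, 1), paste0(b, c("_e", "_c"))), 0, 1000)
  }
  if (nrow(spec@catabolism))
    for (k in seq_len(nrow(spec@catabolism))) {
      ct <- spec@catabolism[k, ]
      addRxn(paste0("C_", ct$byproduct),
             stats::setNames(c(-1, ct$yield),
                             c(paste0(ct$byproduct, "_c"), "P_c")),
             0, if ("cap" %in% names(ct)) ct$cap else 1000, ct$gene)
    }
  if (length(spec@pairCatabolism)) {
    pc <- spec@pairCatabolism
    addRxn("C_pair",
           stats::setNames(c(-1, -1, pc$yield),
                           c(paste0(pc$byproducts, "_c"), "P_c")),
           0, 1000, pc$gene)
  }
  addRxn("BIOMASS", stats::setNames(-1, "P_c"), 0, 1000)

  S <- Matrix::sparseMatrix(
    i = match(vapply(tripl, `[[`, character(1), "m"), mets),
    j = match(vapply(tripl, `[[`, character(1), "r"), rxns),
    x = vapply(tripl, `[[`, numeric(1), "x"),
    dims = c(length(mets), length(rxns)),
    dimnames = list(mets, rxns))
  mdl <- stoichiometricModel(
    modelID = spec@modelID, stoichiometry = S,
    lowerBounds = stats::setNames(lb, rxns),
    upperBounds = stats::setNames(ub, rxns),
    gpr = stats::setNames(gpr, rxns),
    biomassReaction = "BIOMASS")
  wt <- maximizeGrowth(mdl, stats::setNames(-1, paste0("EX_", src_e)))
  if (wt@status != "optimal" || wt@mu <= 0)
    stop("invalid toy spec: the wild-type cannot grow on the source")
  mdl
}

#' Seeded random binary graph with a planted clique
#'
#' Erdos-Renyi G(n, p) graph with an optional planted clique, used to
#' exercise the exact clique search against exhaustive oracles.
#' Regenerating with the same arguments is bit-identical.
#'
#' @param n number of nodes.
#' @param edgeProb edge probability.
#' @param plantedCliqueSize size of the planted clique (0 = none).
#' @param seed RNG seed.
#' @return a binary \linkS4class{DiversityGraph} with nodes
#'   \code{n01, n02, ...}.
#' @export
makeRandomGraph <- function(n, edgeProb = 0.3, plantedCliqueSize = 0L,
                            seed = 1L) {
  stopifnot(plantedCliqueSize <= n)
  nodes <- sprintf("n%02d", seq_len(n))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < edgeProb)
  if (plantedCliqueSize >= 2L) {
    sel <- sample.int(n, plantedCliqueSize)
    A[sel, sel] <- 1
  }
  A[lower.tri(A)] <- 0
  A <- A + t(A)
  A[A > 1] <- 1
  diag(A) <- 0
  methods::new("DiversityGraph", conditionID = "random",
               nodes = nodes, weights = A, binary = TRUE,
               threshold = 0.6)
}

#' The four-node worked-example graph
#'
#' Strains v, u, k, m with u adjacent to all, k adjacent to u and m,
#' and v adjacent to u only: v and k are metabolically similar
#' (interchangeable partners for u), while u, k, m are pairwise
#' different and form the size-3 community.
#'
#' @return a binary \linkS4class{DiversityGraph}.
#' @export
makeFigure1Graph <- function() {
  nodes <- c("v", "u", "k", "m")
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  edges <- rbind(c("v", "u"), c("u", "k"), c("u", "m"), c("k", "m"))
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  methods::new("DiversityGraph", conditionID = "worked-example",
               nodes = nodes, weights = A, binary = TRUE,
               threshold = 0.6)
}
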