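profileOf <- function(cmax, id = "p", cond = "src") {
  new("ByproductProfile", strainID = id, conditionID = cond,
      cmax = cmax)
}

test_that("by-product profiles extract peak concentrations", {
  # strain that never secretes -> empty map
  expect_length(byproductProfile(fxTrajCons())@cmax, 0L)
  # the primal source is excluded
  expect_false("src_e" %in% names(byproductProfile(fxTrajWT())@cmax))
  # the provider's by-product peak equals its total secretion
  prof <- byproductProfile(fxTrajProv())
  expect_equal(unname(prof@cmax[["bp1_e"]]), 0.5 * 10, tolerance = 0.01)
  # explicit exclusion list is honored
  expect_length(byproductProfile(fxTrajProv(), exclude = "bp1_e")@cmax, 0L)
  # co-culture trajectories are rejected
  expect_error(byproductProfile(fxPairCoculture()), "monoculture")
})

test_that("a single secretion step matches the exponential integral", {
  traj <- fxTrajWT()
  dt <- diff(traj@times)[1]
  v <- traj@exchangeFluxes[[1]]["bp1_e", 1]
  mu <- traj@growthRates[1, 1]
  b0 <- traj@biomass[1, 1]
  expect_equal(traj@medium["bp1_e", 2],
               v * b0 * (exp(mu * dt) - 1) / mu, tolerance = 1e-10)
})

test_that("edge weights satisfy the ratio identities", {
  expect_identical(edgeWeight(profileOf(c(A = 2, B = 1)),
                              profileOf(c(A = 2, B = 1), "q")), 0)
  # novel by-product on one side -> weight 1
  expect_identical(edgeWeight(profileOf(c(A = 2)),
                              profileOf(c(A = 2, B = 0.01), "q")), 1)
  expect_equal(edgeWeight(profileOf(c(A = 2)),
                          profileOf(c(A = 1), "q")), 0.5)
  # strains with no secretion at all are identical
  expect_identical(edgeWeight(profileOf(numeric()),
                              profileOf(numeric(), "q")), 0)
  # profiles from different conditions are rejected
  expect_error(edgeWeight(profileOf(c(A = 1)),
                          profileOf(c(A = 1), "q", "other")),
               "different growth conditions")
})

test_that("edge weights are symmetric and in range on fixture pairs", {
  set.seed(7)
  for (i in 1:20) {
    nA <- sample(0:3, 1); nB <- sample(0:3, 1)
    mets <- c("m1", "m2", "m3")
    p <- profileOf(stats::setNames(runif(nA, 0, 5), sample(mets, nA)))
    q <- profileOf(stats::setNames(runif(nB, 0, 5), sample(mets, nB)), "q")
    w <- edgeWeight(p, q)
    expect_identical(w, edgeWeight(q, p))
    expect_gte(w, 0); expect_lte(w, 1)
    oneSided <- length(setdiff(names(p@cmax), names(q@cmax))) > 0 ||
      length(setdiff(names(q@cmax), names(p@cmax))) > 0
    expect_identical(w == 1, oneSided)
  }
})

test_that("the fixture graph has the expected weights and nodes", {
  g <- fxGraph()
  W <- edgeWeights(g)
  expect_identical(unname(W["p1", "p2"]), 0)   # identical providers
  expect_identical(unname(W["p1", "q"]), 1)    # novel by-product
  expect_identical(unname(W["p2", "q"]), 1)
  expect_true(validObject(g))
})

test_that("too few viable strains is a domain error", {
  profs <- fxGraphProfiles()
  expect_error(buildDiversityGraph(profs,
    viability = c(p1 = TRUE, p2 = FALSE, q = FALSE)), "at least 2")
})

test_that("the diversity graph is invariant to the initial source amount", {
  expect_identical(edgeWeights(fxGraph(10)), edgeWeights(fxGraph(20)))
})

test_that("single-step FBA construction reproduces the dynamic binary graph", {
  mods <- list(p1 = fxProvider(), p2 = fxProvider2(), q = fxConsumer())
  gf <- fastGraphFromFBA(mods, fxCond())
  expect_identical(edgeWeights(binarize(gf, 0.6)),
                   edgeWeights(binarize(fxGraph(), 0.6)))
  # by-production efficiencies are invariant to the uptake cap
  gf5 <- fastGraphFromFBA(mods, fxCond(defaultCap = 5))
  expect_identical(edgeWeights(gf5), edgeWeights(gf))
  # a strain that cannot take up carbon is excluded as inviable
  mods$dead <- fxKO(fxToy(), c("srcA", "srcB"), "dead")
  expect_false("dead" %in% nodeIds(fastGraphFromFBA(mods, fxCond())))
})

test_that("binarization keeps boundary weights and is locally robust", {
  profs <- list(a = profileOf(c(A = 2), "a"), b = profileOf(c(A = 1), "b"),
                c = profileOf(numeric(), "c"))
  g <- buildDiversityGraph(profs, conditionID = "src")
  # weights are exactly {0.5, 1, 1}
  bg <- binarize(g, 0.6)
  expect_identical(unname(edgeWeights(bg)["a", "b"]), 0)
  expect_identical(unname(edgeWeights(bg)["a", "c"]), 1)
  # w = threshold is kept (inclusive comparison)
  expect_identical(unname(edgeWeights(binarize(g, 0.5))["a", "b"]), 1)
  # identical binary graphs for thresholds between the weight levels
  expect_identical(edgeWeights(binarize(g, 0.55)),
                   edgeWeights(binarize(g, 0.65)))
  expect_error(binarize(g, 0), "> 0")
})

test_that("structural compression groups identical neighborhoods", {
  # star: hub plus one leaf class
  star <- makeRandomGraph(6, edgeProb = 0)
  W <- edgeWeights(star); W[1, 2:6] <- 1; W[2:6, 1] <- 1
  starG <- new("DiversityGraph", conditionID = "star",
               nodes = nodeIds(star), weights = W, binary = TRUE,
               threshold = 0.6)
  cg <- compressGraph(starG)
  expect_length(cg@supernodes, 2L)
  expect_setequal(lengths(cg@supernodes), c(1L, 5L))
  # edgeless graph -> a single supernode
  cgE <- compressGraph(makeRandomGraph(5, edgeProb = 0))
  expect_length(cgE@supernodes, 1L)
  # fixture: the two identical providers merge, the consumer does not
  cgF <- compressGraph(binarize(fxGraph(), 0.6))
  expect_setequal(unname(cgF@membership[c("p1", "p2")]),
                  unname(cgF@membership["p1"]))
  expect_false(cgF@membership[["q"]] == cgF@membership[["p1"]])
})

test_that("compression is sound: quotient edges expand to original edges", {
  for (seed in 1:10) {
    bg <- makeRandomGraph(10, edgeProb = 0.35, seed = seed)
    cg <- compressGraph(bg)
    A <- edgeWeights(bg) > 0
    ids <- names(cg@supernodes)
    for (i in ids) for (j in ids) {
      if (i == j) {
        # members of a supernode are mutually non-adjacent
        mem <- cg@supernodes[[i]]
        if (length(mem) > 1)
          expect_true(all(!A[mem, mem]))
      } else {
        block <- A[cg@supernodes[[i]], cg@supernodes[[j]], drop = FALSE]
        expect_true(all(block == cg@quotient[i, j]))  # all-or-none
      }
    }
  }
})

test_that("strength centrality is the normalized row strength", {
  # 3-node path with weights 0.5: center 0.5, ends 0.25
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.5
  g <- new("DiversityGraph", conditionID = "p", nodes = c("a", "b", "c"),
           weights = W)
  expect_equal(strengthCentrality(g),
               c(a = 0.25, b = 0.5, c = 0.25))
  # isolated node -> 0; fully connected unit-weight node -> 1
  W2 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W2["a", c("b", "c")] <- 1; W2[c("b", "c"), "a"] <- 1
  g2 <- new("DiversityGraph", conditionID = "p",
            nodes = c("a", "b", "c"), weights = W2)
  expect_identical(unname(strengthCentrality(g2)[["a"]]), 1)
})

test_that("network centralization separates stars from regular graphs", {
  star <- local({
    W <- matrix(0, 5, 5, dimnames = rep(list(paste0("n", 1:5)), 2))
    W[1, 2:5] <- 1; W[2:5, 1] <- 1
    new("DiversityGraph", conditionID = "s", nodes = paste0("n", 1:5),
        weights = W, binary = TRUE, threshold = 0.6)
  })
  expect_equal(networkCentralization(star), 1)
  triangle <- local({
    W <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
    diag(W) <- 0
    new("DiversityGraph", conditionID = "t", nodes = c("a", "b", "c"),
        weights = W, binary = TRUE, threshold = 0.6)
  })
  expect_equal(networkCentralization(triangle), 0)
  # 4-node weighted fixture against direct arithmetic
  W <- matrix(0, 4, 4, dimnames = rep(list(c("a", "b", "c", "d")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["a", "c"] <- W["c", "a"] <- 0.7
  W["c", "d"] <- W["d", "c"] <- 0.2
  g <- new("DiversityGraph", conditionID = "f",
           nodes = c("a", "b", "c", "d"), weights = W)
  cs <- c(a = (0.9 + 0.7) / 3, b = 0.9 / 3, c = (0.7 + 0.2) / 3,
          d = 0.2 / 3)
  expect_equal(networkCentralization(g), sum(max(cs) - cs) / 2,
               tolerance = 1e-12)
  expect_error(networkCentralization(triangle <- new("DiversityGraph",
    conditionID = "x", nodes = c("a", "b"),
    weights = matrix(0, 2, 2, dimnames = rep(list(c("a", "b")), 2)))),
    "at least 3")
})

test_that("clustering coefficients match an exhaustive triangle count", {
  tri <- local({
    W <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
    diag(W) <- 0
    new("DiversityGraph", conditionID = "t", nodes = c("a", "b", "c"),
        weights = W, binary = TRUE, threshold = 0.6)
  })
  expect_equal(unname(clusteringCoefficient(tri)$local), rep(1, 3))
  star <- makeFigure1Graph()  # u is a hub with one closed pair (k, m)
  cc <- clusteringCoefficient(star)
  # independent oracle: count adjacent neighbor pairs per node
  A <- edgeWeights(star) > 0
  oracle <- vapply(nodeIds(star), function(v) {
    nb <- nodeIds(star)[A[v, ]]
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      A[pairs[1, k], pairs[2, k]], logical(1)))
  }, numeric(1))
  expect_equal(cc$local, oracle)
  expect_equal(cc$mean, mean(oracle))
  # and on a seeded random graph
  rg <- makeRandomGraph(9, edgeProb = 0.4, seed = 11)
  A <- edgeWeights(rg) > 0
  oracle <- vapply(nodeIds(rg), function(v) {
    nb <- nodeIds(rg)[A[v, ]]
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      A[pairs[1, k], pairs[2, k]], logical(1)))
  }, numeric(1))
  expect_equal(clusteringCoefficient(rg)$local, oracle)
})

test_that("attribute assortativity matches direct correlation", {
  # two homogeneous cliques, no cross edges -> +1
  W <- matrix(0, 4, 4, dimnames = rep(list(c("a", "b", "c", "d")), 2))
  W["a", "b"] <- W["b", "a"] <- 1
  W["c", "d"] <- W["d", "c"] <- 1
  g <- new("DiversityGraph", conditionID = "x",
           nodes = c("a", "b", "c", "d"), weights = W, binary = TRUE,
           threshold = 0.6)
  expect_equal(attributeAssortativity(g,
    c(a = 0, b = 0, c = 1, d = 1)), 1)
  # complete bipartite between attribute classes -> -1
  W2 <- matrix(0, 4, 4, dimnames = rep(list(c("a", "b", "c", "d")), 2))
  W2[c("a", "b"), c("c", "d")] <- 1
  W2[c("c", "d"), c("a", "b")] <- 1
  g2 <- new("DiversityGraph", conditionID = "x",
            nodes = c("a", "b", "c", "d"), weights = W2, binary = TRUE,
            threshold = 0.6)
  expect_equal(attributeAssortativity(g2,
    c(a = 0, b = 0, c = 1, d = 1)), -1)
  # seeded fixture against both a direct computation and igraph
  rg <- makeRandomGraph(6, edgeProb = 0.6, seed = 3)
  attrs <- stats::setNames(c(0.2, 0.9, 0.4, 0.8, 0.1, 0.6), nodeIds(rg))
  got <- attributeAssortativity(rg, attrs, weighted = FALSE)
  A <- edgeWeights(rg) > 0
  idx <- which(upper.tri(A) & A, arr.ind = TRUE)
  x <- attrs[nodeIds(rg)[idx[, 1]]]; y <- attrs[nodeIds(rg)[idx[, 2]]]
  expect_equal(got, stats::cor(c(x, y), c(y, x)), tolerance = 1e-12)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(got,
               igraph::assortativity(ig, values = attrs[nodeIds(rg)],
                                     directed = FALSE),
               tolerance = 1e-12)
  # zero attribute variance is signaled distinctly
  expect_warning(
    r <- attributeAssortativity(g, c(a = 1, b = 1, c = 1, d = 1)),
    "zero")
  expect_true(is.na(r))
})

test_that("conservation density windows are computed as documented", {
  strains <- sprintf("s%02d", 1:25)
  allHigh <- stats::setNames(rep(1, 25), strains)
  d1 <- conservationDensity(strains, allHigh)
  expect_identical(d1$density, rep(100, 3))
  expect_identical(d1$size, c(10L, 10L, 5L))
  alternating <- stats::setNames(rep(c(0, 1), length.out = 20),
                                 strains[1:20])
  d2 <- conservationDensity(strains[1:20], alternating)
  expect_identical(d2$density, c(50, 50))
  expect_error(conservationDensity(strains, allHigh[1:10]), "missing")
})

test_that("graph export round-trips through GraphML", {
  g <- fxGraph()
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(g, f, "graphml")
  ig <- igraph::read_graph(f, format = "graphml")
  expect_identical(sort(igraph::vertex_attr(ig, "name")),
                   sort(nodeIds(g)))
  expect_equal(igraph::ecount(ig),
               sum(edgeWeights(g)[upper.tri(edgeWeights(g))] > 0))
})
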