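test_that("the benefit formula is the affine identity it claims", {
  monos <- c(0.4, 1.0, 0.7)
  for (x in c(-0.5, -0.1, 0, 0.2, 1.5))
    expect_equal(benefit(max(monos) * (1 + x), monos), x,
                 tolerance = 1e-12)
  expect_identical(benefit(1, c(0.2, 1)), 0)
  expect_equal(benefit(1.2, c(1, 0.6)), 0.2)
  expect_error(benefit(1, c(0, 0)), "undefined")
  expect_error(benefit(1, numeric()), "no monoculture")
})

test_that("growth performance is the endpoint total biomass", {
  expect_equal(growthPerformance(fxTrajProv()), 0.003 + 1,
               tolerance = 0.01)
  # inviable strain keeps its initial biomass
  blocked <- fxKO(fxTriplet(), c("srcA", "srcB"), "C")
  expect_identical(
    growthPerformance(simulateMonoculture(blocked, fxCond(), "C")),
    0.003)
  # co-culture performance sums the members
  co <- fxPairCoculture()
  expect_identical(growthPerformance(co),
                   sum(co@biomass[, ncol(co@biomass)]))
})

test_that("a single-strain community has zero relative benefit", {
  mono <- growthPerformance(fxTrajProv())
  res <- communityBenefit("prov", list(prov = fxProvider()), fxCond(),
                          monoEndpoints = c(prov = mono))
  expect_lt(abs(res@relativeBenefit), 1e-9)
})

test_that("the provider/consumer pair is beneficial through cross-feeding", {
  monos <- c(prov = growthPerformance(fxTrajProv()),
             cons = growthPerformance(fxTrajCons()))
  res <- communityBenefit(c("prov", "cons"),
                          list(prov = fxProvider(), cons = fxConsumer()),
                          fxCond(), monoEndpoints = monos,
                          allEndpoints = c(monos,
                                           WT = growthPerformance(fxTrajWT())))
  expect_gt(res@relativeBenefit, 0.05)
  expect_gt(nrow(res@interactions), 0)
  expect_identical(
    interactionTypes(res@interactions, c("prov", "cons"))$type,
    "unidirectional")
  expect_false(res@truncated)
  # the wild-type outgrows the pair here, so the absolute benefit is
  # negative while the relative benefit is positive
  expect_lt(res@absoluteBenefit, 0)
  # missing endpoints are reported by name
  expect_error(communityBenefit(c("prov", "cons"),
    list(prov = fxProvider(), cons = fxConsumer()), fxCond(),
    monoEndpoints = monos["prov"]), "cons")
})

test_that("complementary double knockouts exchange in both directions", {
  bi <- fxBi()
  mods <- list(X = fxKO(bi, c("srcB", "cat1"), "X"),
               Y = fxKO(bi, c("srcA", "cat2"), "Y"))
  cond <- fxCond()
  co <- simulateCoculture(mods, rep(cond@initialBiomass / 2, 2), cond)
  rec <- detectInteractions(co)
  expect_identical(interactionTypes(rec, c("X", "Y"))$type,
                   "bidirectional")
  expect_setequal(unique(rec$metabolite), c("bp1_e", "bp2_e"))
})

test_that("monocultures produce an empty interaction record", {
  expect_identical(nrow(detectInteractions(fxTrajWT())), 0L)
})

test_that("ratio scans map the benefit curve and report the argmax", {
  monos <- c(prov = growthPerformance(fxTrajProv()),
             cons = growthPerformance(fxTrajCons()))
  rs <- ratioScan(list(prov = fxProvider(), cons = fxConsumer()),
                  fxCond(), monos, ratios = c(0.25, 0.5, 0.75))
  expect_identical(nrow(rs), 3L)
  expect_true(all(diff(rs$relativeBenefit) > 0))  # provider-heavy wins
  expect_identical(attr(rs, "argmax"), 3L)
  expect_error(ratioScan(list(prov = fxProvider(), cons = fxConsumer()),
                         fxCond(), monos, ratios = c(0, 0.5)), "ratios")
})

test_that("a symmetric pair gives a symmetric benefit curve", {
  mods <- fxTripletModels()[c("A", "B")]
  monos <- fxTripletMonos()[c("A", "B")]
  rs <- ratioScan(mods, fxCond(), monos, ratios = c(0.3, 0.5, 0.7))
  expect_equal(rs$groupEndpoint[1], rs$groupEndpoint[3],
               tolerance = 1e-9)
})

test_that("no interaction implies no benefit", {
  mods <- fxTripletModels()
  monos <- fxTripletMonos()
  res <- communityBenefit(c("A", "B"), mods, fxCond(),
                          monoEndpoints = monos[c("A", "B")])
  expect_identical(nrow(res@interactions), 0L)
  expect_lte(res@relativeBenefit, 1e-6)
})

test_that("the triplet is beneficial although no pair is", {
  mods <- fxTripletModels()
  monos <- fxTripletMonos()
  pairs <- utils::combn(names(mods), 2)
  pairRes <- lapply(seq_len(ncol(pairs)), function(k) {
    mem <- pairs[, k]
    communityBenefit(mem, mods, fxCond(), monoEndpoints = monos[mem])
  })
  for (r in pairRes)
    expect_lte(r@relativeBenefit, 1e-3)
  tri <- communityBenefit(c("A", "B", "C"), mods, fxCond(),
                          monoEndpoints = monos)
  expect_gt(tri@relativeBenefit, 0.05)
  # the scavenger C receives from both producers; A and B never trade
  types <- interactionTypes(tri@interactions, c("A", "B", "C"))
  expect_identical(types$type[types$strainA == "A" & types$strainB == "B"],
                   "none")
})

test_that("pair-mean prediction uses all constituent pairs", {
  mods <- fxTripletModels()
  monos <- fxTripletMonos()
  pairs <- utils::combn(names(mods), 2)
  pairRes <- lapply(seq_len(ncol(pairs)), function(k) {
    mem <- pairs[, k]
    communityBenefit(mem, mods, fxCond(), monoEndpoints = monos[mem])
  })
  pred <- pairMeanPrediction(c("A", "B", "C"), pairRes)
  expect_equal(pred$prediction,
               mean(vapply(pairRes, function(r) r@groupEndpoint,
                           numeric(1))))
  # one pair (A, B) does not interact -> flagged for exclusion
  expect_false(pred$allPairsInteract)
  # a community of two predicts its own performance
  p2 <- pairMeanPrediction(c("A", "B"), pairRes[1])
  expect_identical(p2$prediction, pairRes[[1]]@groupEndpoint)
  expect_error(pairMeanPrediction(c("A", "B", "C"), pairRes[1:2]),
               "missing pair")
  # correlation utility restricts to fully interacting communities
  expect_error(pairMeanCorrelation(1:2, 1:2, c(TRUE, TRUE)),
               "at least 3")
  expect_equal(pairMeanCorrelation(c(1, 2, 3, 9), c(1.1, 2.2, 2.9, 0),
                                   c(TRUE, TRUE, TRUE, FALSE)),
               stats::cor(c(1, 2, 3), c(1.1, 2.2, 2.9)))
})

test_that("endpoint biomass respects the substrate conversion bound", {
  # nothing can beat initial biomass + best yield x initial carbon
  # (up to the clamped discretization overdraw, under 1 percent)
  bestYield <- 0.1 + 0.5 * 0.1    # source route plus full by-product use
  bound <- 0.003 + bestYield * 10
  for (e in c(growthPerformance(fxTrajWT()),
              growthPerformance(fxPairCoculture())))
    expect_lte(e, bound * 1.01)
})
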