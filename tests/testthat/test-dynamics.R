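test_that("uptake bounds follow substrate availability and caps", {
  cond <- growthCondition("s_e", inExcess = "o_e",
                          uptakeCaps = c(o_e = 20), defaultCap = Inf)
  exMap <- c(EX_s = "s_e", EX_o = "o_e", EX_b = "b_e")
  # C = 10, b = 1, dt = 0.1, uncapped -> the whole pool in one step
  b1 <- stepUptakeBounds(c(s_e = 10), 1, 0.1, cond, exMap)
  expect_equal(unname(b1[["EX_s"]]), -100)
  # in-excess oxygen capped at 20 regardless of biomass
  expect_equal(unname(b1[["EX_o"]]), -20)
  # absent metabolite -> nothing to take up
  expect_identical(unname(b1[["EX_b"]]), 0)
  # empty pool -> zero bound
  expect_identical(unname(
    stepUptakeBounds(c(s_e = 0), 1, 0.1, cond, exMap)[["EX_s"]]), 0)
  # extinct population is a domain error
  expect_error(stepUptakeBounds(c(s_e = 10), 0, 0.1, cond, exMap),
               "extinct")
  # the cap also applies to tracked metabolites
  cond2 <- growthCondition("s_e", defaultCap = 5)
  expect_equal(unname(
    stepUptakeBounds(c(s_e = 10), 1, 0.1, cond2, exMap)[["EX_s"]]), -5)
})

test_that("biomass update follows the exponential closed form", {
  expect_equal(updateBiomass(1, log(2), 1), 2)
  expect_identical(updateBiomass(3.7, 0, 0.1), 3.7)
  expect_identical(updateBiomass(0, 1, 0.1), 0)
})

test_that("medium update applies the exact exponential-integral term", {
  # uptake at vex = -1 with mu = ln 2 over one hour consumes
  # (e^mu - 1)/mu = 1/ln 2 = 1.442695...
  upd <- updateMedium(c(s = 10),
                      list(list(vex = c(s = -1), b = 1, mu = log(2))),
                      dt = 1)
  expect_equal(unname(upd$medium[["s"]]), 10 - 1 / log(2),
               tolerance = 1e-12)
  # mu -> 0 limit is the linear form vex * b * dt
  upd0 <- updateMedium(c(s = 10),
                       list(list(vex = c(s = -1), b = 1, mu = 0)),
                       dt = 0.1)
  expect_equal(unname(upd0$medium[["s"]]), 9.9, tolerance = 1e-12)
  # additivity: two half-biomass strains equal one full strain
  updA <- updateMedium(c(s = 10),
    list(list(vex = c(s = -1), b = 0.5, mu = 0.3),
         list(vex = c(s = -1), b = 0.5, mu = 0.3)), dt = 0.1)
  updB <- updateMedium(c(s = 10),
    list(list(vex = c(s = -1), b = 1, mu = 0.3)), dt = 0.1)
  expect_equal(updA$medium, updB$medium, tolerance = 1e-12)
  # secretion adds new metabolites to the tracked pool, clamping logs
  updS <- updateMedium(c(s = 1),
    list(list(vex = c(s = -30, by = 2), b = 1, mu = 0)), dt = 0.1)
  expect_equal(unname(updS$medium[["by"]]), 0.2)
  expect_identical(unname(updS$medium[["s"]]), 0)
  expect_equal(updS$clamped, 2, tolerance = 1e-12)
})

test_that("monoculture endpoints match the closed-form mass balance", {
  # provider converts all 10 mmol at yield 0.1 gDW/mmol
  traj <- fxTrajProv()
  expect_identical(traj@terminationReason, "stalled")
  expect_equal(growthPerformance(traj), 0.003 + 0.1 * 10,
               tolerance = 0.01)
  # consumer runs the clean route at yield 0.05
  expect_equal(growthPerformance(fxTrajCons()), 0.003 + 0.05 * 10,
               tolerance = 0.01)
  # discretization overdraw is clamped and small
  expect_lt(traj@clampedMass, 0.01 * 10)
})

test_that("the wild-type secretes its by-product and re-consumes it", {
  traj <- fxTrajWT()
  bp <- traj@medium["bp1_e", ]
  expect_gt(max(bp), 1)                      # appears
  expect_lt(bp[length(bp)], 1e-6)            # fully re-consumed
  expect_lt(which.max(bp), length(bp))       # peak strictly inside
  # two-phase growth: total conversion 0.1*10 source + 0.1*(0.5*10)
  expect_equal(growthPerformance(traj), 0.003 + 1.5, tolerance = 0.01)
})

test_that("an inviable strain yields a length-1 stalled trajectory", {
  blocked <- fxKO(fxTriplet(), c("srcA", "srcB"), "C")
  traj <- simulateMonoculture(blocked, fxCond(), "C")
  expect_length(traj@times, 1L)
  expect_identical(traj@terminationReason, "stalled")
  expect_identical(growthPerformance(traj), 0.003)
})

test_that("a co-culture of identical strains reduces to the monoculture", {
  cond <- fxCond()
  mono <- fxTrajProv()
  for (k in c(2L, 3L)) {
    co <- simulateCoculture(
      stats::setNames(rep(list(fxProvider()), k), paste0("s", 1:k)),
      rep(cond@initialBiomass / k, k), cond)
    expect_identical(length(co@times), length(mono@times))
    dev <- max(abs(colSums(co@biomass) - mono@biomass[1, ]))
    expect_lt(dev, 1e-9)
    devM <- max(abs(co@medium[rownames(mono@medium), ] - mono@medium))
    expect_lt(devM, 1e-9)
  }
})

test_that("a zero-biomass strain contributes nothing", {
  cond <- fxCond()
  co <- simulateCoculture(list(prov = fxProvider(), ghost = fxConsumer()),
                          c(cond@initialBiomass, 0), cond)
  mono <- fxTrajProv()
  expect_identical(length(co@times), length(mono@times))
  expect_lt(max(abs(co@biomass["prov", ] - mono@biomass[1, ])), 1e-9)
  expect_true(all(co@biomass["ghost", ] == 0))
})

test_that("provider and consumer exchange the by-product in co-culture", {
  co <- fxPairCoculture()
  fp <- co@exchangeFluxes[["prov"]]["bp1_e", ]
  fc <- co@exchangeFluxes[["cons"]]["bp1_e", ]
  overlap <- which(fp > 1e-6 & fc < -1e-6)
  expect_gt(length(overlap), 0)
})

test_that("tracked substrate mass balances against the uptake integrals", {
  traj <- fxTrajProv()
  nt <- length(traj@times)
  dt <- diff(traj@times)[1]
  src <- traj@medium["src_e", ]
  vex <- traj@exchangeFluxes[[1]]["src_e", ]
  b <- traj@biomass[1, ]
  mu <- traj@growthRates[1, ]
  # all transitions except the final (clamped) one
  for (k in seq_len(nt - 2)) {
    expI <- if (mu[k] < 1e-9) vex[k] * b[k] * dt else
      vex[k] * b[k] * (exp(mu[k] * dt) - 1) / mu[k]
    expect_equal(src[k + 1] - src[k], expI, tolerance = 1e-8,
                 info = paste("step", k))
  }
})

test_that("halving the time step moves the endpoint by under 1 percent", {
  e1 <- growthPerformance(fxTrajProv())
  e2 <- growthPerformance(
    simulateMonoculture(fxProvider(), fxCond(timeStep = 0.05), "p"))
  expect_lt(abs(e2 - e1) / e1, 0.01)
})

test_that("trajectory invariants hold", {
  for (traj in list(fxTrajWT(), fxPairCoculture())) {
    expect_true(validObject(traj))
    expect_true(all(diff(traj@times) > 0))
    expect_true(all(traj@medium >= 0))
    # biomass non-decreasing
    expect_true(all(apply(traj@biomass, 1, function(x)
      all(diff(x) >= -1e-12))))
  }
})
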