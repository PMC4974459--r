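# Four-state promoter model: stationary solution, rate constraints,
# population simulation and distribution comparison.

test_that("stationary solution reduces to the telegraph model at kOff2 = 0", {
  m <- promoterModel(kOn1 = 0.01, kOff1 = 0.02, kOff2 = 0, kIni = 0.3,
                     kRelease = 0.004, kDeg = 0.0002)
  st <- stationaryStats(m)
  expect_equal(unname(st$pi["ON"]), 0.01 / 0.03)
  expect_equal(unname(st$pi["OFF2a"] + st$pi["OFF2b"]), 0)
})

test_that("mean_mature / mean_nascent equals kRelease / kDeg for any model", {
  set.seed(3)
  for (i in 1:20) {
    m <- promoterModel(kOn1 = runif(1, 1e-3, 0.05),
                       kOff1 = runif(1, 1e-3, 0.05),
                       kOff2 = runif(1, 0, 0.01), f1 = runif(1),
                       kOn2a = runif(1, 1e-3, 0.01),
                       kOn2b = runif(1, 1e-4, 0.01),
                       kIni = runif(1, 0.05, 0.5),
                       kRelease = runif(1, 1e-3, 0.02),
                       kDeg = runif(1, 1e-4, 0.001))
    st <- stationaryStats(m)
    expect_equal(st$mean_mature / st$mean_nascent, m@kRelease / m@kDeg)
    expect_equal(sum(st$pi), 1)
  }
})

test_that("analytic stationary distribution matches the stationary vector of
           the generator matrix", {
  # independent oracle: null space of the CTMC generator
  m <- hivPromoterModel()
  Q <- matrix(0, 4, 4,
              dimnames = list(c("ON", "OFF1", "OFF2a", "OFF2b"),
                              c("ON", "OFF1", "OFF2a", "OFF2b")))
  Q["ON", "OFF1"] <- m@kOff1
  Q["OFF1", "ON"] <- m@kOn1
  Q["OFF1", "OFF2a"] <- m@f1 * m@kOff2
  Q["OFF1", "OFF2b"] <- (1 - m@f1) * m@kOff2
  Q["OFF2a", "OFF1"] <- m@kOn2a
  Q["OFF2b", "OFF1"] <- m@kOn2b
  diag(Q) <- -rowSums(Q)
  ns <- eigen(t(Q))
  piNum <- Re(ns$vectors[, which.min(abs(ns$values))])
  piNum <- piNum / sum(piNum)
  expect_equal(unname(stationaryStats(m)$pi), piNum, tolerance = 1e-9)
})

test_that("linear OFF2<->OFF1<->ON chain is stationarily equivalent to the
           branched OFF2<->ON<->OFF1 arrangement", {
  # swap which neighbour OFF2 attaches to; with identical pairwise rates the
  # stationary weights (detailed balance on a tree) are unchanged
  kOn1 <- 0.012; kOff1 <- 0.009; kOff2 <- 0.002; kOn2 <- 0.004
  piFor <- function(branchOn) {
    Q <- matrix(0, 3, 3)   # states: ON, OFF1, OFF2 (single deep state)
    Q[1, 2] <- kOff1; Q[2, 1] <- kOn1
    if (branchOn) { Q[1, 3] <- kOff2; Q[3, 1] <- kOn2 }
    else { Q[2, 3] <- kOff2; Q[3, 2] <- kOn2 }
    diag(Q) <- -rowSums(Q)
    e <- eigen(t(Q)); p <- Re(e$vectors[, which.min(abs(e$values))])
    p / sum(p)
  }
  piLinear <- piFor(FALSE)
  piBranched <- piFor(TRUE)
  # OFF2 occupancy identical up to the kOn1/kOff1 weight transfer:
  # the linear chain hangs OFF2 off OFF1 (weight 1), the branched one off ON
  # (weight kOn1/kOff1); equality holds when the entry flux is matched
  piBranchedMatched <- piFor(TRUE)
  QlinOff2 <- kOff2 / kOn2                   # weight relative to OFF1
  expect_equal(piLinear[3] / piLinear[2], QlinOff2, tolerance = 1e-9)
  expect_equal(piBranchedMatched[3] / piBranchedMatched[1], QlinOff2,
               tolerance = 1e-9)
  # and the ON:OFF1 odds are kOn1:kOff1 in both arrangements
  expect_equal(piLinear[1] / piLinear[2], kOn1 / kOff1, tolerance = 1e-9)
  expect_equal(piBranched[1] / piBranched[2], kOn1 / kOff1, tolerance = 1e-9)
})

test_that("solveConstrainedRates inverts the stationary solution", {
  m0 <- promoterModel(kOn1 = 1 / 120, kOff1 = 1 / 110, kOff2 = 0.001,
                      f1 = 0.8, kOn2a = 1 / 300, kOn2b = 1 / 1800,
                      kIni = 1 / 3.4, kRelease = 0.005, kDeg = 1 / 4500)
  st <- stationaryStats(m0)
  sol <- solveConstrainedRates(m0, populationSummary(st$mean_mature,
                                                     st$mean_nascent))
  expect_equal(sol$status, "ok")
  expect_equal(sol$model@kOff2, 0.001, tolerance = 1e-9)
  expect_equal(sol$model@kRelease, m0@kRelease, tolerance = 1e-9)

  # the smFISH regime: kRelease = kDeg * 492 / 32 = 0.205 per minute
  m1 <- gridPointModel(3.4, 0.8, 30, 1 / 110, 2)
  sol1 <- solveConstrainedRates(m1, populationSummary(492, 32))
  expect_equal(sol1$model@kRelease * 60, (492 / 32) / 75, tolerance = 1e-12)

  # a target mean above the kOff2 = 0 ceiling is infeasible, not an error
  ceiling0 <- m1@kIni * (m1@kOn1 / m1@kOff1) /
    (m1@kDeg * (1 + m1@kOn1 / m1@kOff1))
  solBad <- solveConstrainedRates(m1, populationSummary(ceiling0 * 1.05,
                                                        ceiling0 * 1.05 / 15))
  expect_equal(solBad$status, "infeasible_negative_koff2")
  expect_null(solBad$model)
})

test_that("population simulation matches the analytic stationary means and
           both schemes agree", {
  m <- hivPromoterModel()
  st <- stationaryStats(m)
  sim <- simulatePopulation(m, nCells = 400, nSteps = 18000, dt = 2, seed = 1)
  expect_equal(attr(sim, "totalTimeS"), 36000)
  seN <- sd(nascentCounts(sim)) / sqrt(400)
  seM <- sd(matureCounts(sim)) / sqrt(400)
  expect_lt(abs(mean(nascentCounts(sim)) - st$mean_nascent), 3 * seN)
  expect_lt(abs(mean(matureCounts(sim)) - st$mean_mature), 3 * seM)

  simEx <- simulatePopulation(m, nCells = 2000, nSteps = 36000, dt = 1,
                              seed = 2, scheme = "exact")
  seN2 <- sqrt(seN^2 * 400 / 400 + var(nascentCounts(simEx)) / 2000)
  seM2 <- sqrt(seM^2 + var(matureCounts(simEx)) / 2000)
  expect_lt(abs(mean(nascentCounts(sim)) - mean(nascentCounts(simEx))),
            3 * seN2)
  expect_lt(abs(mean(matureCounts(sim)) - mean(matureCounts(simEx))),
            3 * seM2)

  # kIni = 0: all counts zero
  m0 <- promoterModel(kOn1 = 0.01, kOff1 = 0.01, kIni = 0,
                      kRelease = 0.01, kDeg = 0.001)
  sim0 <- simulatePopulation(m0, nCells = 20, nSteps = 100, dt = 1, seed = 3)
  expect_equal(sum(nascentCounts(sim0)) + sum(matureCounts(sim0)), 0)

  # stability guard names the offending rate
  mBad <- promoterModel(kOn1 = 0.5, kOff1 = 0.01, kIni = 0.1,
                        kRelease = 0.01, kDeg = 0.001)
  expect_error(simulatePopulation(mBad, 10, 100, dt = 1), "kOn1")
})

test_that("promoter state occupancy in simulation matches the analytic pi", {
  m <- hivPromoterModel()
  pi0 <- stationaryStats(m)$pi
  sim <- simulatePopulation(m, nCells = 800, nSteps = 9000, dt = 2, seed = 4,
                            returnStates = TRUE)
  occ <- table(factor(attr(sim, "finalState"),
                      levels = c("ON", "OFF1", "OFF2a", "OFF2b"))) / 800
  for (s in names(pi0)) {
    se <- sqrt(pi0[s] * (1 - pi0[s]) / 800)
    expect_lt(abs(occ[[s]] - pi0[[s]]), 3 * se + 1e-12)
  }
})

test_that("simulated dwell times reproduce the switching rates", {
  # feed promoter state paths to the dwell-time machinery
  m <- promoterModel(kOn1 = 1 / 100, kOff1 = 1 / 120, kOff2 = 1 / 200,
                     f1 = 0.75, kOn2a = 1 / 240, kOn2b = 1 / 900, kIni = 0)
  set.seed(11)
  onD <- numeric(0); off2D <- numeric(0); off2Which <- character(0)
  for (i in 1:60) {
    path <- ConvoyQuant:::.promoterPath(m, 40000)
    inner <- path[-c(1, nrow(path)), , drop = FALSE]   # uncensored dwells
    onD <- c(onD, inner$end[inner$state == "ON"] -
               inner$start[inner$state == "ON"])
    sel <- inner$state %in% c("OFF2a", "OFF2b")
    off2D <- c(off2D, inner$end[sel] - inner$start[sel])
    off2Which <- c(off2Which, inner$state[sel])
  }
  # ON dwells exponential with mean 1/kOff1
  fitOn <- fitDwell(onD, model = "mono")
  expect_lt(abs(dwellTaus(fitOn) - 120) / 120, 3 / sqrt(length(onD)) * 1.5)
  # OFF2 dwell mixture: entry split f1 / (1 - f1), means 1/kOn2a and 1/kOn2b
  expect_lt(abs(mean(off2Which == "OFF2a") - 0.75),
            3 * sqrt(0.75 * 0.25 / length(off2Which)))
  fitOff2 <- fitDwell(off2D, model = "bi", seed = 2)
  expect_lt(abs(dwellTaus(fitOff2)[1] - 240) / 240, 0.2)
  expect_lt(abs(dwellTaus(fitOff2)[2] - 900) / 900, 0.2)
})

test_that("halving the step size leaves fixed-step means within one SE", {
  m <- hivPromoterModel()
  s1 <- simulatePopulation(m, nCells = 400, nSteps = 18000, dt = 2, seed = 7)
  s2 <- simulatePopulation(m, nCells = 400, nSteps = 36000, dt = 1, seed = 7)
  se <- sqrt(var(matureCounts(s1)) / 400 + var(matureCounts(s2)) / 400)
  expect_lt(abs(mean(matureCounts(s1)) - mean(matureCounts(s2))), 2 * se)
})
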