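# Cycle detection, convoy-model fitting and pooled cohort summaries.

test_that("findIsolatedCycles locates segments and honours the boundary rule", {
  g <- testGeom()
  expect_error(findIsolatedCycles(intensityTrace(numeric(0), numeric(0))))
  # all-zero trace -> no cycles
  z <- intensityTrace(seq(0, 300, 3), rep(0, 101))
  expect_length(findIsolatedCycles(z), 0)

  # two convoys separated by 120 s of silence
  p <- convoyParams(8, 4, 4, 60)
  t1 <- 30
  span <- 7 * 4 + 9300 / (4 * 1000 / 60) + 60
  t2 <- t1 + span + 120
  times <- seq(0, t2 + span + 60, 3)
  vals <- tsIntensity(times, p, g, t0 = t1) + tsIntensity(times, p, g, t0 = t2)
  cycles <- findIsolatedCycles(intensityTrace(times, vals),
                               offThreshold = 0.5, minOffFrames = 3)
  expect_length(cycles, 2)
  expect_true(all(vapply(cycles, function(cc) cc@isolated, logical(1))))
  # descriptive phase boundaries keep their ordering inside the segment
  for (cc in cycles) {
    expect_true(cc@upStart < cc@upEnd)
    expect_true(cc@upEnd <= cc@downStart)
    expect_true(cc@downStart < cc@downEnd)
  }
  # boundaries within one frame of the noiseless threshold crossings, also
  # under measurement noise
  onset1 <- times[which(vals > 0.5)[1L]]
  end2 <- times[tail(which(vals > 0.5), 1L)]
  set.seed(6)
  noisy <- intensityTrace(times, vals + rnorm(length(vals), sd = 0.1))
  cyN <- findIsolatedCycles(noisy, offThreshold = 0.5, minOffFrames = 3)
  expect_length(cyN, 2)
  expect_lt(abs(times[cyN[[1]]@frameStart] - onset1), 3 + 1e-9)
  expect_lt(abs(times[cyN[[2]]@frameEnd] - end2), 3 + 1e-9)

  # convoy overlapping frame 0 is returned but flagged not isolated
  vals0 <- tsIntensity(times, p, g, t0 = -150)
  cyc0 <- findIsolatedCycles(intensityTrace(times, vals0))
  expect_length(cyc0, 1)
  expect_false(cyc0[[1]]@isolated)
})

test_that("noiseless fit recovers the generating parameters", {
  g <- testGeom()
  p <- hivParams()
  tr <- simulateConvoyTrace(p, g, dt = 3, t0 = 30, seed = 1)
  f <- fitConvoyCycle(tr, findIsolatedCycles(tr)[[1]], g, seed = 1)
  expect_equal(nPol(f), 19)
  expect_equal(tSpace(f), 4.1, tolerance = 0.01)
  expect_equal(vEl(f), 4.1, tolerance = 0.01)
  expect_equal(tProc(f), 103, tolerance = 0.01)
  expect_equal(f@t0, 30, tolerance = 0.05)
  # relative residual on noiseless input
  expect_lt(f@residualNorm / max(traceValues(tr)), 1e-6)
  expect_false(f@vElIsLowerBound)
  expect_true(all(f@uncertainty >= 0, na.rm = TRUE))
})

test_that("zero-plateau cycles flag vEl as a lower bound", {
  g <- testGeom()
  p <- convoyParams(19, 12, 4.1, 20)   # spread >> lPost/v + tProc
  expect_true(analyticDurations(p, g)$truncated)
  tr <- simulateConvoyTrace(p, g, dt = 3, t0 = 30, seed = 2)
  f <- fitConvoyCycle(tr, NULL, g, seed = 1)
  expect_true(f@vElIsLowerBound)
  # the reported vEl is a minimal compatible value, not an overestimate
  expect_lte(vEl(f), 4.1 * 1.05)
})

test_that("fit errors on cycles that are too short", {
  tr <- intensityTrace(seq(0, 18, 3), c(0, 1, 3, 3, 1, 0, 0))
  expect_error(fitConvoyCycle(tr, NULL, testGeom()), "8 frames")
})

test_that("pooled UP-ramp regression matches the closed form", {
  g <- testGeom()
  # cycles with tSpace = 4 s and lMs2 / vEl = 40 s: slope 4, intercept 36
  vel <- g@lMs2 / 40 * 60 / 1000
  fits <- lapply(seq(5, 30, 5), function(np)
    new("FittedConvoy", params = convoyParams(np, 4, vel, 100), t0 = 0,
        vElIsLowerBound = FALSE, residualNorm = 0,
        uncertainty = c(nPol = 0, tSpace = 0, vEl = 0, tProc = 0)))
  reg <- pooledUprampRegression(fits, g)
  expect_equal(reg$slope, 4, tolerance = 1e-9)
  expect_equal(reg$intercept, 36, tolerance = 1e-9)
  expect_equal(reg$v_el_pooled, vel, tolerance = 1e-9)

  # degenerate: all cycles share one nPol
  fitsSame <- lapply(1:4, function(i)
    new("FittedConvoy", params = convoyParams(10, 4, vel, 100), t0 = 0,
        vElIsLowerBound = FALSE, residualNorm = 0,
        uncertainty = c(nPol = 0, tSpace = 0, vEl = 0, tProc = 0)))
  expect_error(pooledUprampRegression(fitsSame, g), "degenerate")

  # independent draws of nPol and tSpace: correlation near zero
  set.seed(5)
  n <- 60
  fitsNull <- lapply(1:n, function(i)
    new("FittedConvoy",
        params = convoyParams(sample(5:30, 1), runif(1, 2, 8), vel, 100),
        t0 = 0, vElIsLowerBound = FALSE, residualNorm = 0,
        uncertainty = c(nPol = 0, tSpace = 0, vEl = 0, tProc = 0)))
  regNull <- pooledUprampRegression(fitsNull, g)
  expect_lt(abs(regNull$npol_tspace_correlation), 2 / sqrt(n))
})

test_that("interconvoy statistics follow the duration and gap definitions", {
  g <- testGeom()
  mk <- function(np, ts, t0) new("FittedConvoy",
    params = convoyParams(np, ts, 4.1, 103), t0 = t0,
    vElIsLowerBound = FALSE, residualNorm = 0,
    uncertainty = c(nPol = 0, tSpace = 0, vEl = 0, tProc = 0))
  f1 <- mk(19, 4.1, 0)
  st <- interconvoyStats(list(list(f1)), g)
  expect_equal(st$convoy_durations, 19 * 4.1)   # 77.9 s
  expect_length(st$gaps, 0)
  expect_true(is.na(st$exp_fit_tau))

  # gap = next UP-ramp start minus this cycle's UP-ramp end
  f2 <- mk(10, 5, 500)
  v <- 4.1 * 1000 / 60
  upEnd1 <- 0 + 18 * 4.1 + (g@lPre + g@lMs2) / v
  upStart2 <- 500 + g@lPre / v
  st2 <- interconvoyStats(list(list(f1, f2)), g)
  expect_equal(st2$gaps, upStart2 - upEnd1)

  # MLE of the exponential mean over many gaps
  set.seed(8)
  gaps <- rexp(500, 1 / 100)
  fits <- list(mk(5, 4, 0))
  t0s <- cumsum(c(0, gaps + 50))
  fitsAll <- lapply(t0s, function(t0) mk(5, 4, t0))
  stG <- interconvoyStats(list(fitsAll), g)
  expect_equal(length(stG$gaps), 500)
  expect_lt(abs(stG$exp_fit_tau - mean(stG$gaps)), 1e-9)
})
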