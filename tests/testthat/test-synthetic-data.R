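# Seeded generators: convoy traces, promoter traces, dwell samples.

test_that("noiseless regular-mode trace equals the sampled forward model", {
  p <- hivParams(); g <- testGeom()
  tr <- simulateConvoyTrace(p, g, dt = 3, t0 = 30, seed = 1)
  expect_s4_class(tr, "IntensityTrace")
  expect_equal(traceValues(tr), tsIntensity(traceTimes(tr), p, g, t0 = 30))
  expect_equal(traceUnits(tr), "rna_equivalents")
  expect_length(traceFlags(tr), 0)
})

test_that("identical seeds give identical traces, different seeds differ", {
  p <- hivParams(); g <- testGeom()
  nm <- noiseModel(additiveSd = 0.5)
  t1 <- simulateConvoyTrace(p, g, noise = nm, seed = 11)
  t2 <- simulateConvoyTrace(p, g, noise = nm, seed = 11)
  t3 <- simulateConvoyTrace(p, g, noise = nm, seed = 12)
  expect_identical(traceValues(t1), traceValues(t2))
  expect_false(identical(traceValues(t1), traceValues(t3)))
  # byte-identical CSV round trip under a fixed seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeIntensityTrace(t1, f1); writeIntensityTrace(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(1)
  set.seed(123)
  invisible(simulateConvoyTrace(hivParams(), testGeom(), seed = 5))
  invisible(sampleDwellTimes(dwellMixture(100), 10, seed = 6))
  expect_identical(runif(1), a)
})

test_that("short simulation window is flagged as truncated", {
  p <- hivParams(); g <- testGeom()
  tr <- simulateConvoyTrace(p, g, dt = 3, duration = 100, seed = 1)
  expect_true("duration_truncated" %in% traceFlags(tr))
})

test_that("exponential spacing reproduces regular-mode mean UP-ramp duration", {
  p <- hivParams(); g <- testGeom()
  # UP ramp ends when the last polymerase leaves the repeat; its mean onset
  # under i.i.d. exponential gaps equals the regular-spacing value
  v <- 4.1 * 1000 / 60
  regularUp <- analyticDurations(p, g)$up_ramp
  ups <- vapply(1:500, function(i) {
    tr <- simulateConvoyTrace(p, g, dt = 3, spacingMode = "exponential",
                              seed = i)
    vv <- traceValues(tr); tt <- traceTimes(tr)
    tt[which(vv >= max(vv) - 1e-9)[1L]] - tt[which(vv > 1e-9)[1L]]
  }, numeric(1))
  expect_lt(abs(mean(ups) - regularUp) / regularUp, 0.05)
})

test_that("dwell-time sampler matches its mixture mean", {
  # mono-exponential regime (inter-convoy gaps): tau = 100 s
  d <- sampleDwellTimes(dwellMixture(100), 10000, seed = 3)
  se <- 100 / sqrt(10000)
  expect_lt(abs(mean(d) - 100), 3 * se)
  # degenerate single-component mixture is a plain exponential
  d1 <- sampleDwellTimes(dwellMixture(taus = 50, weights = 1), 5000, seed = 4)
  expect_lt(abs(mean(d1) - 50), 3 * 50 / sqrt(5000))
  # bi-exponential non-permissive regime: 9 min (77%) / 34 min (23%)
  mix <- dwellMixture(c(540, 2040), c(0.77, 0.23))
  d2 <- sampleDwellTimes(mix, 10000, seed = 5)
  mu <- 0.77 * 540 + 0.23 * 2040
  sdMix <- sqrt(0.77 * (540^2 + 540^2) + 0.23 * (2040^2 + 2040^2) - mu^2)
  expect_lt(abs(mean(d2) - mu), 3 * sdMix / sqrt(10000))
})

test_that("promoter trace generator obeys the telegraph limit and the seed", {
  g <- testGeom()
  # two-state limit: kOff2 = 0; ON fraction ~ kOn1 / (kOn1 + kOff1)
  m <- promoterModel(kOn1 = 1 / 120, kOff1 = 1 / 80, kOff2 = 0, kIni = 0)
  onFrac <- vapply(1:50, function(i) {
    sim <- simulatePromoterTrace(m, g, dt = 5, duration = 3000, seed = i)
    mean(sim$statePath == "ON")
  }, numeric(1))
  pOn <- (1 / 120) / (1 / 120 + 1 / 80)
  # 50 cells x 600 frames, but frames are correlated within a cell; use the
  # binomial SE at the number of independent dwells (~ duration / mean dwell)
  nEff <- 50 * 3000 / (1 / (1 / 120 + 1 / 80) * 2)
  expect_lt(abs(mean(onFrac) - pOn), 3 * sqrt(pOn * (1 - pOn) / nEff))

  # kIni = 0: flat zero trace, but the promoter still switches
  sim0 <- simulatePromoterTrace(m, g, dt = 5, duration = 3000, seed = 1)
  expect_equal(sum(traceValues(sim0$trace)), 0)
  expect_gt(length(unique(sim0$statePath)), 1)

  # reproducibility
  mi <- promoterModel(kOn1 = 1 / 100, kOff1 = 1 / 90, kOff2 = 0, kIni = 0.25,
                      kRelease = 0.003, kDeg = 0.0002)
  s1 <- simulatePromoterTrace(mi, g, dt = 3, duration = 900, seed = 9)
  s2 <- simulatePromoterTrace(mi, g, dt = 3, duration = 900, seed = 9)
  expect_identical(traceValues(s1$trace), traceValues(s2$trace))
  expect_identical(s1$statePath, s2$statePath)
})

test_that("movie generator: background, planted intensity, bleaching", {
  spec <- smallMovieSpec(cameraNoiseSd = 2, backgroundLevel = 30,
                         bleachAmplitudes = c(1, 0, 0), bleachRates = rep(0, 3))
  # background-only stack
  sim <- simulateMovieStack(spec, seed = 1)
  expect_equal(dim(sim$stack), c(12, 9, 48, 48))
  expect_lt(abs(mean(sim$stack) - 30), 0.5)
  expect_false(sim$clipped)

  # planted molecule, no noise, no bleach: integrated intensity within 1%
  specClean <- smallMovieSpec(cameraNoiseSd = 0, backgroundLevel = 0,
                              bleachAmplitudes = c(1, 0, 0),
                              bleachRates = rep(0, 3), nFrames = 3)
  simM <- simulateMovieStack(specClean, nSingleMolecules = 1,
                             singleMoleculeIntensity = 500, seed = 2)
  tot <- sum(simM$stack[1, , , ])
  expect_lt(abs(tot - 500) / 500, 0.01)

  # per-frame stack mean follows the specified tri-exponential within 2%
  specB <- smallMovieSpec(nFrames = 30, cameraNoiseSd = 0,
                          backgroundLevel = 100,
                          bleachAmplitudes = c(0.3, 0.3, 0.4),
                          bleachRates = c(1 / 20, 1 / 150, 1 / 2000))
  simB <- simulateMovieStack(specB, seed = 3)
  frameMeans <- apply(simB$stack, 1, mean)
  expect_lt(max(abs(frameMeans / (100 * simB$bleach) - 1)), 0.02)
})

test_that("spots brighter than the saturation cap are clipped and flagged", {
  spec <- smallMovieSpec(nFrames = 2, saturationLevel = 100,
                         cameraNoiseSd = 0, backgroundLevel = 50,
                         bleachAmplitudes = c(1, 0, 0),
                         bleachRates = rep(0, 3))
  sim <- simulateMovieStack(spec, nSingleMolecules = 2,
                            singleMoleculeIntensity = 5e4, seed = 4)
  expect_true(sim$clipped)
  expect_lte(max(sim$stack), 100)
})
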