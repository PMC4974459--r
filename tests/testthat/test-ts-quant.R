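# Movie quantification: bleach correction, filtering, tracking, Gaussian
# fitting, calibration and FRAP normalisation.

test_that("bleach correction is exact on synthetic decays and idempotent on
           constant input", {
  tt <- seq(0, 150, 3)
  # constant nuclear intensity: output within 0.1% of input
  const <- rep(200, length(tt))
  bc <- bleachCorrect(const, tt)
  expect_lt(max(abs(bc$corrected / const - 1)), 0.001)

  # tri-exponential decay flattened within 1%, frame 1 exactly preserved
  decay <- 0.3 * exp(-tt / 20) + 0.3 * exp(-tt / 150) + 0.4 * exp(-tt / 2000)
  y <- 500 * decay
  bc2 <- bleachCorrect(y, tt)
  expect_equal(bc2$corrected[1], y[1])
  expect_lt(max(abs(bc2$corrected / y[1] - 1)), 0.01)
  expect_error(bleachCorrect(y[1:5], tt[1:5]), "10 frames")
})

test_that("bleach correction flattens the movie generator's decay", {
  spec <- smallMovieSpec(nFrames = 30, cameraNoiseSd = 0, backgroundLevel = 80,
                         bleachAmplitudes = c(0.3, 0.3, 0.4),
                         bleachRates = c(1 / 25, 1 / 200, 1 / 2500))
  sim <- simulateMovieStack(spec, seed = 1)
  tt <- (seq_len(30) - 1) * spec@frameIntervalS
  bc <- bleachCorrect(sim$stack, tt)
  nucMean <- apply(bc$corrected, 1, mean)
  expect_lt(max(abs(nucMean / nucMean[1] - 1)), 0.01)
})

test_that("bandpass filter removes DC, is linear and raises peak SNR", {
  img <- array(7.5, dim = c(5, 32, 32))
  out <- bandpassFilter(img, 5, 1)
  expect_lt(max(abs(out)), 1e-9 * 7.5)

  set.seed(2)
  noise <- array(rnorm(5 * 32 * 32, sd = 2), dim = c(5, 32, 32))
  spot <- array(0, dim = c(5, 32, 32))
  for (dz in -2:2) for (dy in -3:3) for (dx in -3:3)
    spot[3 + dz, 16 + dy, 16 + dx] <-
      10 * exp(-(dy^2 + dx^2) / (2 * 1.3^2) - dz^2 / 2)
  raw <- spot + noise
  filt <- bandpassFilter(raw, 5, 1)
  snr <- function(a) a[3, 16, 16] / mad(a[, , 1:8])
  expect_gt(snr(filt), snr(raw))

  # linearity: filter(a * I) = a * filter(I)
  expect_equal(bandpassFilter(3 * raw, 5, 1), 3 * filt, tolerance = 1e-12)
  expect_error(bandpassFilter(raw, 1, 2), "sigmaLarge")
})

test_that("trackTS takes the brightest voxel, carries positions forward and
           breaks ties lexicographically", {
  arr <- array(0, dim = c(4, 3, 8, 8))
  arr[1, 2, 5, 6] <- 10          # frame 1: detection
  arr[2, , , ] <- 0.1            # frame 2: below threshold
  arr[3, 1, 3, 3] <- 8           # frame 3: new position
  arr[3, 2, 7, 2] <- 8           # tie with identical value
  arr[4, , , ] <- 0
  pos <- trackTS(arr, threshold = 1)
  expect_equal(unlist(pos[1, c("z", "y", "x")], use.names = FALSE), c(2, 5, 6))
  expect_false(pos$detected[2])
  expect_equal(unlist(pos[2, c("z", "y", "x")], use.names = FALSE), c(2, 5, 6))
  # tie: lowest (z, y, x) lexicographic index wins
  expect_equal(unlist(pos[3, c("z", "y", "x")], use.names = FALSE), c(1, 3, 3))
  # trailing undetected frame reuses frame 3's position
  expect_equal(unlist(pos[4, c("z", "y", "x")], use.names = FALSE), c(1, 3, 3))

  expect_error(trackTS(array(0, dim = c(2, 3, 4, 4)), threshold = 1),
               "never detected")
})

test_that("two-round Gaussian fitting recovers a planted TS and enforces the
           round-2 constraints", {
  spec <- smallMovieSpec(nFrames = 10, xySizePx = 40, cameraNoiseSd = 2,
                         backgroundLevel = 40,
                         bleachAmplitudes = c(1, 0, 0),
                         bleachRates = rep(0, 3))
  # eight bright frames, then the TS goes dark
  tsTrace <- intensityTrace(seq(0, 27, 3), c(rep(12, 8), 0, 0))
  sim <- simulateMovieStack(spec, tsTrace = tsTrace,
                            singleMoleculeIntensity = 600, seed = 3)
  filt <- array(0, dim = dim(sim$stack))
  for (f in 1:10) filt[f, , , ] <- bandpassFilter(sim$stack[f, , , ], 5, 1)
  pos <- trackTS(filt, threshold = median(filt) + 5 * mad(filt))
  q <- quantifyTSTrace(sim$stack, pos)
  planted <- 12 * 600
  expect_lt(median(abs(q$trace[1:8] - planted) / planted), 0.05)
  # dark frames quantify near zero under the round-2 constraints
  expect_lt(max(q$trace[9:10]), 0.1 * planted)
  # round-2 sigmas respect the constraint interval
  expect_true(all(q$fits$sigma_xy >= q$constraints$sigmaXy[1] - 1e-8))
  expect_true(all(q$fits$sigma_xy <= q$constraints$sigmaXy[2] + 1e-8))
  expect_true(all(q$fits$sigma_z >= q$constraints$sigmaZ[1] - 1e-8))
  expect_true(all(q$fits$sigma_z <= q$constraints$sigmaZ[2] + 1e-8))
  expect_true(all(q$fits$background == q$constraints$background))

  # too few pre-detected frames
  posBad <- pos; posBad$detected <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_error(quantifyTSTrace(sim$stack, posBad), "pre-detected")
})

test_that("calibration formula and its preconditions", {
  rec <- calibrationRecord(iMs2 = c(250, 500, 1000), iFinal = 500,
                           nNascFinal = 10)
  expect_equal(calibrateNascentCounts(rec), c(5, 10, 20))
  # calibration linearity: doubling all fluorescence leaves counts unchanged
  rec2 <- calibrationRecord(iMs2 = 2 * c(250, 500, 1000), iFinal = 1000,
                            nNascFinal = 10)
  expect_equal(calibrateNascentCounts(rec2), c(5, 10, 20))
  # TS dark at movie end
  recBad <- calibrationRecord(iMs2 = c(1, 2), iFinal = 0, nNascFinal = 0)
  expect_error(calibrateNascentCounts(recBad), "movie end")
})

test_that("single-molecule intensity is recovered from a calibration stack", {
  spec <- smallMovieSpec(xySizePx = 64, cameraNoiseSd = 2,
                         backgroundLevel = 40)
  cal <- simulateCalibrationStack(spec, nMolecules = 15,
                                  singleMoleculeIntensity = 800, seed = 4)
  sm <- singleMoleculeIntensity(cal$stack)
  expect_gt(sm$n, 5)
  expect_lt(abs(sm$intensity - 800) / 800, 0.15)
})

test_that("FRAP normalisation cancels global bleaching exactly", {
  # no bleach, constant signals: 1 everywhere
  expect_equal(frapNormalize(rep(5, 20), rep(100, 20), 1:5), rep(1, 20))

  tt <- seq(0, 40, 0.5)
  spotTrue <- c(rep(1, 10), 1 - 0.6 * exp(-tt / 5))
  bleach <- exp(-seq_along(spotTrue) / 200)   # global acquisition bleaching
  spot <- spotTrue * bleach * 80
  cell <- bleach * 4000                       # cell content constant
  out <- frapNormalize(spot, cell, prebleachFrames = 1:10)
  expect_equal(mean(out[1:10]), 1, tolerance = 1e-12)
  # normalisation removes the global decay exactly
  expect_equal(out, spotTrue, tolerance = 1e-9)
  expect_error(frapNormalize(c(1, 2), c(1, 0), 1), "zero")
})
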