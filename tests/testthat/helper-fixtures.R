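# Shared fixtures and independent oracles used across the test files.

# Reporter geometry used throughout unless a test needs a specific one
testGeom <- function() geneGeometry(lPre = 2000, lMs2 = 2800, lPost = 4500)

# Convoy regime reported for the HIV-1 reporter
hivParams <- function() convoyParams(nPol = 19, tSpace = 4.1, vEl = 4.1,
                                     tProc = 103)

# Independent event-list oracle for the convoy signal: per polymerase,
# tabulate entry/exit/release times and interpolate the piecewise-linear
# per-polymerase signal with approx(); sum over polymerases.
oracleConvoySignal <- function(t, nPol, tSpace, vEl, tProc, geom, t0 = 0) {
  v <- vEl * 1000 / 60
  out <- numeric(length(t))
  for (i in seq_len(nPol) - 1L) {
    ini <- t0 + i * tSpace
    enter <- ini + geom@lPre / v
    exit <- ini + (geom@lPre + geom@lMs2) / v
    release <- ini + (geom@lPre + geom@lMs2 + geom@lPost) / v + tProc
    s <- approx(x = c(enter, exit), y = c(0, 1), xout = t, rule = 2,
                yleft = 0, yright = 1)$y
    s[t < enter] <- 0
    s[t >= release] <- 0
    out <- out + s
  }
  out
}

# A small movie spec that keeps image tests fast
smallMovieSpec <- function(nFrames = 12, xySizePx = 48, ...)
  movieSpec(nFrames = nFrames, nZ = 9, xySizePx = xySizePx, ...)

# Population model completed from the HIV-1 smFISH means
hivPromoterModel <- function(invKIniS = 3.4, f1 = 0.8, invKOn2bMin = 30,
                             kOff1PerS = 1 / 110, invKOn1Min = 2) {
  m <- gridPointModel(invKIniS, f1, invKOn2bMin, kOff1PerS, invKOn1Min)
  solveConstrainedRates(m, populationSummary(492, 32))$model
}
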