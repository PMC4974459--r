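## Seeded generators for TS intensity traces and dwell-time samples. These
## emulate the measured inputs of the pipeline; every generator is a pure
## function of its arguments and the seed.

#' Simulate a noisy transcription-site intensity trace for one convoy
#'
#' Samples the convoy forward model at regular frame times and adds
#' per-frame measurement noise. In \code{"regular"} mode polymerases
#' initiate every \code{tSpace(params)} seconds and the noiseless trace
#' equals [tsIntensity()] exactly; in \code{"exponential"} mode the
#' inter-initiation gaps are i.i.d. exponential with mean
#' \code{tSpace(params)}, emulating stochastic initiation.
#'
#' @param params a \linkS4class{ConvoyParams} object.
#' @param geom a \linkS4class{GeneGeometry} object.
#' @param dt frame interval in seconds.
#' @param duration movie duration in seconds; if shorter than the visible
#'   cycle the returned trace carries a \code{"duration_truncated"} flag.
#' @param spacingMode \code{"regular"} or \code{"exponential"}.
#' @param noise a \linkS4class{NoiseModel}.
#' @param t0 initiation time of the first polymerase (s).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return An \linkS4class{IntensityTrace} in RNA equivalents.
#' @export
simulateConvoyTrace <- function(params, geom, dt = 3, duration = NULL,
                                spacingMode = c("regular", "exponential"),
                                noise = noiseModel(), t0 = 0, seed = NULL) {
  stopifnot(is(params, "ConvoyParams"), is(geom, "GeneGeometry"),
            is(noise, "NoiseModel"))
  validObject(params); validObject(geom); validObject(noise)
  spacingMode <- match.arg(spacingMode)
  ## default window: through the last release (regular spacing) plus margin
  if (is.null(duration))
    duration <- t0 + (params@nPol - 1) * params@tSpace +
      (geom@lPre + geom@lMs2 + geom@lPost) / .ntPerS(params@vEl) +
      params@tProc + 10 * dt
  times <- seq(0, duration, by = dt)
  withSeed(seed, {
    initTimes <- if (spacingMode == "regular") {
      t0 + (seq_len(params@nPol) - 1) * params@tSpace
    } else {
      gaps <- if (params@nPol > 1) rexp(params@nPol - 1, rate = 1 / params@tSpace)
              else numeric()
      t0 + c(0, cumsum(gaps))
    }
    values <- .convoySignal(times, initTimes, geom, params@vEl, params@tProc)
    if (noise@multiplicativeSd > 0)
      values <- values * (1 + rnorm(length(values), sd = noise@multiplicativeSd))
    if (noise@additiveSd > 0)
      values <- values + rnorm(length(values), sd = noise@additiveSd)
    flags <- character()
    lastRelease <- max(initTimes) +
      (geom@lPre + geom@lMs2 + geom@lPost) / .ntPerS(params@vEl) + params@tProc
    if (duration < lastRelease) flags <- "duration_truncated"
    intensityTrace(times, values, units = "rna_equivalents", flags = flags)
  })
}

## Exact (Gillespie) path of the four-state promoter over [0, duration].
## Returns data.frame(state, start, end); state in {"ON","OFF1","OFF2a","OFF2b"}.
.promoterPath <- function(model, duration, initState = NULL) {
  states <- c("ON", "OFF1", "OFF2a", "OFF2b")
  if (is.null(initState)) {
    pi0 <- .stationaryWeights(model)
    initState <- sample.int(4L, 1L, prob = pi0)
  }
  s <- initState
  t <- 0
  recS <- integer(0); recA <- numeric(0); recB <- numeric(0)
  while (t < duration) {
    rateOut <- switch(s,
      model@kOff1,                      # ON
      model@kOn1 + model@kOff2,         # OFF1
      model@kOn2a,                      # OFF2a
      model@kOn2b)                      # OFF2b
    dwell <- if (rateOut > 0) rexp(1, rateOut) else Inf
    tEnd <- min(t + dwell, duration)
    recS <- c(recS, s); recA <- c(recA, t); recB <- c(recB, tEnd)
    t <- tEnd
    if (t >= duration) break
    s <- switch(s,
      2L,                                              # ON -> OFF1
      {                                                # OFF1 -> ?
        p <- c(model@kOn1, model@f1 * model@kOff2,
               (1 - model@f1) * model@kOff2)
        c(1L, 3L, 4L)[sample.int(3L, 1L, prob = p)]
      },
      2L, 2L)                                          # OFF2a/b -> OFF1
  }
  data.frame(state = states[recS], start = recA, end = recB,
             stringsAsFactors = FALSE)
}

#' Simulate a promoter state path and the resulting TS intensity trace
#'
#' Runs an exact (event-driven) simulation of the four-state promoter;
#' while ON, polymerases initiate as a Poisson process with rate
#' \code{kIni}. Each initiated polymerase is tracked through the gene
#' exactly as in the convoy model, and the TS intensity is the
#' superposition of their per-polymerase signals.
#'
#' @param model a \linkS4class{PromoterModel}; \code{kIni} is used as the
#'   initiation rate while ON.
#' @param geom a \linkS4class{GeneGeometry} object.
#' @param vEl elongation rate of spawned polymerases, kb/min.
#' @param tProc processing/release time of spawned polymerases, s.
#' @param dt frame interval in seconds.
#' @param duration movie duration in seconds.
#' @param seed integer seed, or NULL.
#' @return A list with \code{trace} (an \linkS4class{IntensityTrace}),
#'   \code{statePath} (character vector, promoter state at each frame),
#'   \code{initTimes} (initiation times in s) and \code{path} (the raw
#'   state-interval table).
#' @export
simulatePromoterTrace <- function(model, geom, vEl = 4.1, tProc = 103,
                                  dt = 3, duration = 1800, seed = NULL) {
  stopifnot(is(model, "PromoterModel"), is(geom, "GeneGeometry"))
  validObject(model); validObject(geom)
  withSeed(seed, {
    path <- .promoterPath(model, duration)
    on <- path[path$state == "ON", , drop = FALSE]
    initTimes <- numeric(0)
    if (nrow(on) && model@kIni > 0) {
      for (i in seq_len(nrow(on))) {
        len <- on$end[i] - on$start[i]
        k <- rpois(1, model@kIni * len)
        if (k > 0) initTimes <- c(initTimes, sort(runif(k, on$start[i], on$end[i])))
      }
    }
    times <- seq(0, duration, by = dt)
    values <- if (length(initTimes))
      .convoySignal(times, initTimes, geom, vEl, tProc) else numeric(length(times))
    idx <- findInterval(times, path$start, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L; idx[idx > nrow(path)] <- nrow(path)
    list(trace = intensityTrace(times, values, units = "rna_equivalents"),
         statePath = path$state[idx],
         initTimes = initTimes,
         path = path)
  })
}

#' Sample dwell times from a mixture of exponentials
#'
#' @param mix a \linkS4class{DwellMixture}.
#' @param n number of samples (>= 1).
#' @param seed integer seed, or NULL.
#' @return Numeric vector of \code{n} i.i.d. dwell times in seconds.
#' @examples
#' d <- sampleDwellTimes(dwellMixture(c(540, 2040), c(0.77, 0.23)), 1000, seed = 1)
#' mean(d)   # ~ 0.77*540 + 0.23*2040
#' @export
sampleDwellTimes <- function(mix, n, seed = NULL) {
  stopifnot(is(mix, "DwellMixture"))
  validObject(mix)
  if (n < 1) stop("'n' must be >= 1")
  withSeed(seed, {
    comp <- sample.int(length(mix@taus), n, replace = TRUE, prob = mix@weights)
    rexp(n, rate = 1) * mix@taus[comp]
  })
}
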