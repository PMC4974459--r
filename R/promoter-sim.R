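## Population Monte-Carlo simulation of the four-state promoter model.
## Two schemes: the fixed-step scheme (per-step transition probabilities
## rate*dt, compiled) and an exact event-driven scheme used as cross-check.

.STATE_NAMES <- c("ON", "OFF1", "OFF2a", "OFF2b")

## per-state total exit rates of the promoter chain
.exitRates <- function(model) {
  c(ON = model@kOff1,
    OFF1 = model@kOn1 + model@kOff2,
    OFF2a = model@kOn2a,
    OFF2b = model@kOn2b)
}

#' Simulate a population of cells under the promoter model
#'
#' Simulates \code{nCells} independent cells for \code{nSteps * dt} seconds
#' and returns the end-of-run nascent and mature RNA counts per cell.
#' Initial promoter states are drawn from the analytic stationary
#' distribution; RNA counts start at zero, which is immaterial for runs much
#' longer than \code{1/kDeg}.
#'
#' Two schemes are available. \code{"fixed_step"} is the reference scheme:
#' discrete steps of \code{dt} seconds in which the promoter switches with
#' probability \code{rate * dt}, initiation while ON adds
#' \code{Poisson(kIni * dt)} nascent RNAs, each nascent RNA converts to
#' mature with probability \code{kRelease * dt} and each mature RNA decays
#' with probability \code{kDeg * dt}. Its stability precondition
#' \code{dt * rate < 0.1} is enforced for every promoter switching rate and
#' the per-molecule rates (initiation is exempt: the Poisson draw is exact).
#' \code{"exact"} is an event-driven sampler: the promoter path is simulated
#' by the Gillespie algorithm and, conditional on the path, the end-of-run
#' nascent and mature counts are independent Poisson draws whose means are
#' closed-form integrals of the initiation process thinned by the
#' release/decay kinetics. It has no time-discretisation error and serves
#' as a cross-check of the fixed-step scheme.
#'
#' @param model a \linkS4class{PromoterModel}.
#' @param nCells number of independent cells.
#' @param nSteps number of fixed steps (scheme \code{"fixed_step"}).
#' @param dt step size in seconds.
#' @param seed integer seed, or NULL.
#' @param scheme \code{"fixed_step"} or \code{"exact"}.
#' @param returnStates if TRUE, also return the final promoter state per
#'   cell (fixed-step scheme only).
#' @return A \linkS4class{CellCounts} object with attribute
#'   \code{"totalTimeS"} giving the total simulated time in seconds and,
#'   when requested, attribute \code{"finalState"}.
#' @examples
#' m <- gridPointModel(3.4, 0.8, 30, 1/110, 2)
#' m <- solveConstrainedRates(m, populationSummary(492, 32))$model
#' simulatePopulation(m, nCells = 50, nSteps = 3600, dt = 1, seed = 1)
#' @export
simulatePopulation <- function(model, nCells, nSteps = 36000, dt = 1,
                               seed = NULL,
                               scheme = c("fixed_step", "exact"),
                               returnStates = FALSE) {
  stopifnot(is(model, "PromoterModel"))
  validObject(model)
  scheme <- match.arg(scheme)
  totalTime <- nSteps * dt
  if (scheme == "fixed_step") {
    checks <- c(kOff1 = model@kOff1, `kOn1 + kOff2` = model@kOn1 + model@kOff2,
                kOn2a = model@kOn2a, kOn2b = model@kOn2b,
                kRelease = model@kRelease, kDeg = model@kDeg)
    bad <- checks * dt >= 0.1
    if (any(bad))
      stop(sprintf("fixed-step stability violated: dt * %s = %.3g >= 0.1",
                   names(checks)[which(bad)[1L]],
                   (checks * dt)[which(bad)[1L]]))
  }
  withSeed(seed, {
    pi0 <- .stationaryWeights(model)
    init <- sample.int(4L, nCells, replace = TRUE, prob = pi0)
    if (scheme == "fixed_step") {
      rates <- c(kOn1 = model@kOn1, kOff1 = model@kOff1, kOff2 = model@kOff2,
                 f1 = model@f1, kOn2a = model@kOn2a, kOn2b = model@kOn2b,
                 kIni = model@kIni, kRelease = model@kRelease,
                 kDeg = model@kDeg)
      m <- cpp_simulate_population(rates, init, as.integer(nSteps), dt)
      res <- cellCounts(m[, 1L], m[, 2L])
      if (returnStates) attr(res, "finalState") <- .STATE_NAMES[m[, 3L]]
    } else {
      res <- .simulatePopulationExact(model, nCells, totalTime, init)
    }
    attr(res, "totalTimeS") <- totalTime
    res
  })
}

## Exact scheme: batch Gillespie over all cells, accumulating the Poisson
## means of the end-of-run nascent and mature counts. An initiation at time
## u is still nascent at T with probability exp(-kRelease*(T-u)) and mature
## at T with probability kRelease/(kRelease-kDeg) *
## (exp(-kDeg*(T-u)) - exp(-kRelease*(T-u))); categories of a marked Poisson
## process are independent Poisson given the promoter path, so per-cell
## counts are Poisson draws with the integrated means.
.simulatePopulationExact <- function(model, nCells, totalTime, initState) {
  if (model@kIni > 0 && (model@kRelease <= 0 || model@kDeg <= 0))
    stop("exact scheme requires kRelease > 0 and kDeg > 0 when kIni > 0")
  kR <- model@kRelease; kD <- model@kDeg; T <- totalTime
  exitRates <- unname(.exitRates(model))
  state <- initState
  tNow <- numeric(nCells)
  lamN <- numeric(nCells)
  lamM <- numeric(nCells)
  pOff1 <- c(model@kOn1, model@f1 * model@kOff2, (1 - model@f1) * model@kOff2)
  active <- rep(TRUE, nCells)
  while (any(active)) {
    idx <- which(active)
    r <- exitRates[state[idx]]
    dwell <- ifelse(r > 0, rexp(length(idx), pmax(r, .Machine$double.xmin)), Inf)
    tEnd <- pmin(tNow[idx] + dwell, T)
    onSel <- state[idx] == 1L
    if (any(onSel) && model@kIni > 0) {
      i2 <- idx[onSel]
      a <- tNow[i2]; b <- tEnd[onSel]
      eRel <- exp(-kR * (T - b)) - exp(-kR * (T - a))
      lamN[i2] <- lamN[i2] + model@kIni / kR * eRel
      if (abs(kR - kD) > 1e-12 * max(kR, kD)) {
        eDeg <- exp(-kD * (T - b)) - exp(-kD * (T - a))
        lamM[i2] <- lamM[i2] + model@kIni * kR / (kR - kD) *
          (eDeg / kD - eRel / kR)
      } else {
        # kRelease == kDeg limit: p_mature(d) = kR * d * exp(-kR * d)
        dA <- T - a; dB <- T - b
        F <- function(d) -exp(-kR * d) * (d + 1 / kR)
        lamM[i2] <- lamM[i2] + model@kIni * kR * (F(dB) - F(dA))
      }
    }
    tNow[idx] <- tEnd
    done <- tEnd >= T
    if (any(!done)) {
      i3 <- idx[!done]
      s <- state[i3]
      newS <- integer(length(i3))
      newS[s == 1L] <- 2L
      newS[s == 3L] <- 2L
      newS[s == 4L] <- 2L
      off1 <- which(s == 2L)
      if (length(off1)) {
        u <- runif(length(off1)) * sum(pOff1)
        dest <- ifelse(u < pOff1[1L], 1L, ifelse(u < pOff1[1L] + pOff1[2L], 3L, 4L))
        newS[off1] <- dest
      }
      state[i3] <- newS
    }
    active[idx[done]] <- FALSE
  }
  cellCounts(rpois(nCells, lamN), rpois(nCells, lamM))
}
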