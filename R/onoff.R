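## Threshold-based ON/OFF segmentation of long-movie traces and
## maximum-likelihood exponential / bi-exponential dwell-time inference.

#' Segment a trace into ON and OFF periods by thresholding
#'
#' The trace is smoothed with a centred moving average, frames are
#' classified as ON (above threshold) or OFF, and runs shorter than
#' \code{minStateFrames} are merged into the flanking state (merging
#' repeats until stable; the preceding state wins). The first and last
#' periods are flagged censored because their true onset/offset falls
#' outside the movie.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param cfg an \linkS4class{OnOffConfig}.
#' @return A data.frame with columns \code{state} ("ON"/"OFF"),
#'   \code{start_s}, \code{duration_s} and \code{censored}.
#' @export
segmentOnOff <- function(trace, cfg) {
  stopifnot(is(trace, "IntensityTrace"), is(cfg, "OnOffConfig"))
  validObject(cfg)
  v <- traceValues(trace)
  if (length(v) < cfg@smoothWindow)
    stop("trace shorter than the smoothing window")
  dt <- frameInterval(trace)
  sm <- movingAverage(v, cfg@smoothWindow)
  on <- sm > cfg@threshold
  ## merge short runs into the flanking state until stable
  repeat {
    r <- runs(on)
    short <- which(r$length < cfg@minStateFrames)
    short <- short[!(short %in% c(1L, nrow(r)))]   # keep censored edge runs
    if (!length(short)) break
    i <- short[1L]
    idx <- r$start[i]:(r$start[i] + r$length[i] - 1L)
    on[idx] <- r$value[i - 1L]                     # preceding state wins
  }
  r <- runs(on)
  t0 <- traceTimes(trace)[1L]
  data.frame(
    state = ifelse(r$value, "ON", "OFF"),
    start_s = t0 + (r$start - 1L) * dt,
    duration_s = r$length * dt,
    censored = seq_len(nrow(r)) %in% c(1L, nrow(r)),
    stringsAsFactors = FALSE)
}

## log-likelihood of an exponential mixture, with optional right-censoring
.dwellLogLik <- function(d, cens, taus, w) {
  ll <- 0
  if (any(!cens)) {
    x <- d[!cens]
    dens <- sapply(seq_along(taus), function(k) w[k] / taus[k] * exp(-x / taus[k]))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1L)
    ll <- ll + sum(log(pmax(rowSums(dens), 1e-300)))
  }
  if (any(cens)) {
    x <- d[cens]
    surv <- sapply(seq_along(taus), function(k) w[k] * exp(-x / taus[k]))
    if (is.null(dim(surv))) surv <- matrix(surv, nrow = 1L)
    ll <- ll + sum(log(pmax(rowSums(surv), 1e-300)))
  }
  ll
}

#' Maximum-likelihood exponential dwell-time fit
#'
#' Fits dwell-time durations with a single exponential (\code{model =
#' "mono"}; the MLE of the time constant is the sample mean) or a
#' two-component exponential mixture (\code{model = "bi"}) via
#' expectation-maximisation with seeded random restarts. Censored
#' durations (movie-boundary periods) are excluded by default or, with
#' \code{censoring = "survival"}, contribute survival-function terms to the
#' likelihood and are handled inside EM via their conditional expectations.
#'
#' @param durations numeric vector of dwell times in seconds.
#' @param model \code{"mono"} or \code{"bi"}.
#' @param censored logical vector marking right-censored durations.
#' @param censoring \code{"exclude"} (default) or \code{"survival"}.
#' @param nRestarts EM restarts for the bi-exponential fit.
#' @param maxIter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed integer seed for the restarts, or NULL.
#' @return A \linkS4class{DwellFit}.
#' @examples
#' d <- sampleDwellTimes(dwellMixture(c(540, 2040), c(0.77, 0.23)), 2000, seed = 2)
#' fitDwell(d, model = "bi", seed = 1)
#' @export
fitDwell <- function(durations, model = c("mono", "bi"),
                     censored = rep(FALSE, length(durations)),
                     censoring = c("exclude", "survival"),
                     nRestarts = 10L, maxIter = 500L, tol = 1e-8,
                     seed = NULL) {
  model <- match.arg(model)
  censoring <- match.arg(censoring)
  stopifnot(length(censored) == length(durations))
  if (censoring == "exclude") {
    durations <- durations[!censored]
    censored <- rep(FALSE, length(durations))
  }
  d <- durations; cens <- censored
  nUnc <- sum(!cens)
  if (model == "mono") {
    if (nUnc < 1L) stop("need at least one uncensored duration")
    tau <- sum(d) / nUnc          # censored times add exposure, not events
    return(new("DwellFit", model = "mono", taus = tau, weights = 1,
               logLik = .dwellLogLik(d, cens, tau, 1)))
  }
  if (length(d) < 10L) stop("bi-exponential fit needs at least 10 durations")
  withSeed(seed, {
    best <- NULL
    mu <- mean(d)
    for (r in seq_len(nRestarts)) {
      taus <- sort(mu * c(runif(1, 0.1, 0.9), runif(1, 1.1, 4)))
      w <- c(runif(1, 0.3, 0.9))
      w <- c(w, 1 - w)
      llOld <- -Inf
      for (it in seq_len(maxIter)) {
        ## E step: responsibilities (density for events, survival for censored)
        g1 <- ifelse(cens, w[1L] * exp(-d / taus[1L]),
                     w[1L] / taus[1L] * exp(-d / taus[1L]))
        g2 <- ifelse(cens, w[2L] * exp(-d / taus[2L]),
                     w[2L] / taus[2L] * exp(-d / taus[2L]))
        tot <- pmax(g1 + g2, 1e-300)
        g1 <- g1 / tot; g2 <- 1 - g1
        ## M step; censored observations contribute d + tau_k expected time
        e1 <- ifelse(cens, d + taus[1L], d)
        e2 <- ifelse(cens, d + taus[2L], d)
        w <- c(mean(g1), mean(g2))
        taus <- c(sum(g1 * e1) / sum(g1), sum(g2 * e2) / sum(g2))
        taus <- pmax(taus, 1e-9)
        ll <- .dwellLogLik(d, cens, taus, w)
        if (is.finite(ll) && abs(ll - llOld) < tol * (abs(ll) + 1)) break
        llOld <- ll
      }
      ll <- .dwellLogLik(d, cens, taus, w)
      if (is.null(best) || ll > best$ll)
        best <- list(taus = taus, w = w, ll = ll)
    }
    ord <- order(best$taus)
    new("DwellFit", model = "bi", taus = best$taus[ord],
        weights = best$w[ord], logLik = best$ll)
  })
}
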