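## Detection of isolated transcription cycles in short-movie traces and
## least-squares fitting of the convoy model to each cycle, plus the pooled
## cohort summaries (UP-ramp regression, convoy/gap statistics).

#' Find isolated transcription cycles in a TS intensity trace
#'
#' Returns maximal above-threshold segments. A segment is \emph{isolated}
#' when it is flanked on both sides by at least \code{minOffFrames} frames
#' below the threshold; segments touching the trace boundaries are returned
#' with \code{isolated = FALSE} and should normally be excluded from fits.
#'
#' @param trace an \linkS4class{IntensityTrace} in RNA equivalents.
#' @param offThreshold intensity below which the TS counts as silent
#'   (RNA equivalents).
#' @param minOffFrames minimum silent frames required on each side.
#' @param smoothWindow odd moving-average window applied before
#'   thresholding (1 disables smoothing).
#' @param minOnFrames above-threshold runs shorter than this are treated
#'   as noise blips and discarded.
#' @return A list of \linkS4class{TranscriptionCycle} objects.
#' @export
findIsolatedCycles <- function(trace, offThreshold = 0.5, minOffFrames = 3L,
                               smoothWindow = 3L, minOnFrames = 3L) {
  stopifnot(is(trace, "IntensityTrace"))
  v <- traceValues(trace)
  if (!length(v)) stop("empty trace")
  if (smoothWindow > 1L && length(v) >= smoothWindow)
    v <- movingAverage(v, smoothWindow)
  above <- v > offThreshold
  rr <- runs(above)
  for (i in which(rr$value & rr$length < minOnFrames))
    above[rr$start[i]:(rr$start[i] + rr$length[i] - 1L)] <- FALSE
  if (!any(above)) return(list())
  r <- runs(above)
  segs <- r[r$value, , drop = FALSE]
  out <- vector("list", nrow(segs))
  n <- length(v)
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$start[i] + segs$length[i] - 1L
    offBefore <- if (s == 1L) 0L else {
      j <- which(r$value & r$start < s)
      prevEnd <- if (length(j)) max(r$start[j] + r$length[j] - 1L) else 0L
      s - 1L - prevEnd
    }
    offAfter <- if (e == n) 0L else {
      j <- which(r$value & r$start > s)
      nextStart <- if (length(j)) min(r$start[j]) else n + 1L
      nextStart - 1L - e
    }
    touchesEdge <- s == 1L || e == n
    iso <- !touchesEdge && offBefore >= minOffFrames && offAfter >= minOffFrames
    ## descriptive phase boundaries from 10%/90%-of-peak crossings,
    ## clamped to a consistent ordering
    seg <- v[s:e]
    pk <- max(seg); iPk <- which.max(seg)
    upStart <- s - 1L + which(seg[seq_len(iPk)] >= 0.1 * pk)[1L]
    upEnd <- s - 1L + which(seg >= 0.9 * pk)[1L]
    downStart <- s - 1L + tail(which(seg >= 0.9 * pk), 1L)
    downEnd <- s - 1L + tail(which(seg >= 0.1 * pk), 1L) + 1L
    upStart <- max(s, min(upStart, e - 1L))
    upEnd <- max(upStart + 1L, min(upEnd, e))
    downStart <- max(upEnd, min(downStart, e))
    downEnd <- max(downStart + 1L, min(downEnd, e + 1L))
    out[[i]] <- new("TranscriptionCycle", frameStart = s, frameEnd = e,
                    upStart = upStart, upEnd = upEnd,
                    downStart = downStart, downEnd = downEnd,
                    isolated = iso)
  }
  out
}

## sum of squares of the convoy model against a segment, given a candidate
## integer nPol and continuous theta = (tSpace, vEl, tProc, t0)
.cycleSS <- function(theta, n, tt, vv, geom) {
  if (!all(is.finite(theta)) || theta[1L] < 0 || theta[2L] <= 0 ||
      theta[3L] < 0) return(1e30)
  initTimes <- theta[4L] + (seq_len(n) - 1) * theta[1L]
  sum((vv - .convoySignal(tt, initTimes, geom, theta[2L], theta[3L]))^2)
}

## Corner geometry of the (near-)trapezoidal cycle: crossing times of the
## smoothed segment at fractions of the peak, interpolated linearly.
## Returns list(peak, A, B, C, D, riseSlope): A/B rise foot and shoulder,
## C/D fall shoulder and foot.
.cycleCorners <- function(tt, vv) {
  w <- if (length(vv) %% 2L == 0L) 3L else min(3L, length(vv))
  sm <- movingAverage(vv, w)
  pk <- max(sm)
  iPk <- which.max(sm)
  crossRise <- function(q) {
    pre <- sm[seq_len(iPk)]
    i <- which(pre[-iPk] < q & pre[-1L] >= q)
    if (!length(i)) return(tt[1L])
    i <- tail(i, 1L)
    tt[i] + (q - pre[i]) / (pre[i + 1L] - pre[i]) * (tt[i + 1L] - tt[i])
  }
  crossFall <- function(q) {
    post <- sm[iPk:length(sm)]
    i <- which(post[-length(post)] >= q & post[-1L] < q)
    if (!length(i)) return(tt[length(tt)])
    i <- i[1L]
    j <- iPk + i - 1L
    tt[j] + (sm[j] - q) / (sm[j] - sm[j + 1L]) * (tt[j + 1L] - tt[j])
  }
  t25r <- crossRise(0.25 * pk); t75r <- crossRise(0.75 * pk)
  t75f <- crossFall(0.75 * pk); t25f <- crossFall(0.25 * pk)
  dtf <- tt[2L] - tt[1L]
  riseSlope <- 0.5 * pk / max(t75r - t25r, dtf / 2)
  fallSlope <- 0.5 * pk / max(t25f - t75f, dtf / 2)
  list(peak = pk,
       A = t25r - 0.25 * pk / riseSlope,
       B = t75r + 0.25 * pk / riseSlope,
       C = t75f - 0.25 * pk / fallSlope,
       D = t25f + 0.25 * pk / fallSlope,
       riseSlope = riseSlope)
}

.VEL_GRID <- c(0.5, 1, 2, 3, 4, 6, 10, 15)

## Analytic initial guesses for (tSpace, tProc, t0) at fixed nPol and a
## candidate vEl. The extrapolated rise corners sit on the linear midline,
## offset from the true corners by half the repeat transit time
## lMs2 / (2v); the fall is exactly linear. Two regimes:
##  - plateau: peak = nPol, fall duration = (nPol - 1) * tSpace
##  - truncated: rise slope = 1 / tSpace, fall = lPost / v + tProc
.cycleInits <- function(n, vel, corners, geom, dtf) {
  v <- .ntPerS(vel)
  half <- geom@lMs2 / (2 * v)
  t0 <- corners$A - geom@lPre / v - half
  total <- corners$D - corners$A + half      # D - t0 - lPre / v
  F <- max(corners$D - corners$C, 0)         # fall duration
  inits <- list()
  if (n > 1) {
    tsP <- max(F / (n - 1), 0.05)
    tprocP <- max(total - (n - 1) * tsP - (geom@lMs2 + geom@lPost) / v, 0)
    inits[["plateau"]] <- c(tSpace = tsP, vEl = vel, tProc = tprocP, t0 = t0)
  }
  tsT <- max(1 / corners$riseSlope, 0.05)
  tprocT <- max(F - geom@lPost / v, 0)
  inits[["truncated"]] <- c(tSpace = tsT, vEl = vel, tProc = tprocT, t0 = t0)
  inits
}

## 3-D subproblem: optimise (tSpace, tProc, t0) at fixed nPol and vEl
.fitAtVel <- function(n, init, tt, vv, geom, maxit = 400) {
  vel <- init[2L]
  obj <- function(th3) .cycleSS(c(th3[1L], vel, th3[2L], th3[3L]),
                                n, tt, vv, geom)
  o <- optim(init[c(1L, 3L, 4L)], obj, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = 1e-12))
  list(theta = c(o$par[1L], vel, o$par[2L], o$par[3L]), ss = o$value)
}

## Full fit at fixed integer nPol: profile vEl over a coarse grid with the
## 3-D subproblem, then polish all four continuous parameters, optionally
## with jittered restarts.
.polishFixedN <- function(n, corners, geom, tt, vv, starts = 1L,
                          jitterSd = 0.15, ssStop = 0) {
  dtf <- tt[2L] - tt[1L]
  best <- NULL
  iBest <- 1L
  for (i in seq_along(.VEL_GRID)) {
    vel <- .VEL_GRID[i]
    inits <- .cycleInits(n, vel, corners, geom, dtf)
    ss0 <- vapply(inits, .cycleSS, numeric(1), n = n, tt = tt, vv = vv,
                  geom = geom)
    r <- .fitAtVel(n, inits[[which.min(ss0)]], tt, vv, geom)
    if (is.null(best) || r$ss < best$ss) { best <- r; iBest <- i }
    if (best$ss <= ssStop) break
  }
  polish <- function(th0) {
    th0[1L] <- max(th0[1L], 0.05); th0[2L] <- min(max(th0[2L], 0.1), 20)
    th0[3L] <- max(th0[3L], 0)
    o <- optim(th0, .cycleSS, n = n, tt = tt, vv = vv, geom = geom,
               method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-12))
    optim(o$par, .cycleSS, n = n, tt = tt, vv = vv, geom = geom,
          method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-12))
  }
  ## alternate a continuous vEl profile with a joint polish until the
  ## objective stops improving (the transit-dominated regime needs a few
  ## passes to escape shallow basins)
  for (pass in 1:3) {
    if (best$ss <= ssStop) break
    velC <- best$theta[2L]
    velLo <- if (pass == 1L) .VEL_GRID[max(iBest - 1L, 1L)] else velC / 1.5
    velHi <- if (pass == 1L) .VEL_GRID[min(iBest + 1L, length(.VEL_GRID))]
             else velC * 1.5
    if (velHi > velLo) {
      th3 <- best$theta[c(1L, 3L, 4L)]
      profOne <- function(vel) {
        .fitAtVel(n, c(th3[1L], vel, th3[2L], th3[3L]), tt, vv, geom,
                  maxit = 300)$ss
      }
      op <- stats::optimize(profOne, interval = c(velLo, velHi),
                            tol = 0.005 * velC)
      r <- .fitAtVel(n, c(th3[1L], op$minimum, th3[2L], th3[3L]), tt, vv,
                     geom)
      if (r$ss < best$ss) best <- r
    }
    ssBefore <- best$ss
    o <- polish(best$theta)
    if (o$value < best$ss) best <- list(theta = o$par, ss = o$value)
    if (best$ss > ssBefore * (1 - 1e-4)) break
  }
  if (starts > 1L && best$ss > ssStop) {
    for (k in seq_len(starts - 1L)) {
      th0 <- best$theta
      th0[1:3] <- th0[1:3] * exp(rnorm(3L, sd = jitterSd))
      th0[4L] <- th0[4L] + rnorm(1L, sd = 1.5 * dtf)
      o <- polish(th0)
      if (o$value < best$ss) best <- list(theta = o$par, ss = o$value)
    }
  }
  best
}

## profile SS over vEl with the other continuous parameters re-optimised
.profileVel <- function(vel, n, theta, tt, vv, geom) {
  f <- function(th3) {
    .cycleSS(c(th3[1L], vel, th3[2L], th3[3L]), n, tt, vv, geom)
  }
  o <- optim(theta[c(1L, 3L, 4L)], f, method = "Nelder-Mead",
             control = list(maxit = 500, reltol = 1e-12))
  o$value
}

#' Fit the convoy model to one transcription cycle
#'
#' Least-squares fit of [tsIntensity()] to the cycle segment over the four
#' convoy parameters plus the nuisance onset time \code{t0}. The number of
#' polymerases is optimised over an integer grid spanning +/-50% around the
#' peak-intensity estimate (the plateau equals \code{nPol} when present);
#' the continuous parameters are fitted by multi-start Nelder-Mead within
#' bounds. Ties in residual between adjacent \code{nPol} values break
#' toward the smaller convoy (parsimony).
#'
#' When the cycle has no plateau the elongation rate is unidentifiable from
#' above: the residual profile over \code{vEl} is flat. The fit detects
#' this by re-optimising with \code{vEl} doubled; if the root-mean-square
#' residual changes by less than 1% (relative, with a floor of 1e-6 of the
#' peak), \code{vElIsLowerBound} is set and the reported \code{vEl} is the
#' smallest value whose profiled residual stays within 1% of the optimum.
#'
#' @param trace an \linkS4class{IntensityTrace} in RNA equivalents.
#' @param cycle a \linkS4class{TranscriptionCycle} from
#'   [findIsolatedCycles()], or NULL to fit the whole trace.
#' @param geom a \linkS4class{GeneGeometry}.
#' @param pad frames of below-threshold context included on each side of
#'   the segment (anchors the baseline).
#' @param nStarts multi-starts for the refinement stage.
#' @param seed integer seed for the start jitter, or NULL.
#' @return A \linkS4class{FittedConvoy}.
#' @export
fitConvoyCycle <- function(trace, cycle = NULL, geom = geneGeometry(),
                           pad = 3L, nStarts = 5L, seed = NULL) {
  stopifnot(is(trace, "IntensityTrace"), is(geom, "GeneGeometry"))
  tAll <- traceTimes(trace); vAll <- traceValues(trace)
  if (is.null(cycle)) {
    sel <- seq_along(vAll)
  } else {
    stopifnot(is(cycle, "TranscriptionCycle"))
    sel <- max(1L, cycle@frameStart - pad):min(length(vAll), cycle@frameEnd + pad)
  }
  tt <- tAll[sel]; vv <- vAll[sel]
  if (length(tt) < 8L) stop("cycle must span at least 8 frames")
  withSeed(seed, {
    dtf <- tt[2L] - tt[1L]
    corners <- .cycleCorners(tt, vv)
    pk <- corners$peak
    n0 <- max(1L, round(pk))
    ## duration-based estimates: in the plateau regime the fall spans
    ## (nPol - 1) * tSpace with rise slope 1 / tSpace; in the truncated
    ## regime the full extent bounds (nPol - 1) * tSpace from above
    n1 <- max(1L, round((corners$D - corners$C) * corners$riseSlope + 1))
    n2 <- max(1L, round((corners$D - corners$A) * corners$riseSlope + 1))
    lo <- max(1L, floor(0.5 * min(n0, n1)))
    hi <- min(ceiling(1.1 * max(n0, n1, n2)) + 1L, max(n0, n1) + 45L)
    nCand <- lo:hi
    ## coarse pass: score analytic initial guesses only (no optimisation)
    velCoarse <- c(1, 2, 4, 8)
    ssC <- vapply(nCand, function(n) {
      min(vapply(velCoarse, function(vel)
        min(vapply(.cycleInits(n, vel, corners, geom, dtf), .cycleSS,
                   numeric(1), n = n, tt = tt, vv = vv, geom = geom)),
        numeric(1)))
    }, numeric(1))
    ## refine the best coarse candidates plus the peak-value neighbourhood
    ## (the plateau equals nPol exactly whenever a plateau exists)
    keep <- unique(c(order(ssC)[seq_len(min(3L, length(nCand)))],
                     which(nCand %in% c(n0 - 1L, n0, n0 + 1L))))
    keep <- keep[order(ssC[keep])]        # most promising first
    perfect <- 1e-10 * sum(vv^2)
    best <- NULL
    for (j in keep) {
      r <- .polishFixedN(nCand[j], corners, geom, tt, vv, starts = nStarts,
                         ssStop = perfect)
      ## parsimony tie-break: strictly better required to displace smaller n
      if (is.null(best) || r$ss < best$ss * (1 - 1e-9) ||
          (abs(r$ss - best$ss) <= best$ss * 1e-9 && nCand[j] < best$n)) {
        best <- r; best$n <- nCand[j]
      }
      if (best$ss <= perfect) break
    }
    if (!is.finite(best$ss) || best$ss >= 1e30)
      stop("convoy fit did not converge")
    ## final polish rounds until the objective stalls
    repeat {
      o <- optim(best$theta, .cycleSS, n = best$n, tt = tt, vv = vv,
                 geom = geom, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-15))
      if (o$value >= best$ss * (1 - 1e-4)) {
        if (o$value < best$ss) best$theta <- o$par; best$ss <- min(o$value, best$ss)
        break
      }
      best$theta <- o$par; best$ss <- o$value
    }
    theta <- best$theta
    rmse <- sqrt(best$ss / length(vv))
    floorR <- 1e-6 * max(pk, 1)
    ssUp <- .profileVel(2 * theta[2L], best$n, theta, tt, vv, geom)
    rmseUp <- sqrt(ssUp / length(vv))
    flat <- (rmseUp - rmse) / max(rmse, floorR) < 0.01
    ## no plateau in the fitted cycle: the trapezoid envelope leaves vEl
    ## constrained only from below, whatever the sub-frame residual says
    fittedTrunc <- analyticDurations(
      convoyParams(best$n, max(theta[1L], 1e-6), theta[2L], theta[3L]),
      geom)$truncated
    flat <- flat || fittedTrunc
    velOut <- theta[2L]
    if (flat) {
      ## walk vEl down to the smallest value within 1% of the optimum
      vel <- theta[2L]
      repeat {
        velTry <- vel / 1.15
        if (velTry < 0.05) break
        rmseTry <- sqrt(.profileVel(velTry, best$n, theta, tt, vv, geom) /
                          length(vv))
        if ((rmseTry - rmse) / max(rmse, floorR) >= 0.01) break
        vel <- velTry
      }
      velOut <- vel
    }
    unc <- .fitUncertainty(best$n, c(theta[1L], velOut, theta[3L], theta[4L]),
                           tt, vv, geom, rmse)
    new("FittedConvoy",
        params = convoyParams(best$n, theta[1L], velOut, theta[3L]),
        t0 = unname(theta[4L]), vElIsLowerBound = flat,
        residualNorm = rmse, uncertainty = unc)
  })
}

## crude per-parameter standard errors from the SS curvature (diagonal
## finite differences); nPol uncertainty from the residual gap to n +/- 1
.fitUncertainty <- function(n, theta, tt, vv, geom, rmse) {
  sig2 <- max(rmse^2, 1e-12)
  se <- numeric(4L)
  h <- pmax(abs(theta) * 1e-3, 1e-4)
  f0 <- .cycleSS(theta, n, tt, vv, geom)
  for (i in 1:4) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h[i]; tm[i] <- max(tm[i] - h[i], 0)
    d2 <- (.cycleSS(tp, n, tt, vv, geom) - 2 * f0 +
             .cycleSS(tm, n, tt, vv, geom)) / (h[i]^2)
    se[i] <- if (is.finite(d2) && d2 > 0) sqrt(2 * sig2 / d2) else NA_real_
  }
  c(nPol = 0.5, tSpace = se[1L], vEl = se[2L], tProc = se[3L])
}

#' Pooled UP-ramp regression over a cohort of fitted cycles
#'
#' Under the convoy model the UP-ramp duration is
#' \code{(nPol - 1) * tSpace + lMs2 / vEl}, i.e. linear in \code{nPol} with
#' slope \code{tSpace} and intercept \code{lMs2 / vEl - tSpace}. Ordinary
#' least squares of the per-cycle UP-ramp durations on \code{nPol}
#' therefore yields pooled estimates \code{tSpace = slope} and
#' \code{vEl = lMs2 / (slope + intercept)}. The Pearson correlation of
#' per-cycle \code{(nPol, tSpace)} estimates is also returned (convoys with
#' more polymerases tend to be more compact).
#'
#' @param fits list of \linkS4class{FittedConvoy} objects.
#' @param geom a \linkS4class{GeneGeometry} (for \code{lMs2}).
#' @param upramps optional numeric vector of UP-ramp durations in seconds;
#'   defaults to the analytic durations implied by each fit.
#' @return A list with \code{slope} (s per polymerase), \code{intercept}
#'   (s), \code{t_space_pooled}, \code{v_el_pooled} (kb/min) and
#'   \code{npol_tspace_correlation}.
#' @export
pooledUprampRegression <- function(fits, geom = geneGeometry(),
                                   upramps = NULL) {
  if (length(fits) < 3L) stop("need at least 3 fitted cycles")
  np <- vapply(fits, nPol, numeric(1))
  ts <- vapply(fits, tSpace, numeric(1))
  if (length(unique(np)) < 2L)
    stop("all cycles have the same nPol; regression is degenerate")
  if (is.null(upramps))
    upramps <- vapply(fits, function(f)
      analyticDurations(f@params, geom)$up_ramp, numeric(1))
  fit <- lm(upramps ~ np)
  slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  list(slope = slope, intercept = intercept,
       t_space_pooled = slope,
       v_el_pooled = geom@lMs2 / (slope + intercept) * 60 / 1000,
       npol_tspace_correlation = cor(np, ts))
}

#' Convoy durations and inter-convoy gaps across traces
#'
#' Convoy duration is \code{nPol * tSpace} per fitted cycle. The gap
#' between consecutive convoys in a trace is measured from the end of the
#' UP ramp of one cycle to the beginning of the UP ramp of the next
#' (both from the fitted model: UP ramp begins when the first polymerase
#' enters the repeat and ends when the last one leaves it). The gaps are
#' summarised by the maximum-likelihood exponential mean.
#'
#' @param fitsPerTrace list (one element per trace) of lists of
#'   \linkS4class{FittedConvoy} objects in temporal order.
#' @param geom a \linkS4class{GeneGeometry}.
#' @return A list with \code{convoy_durations} (s), \code{gaps} (s) and
#'   \code{exp_fit_tau} (s; NA when no gaps exist).
#' @export
interconvoyStats <- function(fitsPerTrace, geom = geneGeometry()) {
  if (is(fitsPerTrace[[1L]], "FittedConvoy"))
    fitsPerTrace <- list(fitsPerTrace)
  durations <- numeric(0); gaps <- numeric(0)
  for (fits in fitsPerTrace) {
    if (!length(fits)) next
    durations <- c(durations,
                   vapply(fits, function(f) nPol(f) * tSpace(f), numeric(1)))
    if (length(fits) >= 2L) {
      upStart <- vapply(fits, function(f)
        f@t0 + geom@lPre / .ntPerS(vEl(f)), numeric(1))
      upEnd <- vapply(fits, function(f)
        f@t0 + (nPol(f) - 1) * tSpace(f) +
          (geom@lPre + geom@lMs2) / .ntPerS(vEl(f)), numeric(1))
      ord <- order(upStart)
      gaps <- c(gaps, upStart[ord][-1L] - upEnd[ord][-length(fits)])
    }
  }
  list(convoy_durations = durations, gaps = gaps,
       exp_fit_tau = if (length(gaps)) mean(gaps) else NA_real_)
}
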