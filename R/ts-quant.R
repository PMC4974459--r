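## Movie quantification: photobleaching correction, bandpass filtering,
## TS tracking, two-round constrained 3D Gaussian fitting, single-molecule
## calibration to absolute nascent counts, and FRAP normalisation.

## multi-exponential decay model A1*exp(-t/T1) + ... fitted by nlsLM;
## returns list(fitted(t) function, pars data.frame, nExp)
.fitMultiExp <- function(t, y, nExp = 3L) {
  tShift <- t[1L]
  t <- t - tShift
  span <- max(t[length(t)], 1)
  fitOne <- function(k, taus0) {
    a0 <- rep(y[1L] / k, k)
    st <- as.list(setNames(c(rbind(a0, taus0)),
                           c(rbind(paste0("a", 1:k), paste0("t", 1:k)))))
    fo <- switch(k,
      y ~ a1 * exp(-t / t1),
      y ~ a1 * exp(-t / t1) + a2 * exp(-t / t2),
      y ~ a1 * exp(-t / t1) + a2 * exp(-t / t2) + a3 * exp(-t / t3))
    fit <- minpack.lm::nlsLM(fo, data = data.frame(t = t, y = y), start = st,
                             lower = rep(1e-9, 2 * k),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- coef(fit)
    amps <- unname(cf[seq(1, 2 * k, by = 2)])
    taus <- unname(cf[seq(2, 2 * k, by = 2)])
    list(predict = function(tt) {
           tl <- tt - tShift
           as.numeric(colSums(amps * exp(-outer(1 / taus, tl))))
         },
         amplitudes = amps, taus = taus, nExp = k,
         rss = sum(residuals(fit)^2))
  }
  startSets <- list(
    `3` = list(span * c(0.1, 1, 8), span * c(0.03, 0.3, 3),
               span * c(0.3, 3, 30)),
    `2` = list(span * c(0.2, 2), span * c(0.05, 1)),
    `1` = list(span))
  for (k in rev(seq_len(nExp))) {
    best <- NULL
    for (taus0 in startSets[[as.character(k)]]) {
      res <- tryCatch(fitOne(k, taus0), error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    }
    if (!is.null(best)) {
      if (k < nExp)
        warning(sprintf("multi-exponential bleach fit fell back to %d component(s)", k))
      return(best)
    }
  }
  ## last resort: constant
  list(predict = function(tt) rep(mean(y), length(tt)),
       amplitudes = mean(y), taus = Inf, nExp = 0L)
}

#' Correct a movie stack or trace for photobleaching
#'
#' The mean nuclear intensity per frame is fitted with a sum of three
#' exponentials (falling back to fewer components with a warning when the
#' fit degenerates) and each frame is rescaled so that its fitted nuclear
#' intensity equals that of the first frame.
#'
#' @param x a 4D movie array (t, z, y, x) or a numeric vector of per-frame
#'   nuclear mean intensities.
#' @param frameTimes frame acquisition times in seconds.
#' @param nuclearMask optional logical (y, x) mask restricting the nuclear
#'   mean; defaults to the full field.
#' @param nExp maximum number of exponential components (default 3).
#' @return A list with \code{corrected} (same shape as \code{x}),
#'   \code{scale} (per-frame multiplicative correction),
#'   \code{nuclearMean} (raw per-frame means) and \code{fit}
#'   (amplitudes/taus of the bleach curve).
#' @export
bleachCorrect <- function(x, frameTimes = NULL, nuclearMask = NULL,
                          nExp = 3L) {
  isStack <- is.array(x) && length(dim(x)) == 4L
  if (isStack) {
    nT <- dim(x)[1L]
    nuc <- vapply(seq_len(nT), function(f) {
      vol <- x[f, , , , drop = TRUE]
      if (is.null(nuclearMask)) mean(vol)
      else mean(apply(vol, 1L, function(sl) mean(sl[nuclearMask])))
    }, numeric(1))
  } else {
    nuc <- as.numeric(x)
    nT <- length(nuc)
  }
  if (nT < 10L) stop("bleach correction needs at least 10 frames")
  if (is.null(frameTimes)) frameTimes <- seq_len(nT) - 1
  fit <- .fitMultiExp(frameTimes, nuc, nExp = nExp)
  pred <- fit$predict(frameTimes)
  scale <- pred[1L] / pred
  corrected <- if (isStack) {
    out <- x
    for (f in seq_len(nT)) out[f, , , ] <- out[f, , , ] * scale[f]
    out
  } else nuc * scale
  list(corrected = corrected, scale = scale, nuclearMean = nuc,
       fit = list(amplitudes = fit$amplitudes, taus = fit$taus,
                  nExp = fit$nExp))
}

#' Bandpass (difference-of-Gaussians) filter of a 3D image
#'
#' The image is convolved with the larger kernel to estimate a smooth
#' background, which is subtracted; the residual is then smoothed with the
#' smaller kernel to enhance the SNR of diffraction-limited particles:
#' \code{G_small * (image - G_large * image)}. The filter is linear and
#' shift-invariant; kernels act laterally (per z-plane).
#'
#' @param image3d 3D array (z, y, x).
#' @param sigmaLarge background kernel sd in px (> sigmaSmall).
#' @param sigmaSmall smoothing kernel sd in px.
#' @return Filtered 3D array of the same dimensions.
#' @export
bandpassFilter <- function(image3d, sigmaLarge = 5, sigmaSmall = 1) {
  if (!(sigmaLarge > sigmaSmall && sigmaSmall > 0))
    stop("need sigmaLarge > sigmaSmall > 0")
  stopifnot(length(dim(image3d)) == 3L)
  bg <- gaussBlur3d(image3d, sigmaLarge, 0)
  gaussBlur3d(image3d - bg, sigmaSmall, 0)
}

#' Track the transcription site across a filtered movie
#'
#' Per frame, the TS is pre-detected as the brightest voxel above
#' \code{threshold} within the user-specified search region; frames without
#' a voxel above the threshold reuse the last known position (frames before
#' the first detection use the first detected position). Ties at the
#' maximal value break toward the lowest (z, y, x) lexicographic index.
#'
#' @param filtered 4D filtered movie array (t, z, y, x).
#' @param threshold detection threshold in filtered-image units.
#' @param regionMask optional logical (y, x) mask of the search region.
#' @return data.frame with columns \code{frame}, \code{z}, \code{y},
#'   \code{x} (integer voxel coordinates) and \code{detected}.
#' @export
trackTS <- function(filtered, threshold, regionMask = NULL) {
  stopifnot(length(dim(filtered)) == 4L)
  d <- dim(filtered)
  if (is.null(regionMask)) regionMask <- matrix(TRUE, d[3L], d[4L])
  if (!any(regionMask)) stop("search region is empty")
  res <- data.frame(frame = seq_len(d[1L]), z = NA_integer_,
                    y = NA_integer_, x = NA_integer_, detected = FALSE)
  for (f in seq_len(d[1L])) {
    vol <- filtered[f, , , , drop = TRUE]
    for (zz in seq_len(d[2L])) vol[zz, , ][!regionMask] <- -Inf
    mx <- max(vol)
    if (mx > threshold) {
      idx <- which(vol == mx)
      pos <- arrayInd(idx, dim(vol))           # columns: z, y, x
      pos <- pos[order(pos[, 1L], pos[, 2L], pos[, 3L]), , drop = FALSE]
      res[f, c("z", "y", "x")] <- pos[1L, ]
      res$detected[f] <- TRUE
    }
  }
  if (!any(res$detected)) stop("TS never detected in the movie")
  firstDet <- which(res$detected)[1L]
  for (f in seq_len(d[1L])) {
    if (!res$detected[f]) {
      src <- if (f < firstDet) firstDet else max(which(res$detected[seq_len(f)]))
      res[f, c("z", "y", "x")] <- res[src, c("z", "y", "x")]
    }
  }
  res
}

## Fit a 3D Gaussian + constant background to a subvolume of `vol` around
## (z0, y0, x0). `bounds` may fix/constrain sigmaXy, sigmaZ, background.
.fitGaussian3d <- function(vol, z0, y0, x0, sigmaXy0 = 1.3, sigmaZ0 = 1.0,
                           bounds = NULL) {
  d <- dim(vol)
  rxy <- ceiling(3 * sigmaXy0) + 1L
  rz <- ceiling(3 * sigmaZ0) + 1L
  zi <- max(1L, round(z0) - rz):min(d[1L], round(z0) + rz)
  yi <- max(1L, round(y0) - rxy):min(d[2L], round(y0) + rxy)
  xi <- max(1L, round(x0) - rxy):min(d[3L], round(x0) + rxy)
  cube <- vol[zi, yi, xi, drop = FALSE]
  grid <- expand.grid(z = zi, y = yi, x = xi)
  val <- as.numeric(cube)
  bg0 <- median(val)
  a0 <- max(val) - bg0
  model <- function(p) {
    p["bg"] + p["amp"] * exp(
      -((grid$z - p["z"])^2) / (2 * p["sz"]^2)
      - ((grid$y - p["y"])^2 + (grid$x - p["x"])^2) / (2 * p["sxy"]^2))
  }
  obj <- function(p) sum((val - model(p))^2)
  p0 <- c(bg = bg0, amp = max(a0, 1e-6), z = z0, y = y0, x = x0,
          sxy = sigmaXy0, sz = sigmaZ0)
  lower <- c(bg = -Inf, amp = 0, z = min(zi) - 1, y = min(yi) - 1,
             x = min(xi) - 1, sxy = 0.3, sz = 0.3)
  upper <- c(bg = Inf, amp = Inf, z = max(zi) + 1, y = max(yi) + 1,
             x = max(xi) + 1, sxy = 3 * sigmaXy0 + 2, sz = 3 * sigmaZ0 + 2)
  if (!is.null(bounds)) {
    if (!is.null(bounds$sigmaXy)) {
      lower["sxy"] <- bounds$sigmaXy[1L]; upper["sxy"] <- bounds$sigmaXy[2L]
      p0["sxy"] <- mean(bounds$sigmaXy)
    }
    if (!is.null(bounds$sigmaZ)) {
      lower["sz"] <- bounds$sigmaZ[1L]; upper["sz"] <- bounds$sigmaZ[2L]
      p0["sz"] <- mean(bounds$sigmaZ)
    }
    if (!is.null(bounds$background)) {
      lower["bg"] <- bounds$background; upper["bg"] <- bounds$background
      p0["bg"] <- bounds$background
    }
  }
  free <- upper > lower
  objFree <- function(pf) {
    p <- p0; p[free] <- pf; obj(p)
  }
  o <- optim(p0[free], objFree, method = "L-BFGS-B",
             lower = lower[free], upper = upper[free],
             control = list(maxit = 300, factr = 1e4))
  p <- p0; p[free] <- o$par
  data.frame(z = unname(p["z"]), y = unname(p["y"]), x = unname(p["x"]),
             sigma_xy = unname(p["sxy"]), sigma_z = unname(p["sz"]),
             amplitude = unname(p["amp"]), background = unname(p["bg"]),
             integrated_intensity = unname(
               p["amp"] * (2 * pi)^1.5 * p["sxy"]^2 * p["sz"]),
             rss = o$value)
}

#' Quantify the TS intensity trace by two-round 3D Gaussian fitting
#'
#' Round 1 fits an unconstrained 3D Gaussian (amplitude, background,
#' position, lateral and axial sd) at the tracked position in every frame.
#' The medians and sds of \code{sigma_xy}, \code{sigma_z} and
#' \code{background} over the pre-detected frames then define round-2
#' constraints: sigmas are bounded to median +/- sd and the background is
#' fixed at its median, which stabilises the estimates in frames with a dim
#' or absent TS. The TS intensity per frame is the integrated intensity
#' above background, \code{amplitude * (2*pi)^(3/2) * sigma_xy^2 * sigma_z}.
#'
#' @param stack raw (bleach-corrected) 4D movie array (t, z, y, x).
#' @param positions tracking table from [trackTS()].
#' @param sigmaXy0,sigmaZ0 initial PSF sd guesses (px, planes).
#' @return A list with \code{fits} (per-frame round-2 Gaussian table),
#'   \code{round1} (round-1 table), \code{trace} (per-frame integrated
#'   intensity, a.u.) and \code{constraints}.
#' @export
quantifyTSTrace <- function(stack, positions, sigmaXy0 = 1.3, sigmaZ0 = 1.0) {
  stopifnot(length(dim(stack)) == 4L)
  nT <- dim(stack)[1L]
  stopifnot(nrow(positions) == nT)
  r1 <- do.call(rbind, lapply(seq_len(nT), function(f)
    .fitGaussian3d(stack[f, , , , drop = TRUE], positions$z[f],
                   positions$y[f], positions$x[f], sigmaXy0, sigmaZ0)))
  det <- positions$detected
  if (sum(det) < 3L)
    stop("fewer than 3 pre-detected frames; round-2 constraints undefined")
  cons <- list(
    sigmaXy = c(max(median(r1$sigma_xy[det]) - sd(r1$sigma_xy[det]), 0.3),
                median(r1$sigma_xy[det]) + sd(r1$sigma_xy[det])),
    sigmaZ = c(max(median(r1$sigma_z[det]) - sd(r1$sigma_z[det]), 0.3),
               median(r1$sigma_z[det]) + sd(r1$sigma_z[det])),
    background = median(r1$background[det]))
  r2 <- do.call(rbind, lapply(seq_len(nT), function(f)
    .fitGaussian3d(stack[f, , , , drop = TRUE], positions$z[f],
                   positions$y[f], positions$x[f], sigmaXy0, sigmaZ0,
                   bounds = cons)))
  list(fits = r2, round1 = r1, trace = r2$integrated_intensity,
       constraints = cons)
}

#' Detect diffraction-limited spots in a filtered 3D stack
#'
#' Local maxima (within a (2r+1)^3 neighbourhood) above a threshold; the
#' default threshold is the background median plus 5 robust sds of the
#' filtered image.
#'
#' @param filtered3d bandpass-filtered 3D array (z, y, x).
#' @param threshold detection threshold; NULL for the robust default.
#' @param radius neighbourhood radius in voxels.
#' @param nSdThreshold robust-sd multiplier for the default threshold.
#' @return data.frame with \code{z}, \code{y}, \code{x}, \code{value}.
#' @export
detectSpots <- function(filtered3d, threshold = NULL, radius = 2L,
                        nSdThreshold = 5) {
  stopifnot(length(dim(filtered3d)) == 3L)
  if (is.null(threshold))
    threshold <- median(filtered3d) + nSdThreshold * mad(filtered3d)
  d <- dim(filtered3d)
  cand <- which(filtered3d > threshold)
  if (!length(cand)) return(data.frame(z = integer(), y = integer(),
                                       x = integer(), value = numeric()))
  pos <- arrayInd(cand, d)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    zc <- pos[i, 1L]; yc <- pos[i, 2L]; xc <- pos[i, 3L]
    zi <- max(1L, zc - radius):min(d[1L], zc + radius)
    yi <- max(1L, yc - radius):min(d[2L], yc + radius)
    xi <- max(1L, xc - radius):min(d[3L], xc + radius)
    keep[i] <- filtered3d[zc, yc, xc] >= max(filtered3d[zi, yi, xi])
  }
  pos <- pos[keep, , drop = FALSE]
  data.frame(z = pos[, 1L], y = pos[, 2L], x = pos[, 3L],
             value = filtered3d[cbind(pos[, 1L], pos[, 2L], pos[, 3L])])
}

#' Single-molecule intensity from a calibration stack
#'
#' Detects nucleoplasmic single molecules in the (bandpass-filtered)
#' calibration stack, fits each with a 3D Gaussian on the raw stack (the
#' per-spot background estimate performs the per-cell background
#' subtraction) and averages their integrated intensities. When a cohort
#' mean is supplied, the returned reference intensity is the cohort value
#' rescaled by the ratio of this cell's molecule mean to the cohort mean —
#' equivalent to matching the averaged molecule image to the molecules
#' detected in the analysed cell — which accounts for the correlation of
#' molecule brightness with the cell's MCP-GFP level.
#'
#' @param calibStack raw 3D calibration stack (z, y, x).
#' @param sigmaXy0,sigmaZ0 PSF sd guesses.
#' @param threshold spot-detection threshold on the filtered stack;
#'   NULL for the robust default of [detectSpots()].
#' @param sigmaLarge,sigmaSmall bandpass kernel sds.
#' @param cohortMean optional cohort-averaged molecule intensity (a.u.).
#' @param excludeRegion optional function(z, y, x) returning TRUE for spots
#'   to exclude (e.g. near the TS).
#' @return A list with \code{intensity} (the reference single-molecule
#'   intensity, a.u.), \code{cellMean}, \code{n} and \code{spots}.
#' @export
singleMoleculeIntensity <- function(calibStack, sigmaXy0 = 1.3, sigmaZ0 = 1.0,
                                    threshold = NULL, sigmaLarge = 5,
                                    sigmaSmall = 1, cohortMean = NULL,
                                    excludeRegion = NULL) {
  filt <- bandpassFilter(calibStack, sigmaLarge, sigmaSmall)
  spots <- detectSpots(filt, threshold)
  d <- dim(calibStack)
  if (nrow(spots)) {
    border <- ceiling(3 * sigmaXy0)
    keep <- spots$y > border & spots$y <= d[2L] - border &
      spots$x > border & spots$x <= d[3L] - border &
      spots$z > 1L & spots$z < d[1L]
    spots <- spots[keep, , drop = FALSE]
  }
  if (!is.null(excludeRegion) && nrow(spots))
    spots <- spots[!mapply(excludeRegion, spots$z, spots$y, spots$x), ,
                   drop = FALSE]
  if (!nrow(spots)) stop("no single molecules detected in calibration stack")
  psfBounds <- list(sigmaXy = c(0.6 * sigmaXy0, 1.6 * sigmaXy0),
                    sigmaZ = c(0.6 * sigmaZ0, 1.6 * sigmaZ0))
  fits <- do.call(rbind, lapply(seq_len(nrow(spots)), function(i)
    .fitGaussian3d(calibStack, spots$z[i], spots$y[i], spots$x[i],
                   sigmaXy0, sigmaZ0, bounds = psfBounds)))
  cellMean <- mean(fits$integrated_intensity)
  ref <- if (is.null(cohortMean)) cellMean
         else cohortMean * (cellMean / cohortMean)
  list(intensity = ref, cellMean = cellMean, n = nrow(fits), spots = fits)
}

#' Convert an a.u. TS intensity trace to absolute nascent counts
#'
#' Applies the single-molecule calibration: the measured TS intensities
#' \code{iMs2} are normalised so that the mean of the last four frames
#' equals the nascent count estimated from the calibration stack,
#' \code{N(t) = iMs2(t) * nNascFinal / iFinal}. The approach requires an
#' active TS at movie end (\code{iFinal > 0}).
#'
#' @param rec a \linkS4class{CalibrationRecord}.
#' @param frameTimes optional frame times (s) to build the returned trace.
#' @return An \linkS4class{IntensityTrace} in RNA equivalents (or a bare
#'   numeric vector when \code{frameTimes} is NULL).
#' @export
calibrateNascentCounts <- function(rec, frameTimes = NULL) {
  stopifnot(is(rec, "CalibrationRecord"))
  if (!is.finite(rec@iFinal) || rec@iFinal <= 0)
    stop("calibration impossible: TS inactive at movie end (iFinal <= 0)")
  counts <- rec@iMs2 * rec@nNascFinal / rec@iFinal
  if (is.null(frameTimes)) return(counts)
  intensityTrace(frameTimes, counts, units = "rna_equivalents")
}

#' Build a calibration record from a quantified movie and calibration stack
#'
#' Computes \code{iFinal} as the mean of the last four frames of the a.u.
#' TS trace and \code{nNascFinal} as the TS integrated intensity in the
#' calibration stack divided by the single-molecule intensity.
#'
#' @param tsTraceAu per-frame TS intensity in a.u. (from
#'   [quantifyTSTrace()]).
#' @param tsCalibIntensity TS integrated intensity in the calibration
#'   stack, a.u.
#' @param smIntensity single-molecule reference intensity, a.u.
#' @return A \linkS4class{CalibrationRecord}.
#' @export
makeCalibrationRecord <- function(tsTraceAu, tsCalibIntensity, smIntensity) {
  iFinal <- mean(tail(tsTraceAu, 4L))
  calibrationRecord(iMs2 = tsTraceAu, iFinal = iFinal,
                    nNascFinal = tsCalibIntensity / smIntensity,
                    singleMoleculeIntensity = smIntensity)
}

#' Per-molecule copy-number estimates from a validation movie
#'
#' Runs the full quantification-and-calibration scheme on a movie that
#' contains only single molecules: bleach correction against the nuclear
#' mean, bandpass filtering and spot detection per analysed frame, 3D
#' Gaussian fits with the sigmas bounded to a diffraction-limited range
#' around the expected PSF, and division of each integrated intensity by
#' the single-molecule reference measured on the calibration stack. For a
#' well-calibrated pipeline the estimates scatter around 1 RNA equivalent.
#'
#' @param movieStack 4D movie array (t, z, y, x).
#' @param calibStack 3D calibration stack (z, y, x).
#' @param frameTimes frame times of the movie in seconds.
#' @param frames frame indices to quantify (default: every third frame).
#' @param sigmaXy0,sigmaZ0 expected PSF sds (px, planes).
#' @param border detections closer than this to the lateral edges, or in
#'   the first/last z plane, are discarded (their fit window is truncated).
#' @return Numeric vector of per-detection copy-number estimates
#'   (RNA equivalents), with the single-molecule reference intensity as
#'   attribute \code{"smIntensity"}.
#' @export
singleMoleculeCopyEstimates <- function(movieStack, calibStack, frameTimes,
                                        frames = NULL, sigmaXy0 = 1.3,
                                        sigmaZ0 = 1.0, border = 6) {
  stopifnot(length(dim(movieStack)) == 4L, length(dim(calibStack)) == 3L)
  d <- dim(movieStack)
  if (is.null(frames)) frames <- seq(1L, d[1L], by = 3L)
  sm <- singleMoleculeIntensity(calibStack, sigmaXy0, sigmaZ0)
  bc <- bleachCorrect(movieStack, frameTimes)
  psfBounds <- list(sigmaXy = c(0.6 * sigmaXy0, 1.6 * sigmaXy0),
                    sigmaZ = c(0.6 * sigmaZ0, 1.6 * sigmaZ0))
  out <- numeric(0)
  for (f in frames) {
    vol <- bc$corrected[f, , , , drop = TRUE]
    spots <- detectSpots(bandpassFilter(vol, 5, 1))
    if (!nrow(spots)) next
    keep <- spots$y > border & spots$y <= d[3L] - border &
      spots$x > border & spots$x <= d[4L] - border &
      spots$z > 1L & spots$z < d[2L]
    spots <- spots[keep, , drop = FALSE]
    if (!nrow(spots)) next
    fits <- do.call(rbind, lapply(seq_len(nrow(spots)), function(i)
      .fitGaussian3d(vol, spots$z[i], spots$y[i], spots$x[i],
                     sigmaXy0, sigmaZ0, bounds = psfBounds)))
    out <- c(out, fits$integrated_intensity / sm$intensity)
  }
  attr(out, "smIntensity") <- sm$intensity
  out
}

#' Normalise a FRAP recovery curve
#'
#' Each spot intensity is corrected for acquisition bleaching by dividing
#' by the total cell fluorescence at the same time point, then normalised
#' to the mean pre-bleach ratio, so the pre-bleach level is 1.
#'
#' @param spot per-frame bleached-spot intensities.
#' @param cell per-frame total cell fluorescence (all > 0).
#' @param prebleachFrames indices of the pre-bleach frames.
#' @return Numeric normalised recovery curve.
#' @export
frapNormalize <- function(spot, cell, prebleachFrames) {
  stopifnot(length(spot) == length(cell))
  if (any(cell == 0)) stop("zero total cell fluorescence frame")
  ratio <- spot / cell
  pre <- mean(ratio[prebleachFrames])
  if (pre <= 0) stop("pre-bleach mean must be > 0")
  ratio / pre
}
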