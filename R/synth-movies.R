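## Synthetic 4D movie stacks: diffraction-limited spots rendered as 3D
## Gaussians on a fluorescent background, global tri-exponential
## photobleaching and Poisson-Gaussian camera noise, with ground-truth
## sidecars for oracle comparisons.

## Add one 3D Gaussian spot (integrated intensity `intensity`) to a volume
## with dims (z, y, x). Positions are continuous, 1-based voxel coordinates.
.renderSpot <- function(vol, z0, y0, x0, intensity, sigmaXy, sigmaZ) {
  d <- dim(vol)
  amp <- intensity / ((2 * pi)^1.5 * sigmaXy^2 * sigmaZ)
  rz <- ceiling(4 * sigmaZ); rxy <- ceiling(4 * sigmaXy)
  zi <- max(1L, floor(z0 - rz)):min(d[1L], ceiling(z0 + rz))
  yi <- max(1L, floor(y0 - rxy)):min(d[2L], ceiling(y0 + rxy))
  xi <- max(1L, floor(x0 - rxy)):min(d[3L], ceiling(x0 + rxy))
  gz <- exp(-(zi - z0)^2 / (2 * sigmaZ^2))
  gy <- exp(-(yi - y0)^2 / (2 * sigmaXy^2))
  gx <- exp(-(xi - x0)^2 / (2 * sigmaXy^2))
  vol[zi, yi, xi] <- vol[zi, yi, xi] + amp * outer(gz, outer(gy, gx))
  vol
}

## Tri-exponential bleaching factor at times t (seconds)
.bleachFactor <- function(spec, t)
  colSums(spec@bleachAmplitudes * exp(-outer(spec@bleachRates, t)))

#' Simulate a 4D movie stack with planted spots and photobleaching
#'
#' Renders a movie of \code{nFrames} 3D stacks (dimension order t, z, y, x)
#' containing an optional fixed transcription site whose intensity follows
#' \code{tsTrace}, plus \code{nSingleMolecules} single molecules of unit
#' brightness \code{singleMoleculeIntensity} placed at random positions in
#' every frame (static within a frame). All fluorescence (spots and the
#' fluorescent background) is multiplied by a global tri-exponential
#' bleaching curve, and Poisson-Gaussian camera noise is added (Gaussian
#' with variance equal to the signal, plus additive read noise). Voxels
#' above the saturation level are clipped and flagged.
#'
#' @param spec a \linkS4class{MovieSpec}.
#' @param tsTrace optional \linkS4class{IntensityTrace} (RNA equivalents)
#'   driving the TS intensity; must have at least \code{nFrames} frames.
#' @param tsPosition numeric (z, y, x) voxel position of the TS; defaults
#'   to the stack centre.
#' @param nSingleMolecules single molecules planted per frame.
#' @param singleMoleculeIntensity integrated intensity of one RNA molecule
#'   (a.u.).
#' @param margin border in pixels kept free of planted molecules.
#' @param seed integer seed, or NULL.
#' @return A list with \code{stack} (4D array t, z, y, x),
#'   \code{groundTruth} (data.frame: frame, type, z, y, x, intensity —
#'   pre-bleach intensities), \code{bleach} (per-frame bleach factor),
#'   \code{clipped} (logical) and \code{spec}.
#' @export
simulateMovieStack <- function(spec, tsTrace = NULL, tsPosition = NULL,
                               nSingleMolecules = 0,
                               singleMoleculeIntensity = 800,
                               margin = 6, seed = NULL) {
  stopifnot(is(spec, "MovieSpec"))
  validObject(spec)
  nT <- as.integer(spec@nFrames); nZ <- as.integer(spec@nZ)
  nXY <- as.integer(spec@xySizePx)
  if (!is.null(tsTrace)) {
    stopifnot(is(tsTrace, "IntensityTrace"))
    if (length(traceValues(tsTrace)) < nT)
      stop("tsTrace must cover at least nFrames frames")
  }
  if (is.null(tsPosition)) tsPosition <- c((nZ + 1) / 2, nXY / 2, nXY / 2)
  frameT <- (seq_len(nT) - 1L) * spec@frameIntervalS
  bleach <- .bleachFactor(spec, frameT)
  withSeed(seed, {
    stack <- array(0, dim = c(nT, nZ, nXY, nXY))
    gt <- vector("list", nT)
    for (f in seq_len(nT)) {
      vol <- array(spec@backgroundLevel, dim = c(nZ, nXY, nXY))
      rows <- list()
      if (!is.null(tsTrace)) {
        tsI <- traceValues(tsTrace)[f] * singleMoleculeIntensity
        if (tsI > 0)
          vol <- .renderSpot(vol, tsPosition[1L], tsPosition[2L],
                             tsPosition[3L], tsI, spec@psfSigmaXyPx,
                             spec@psfSigmaZPlanes)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, type = "TS", z = tsPosition[1L], y = tsPosition[2L],
          x = tsPosition[3L], intensity = tsI)
      }
      if (nSingleMolecules > 0) {
        zM <- runif(nSingleMolecules, 1.5, nZ - 0.5)
        yM <- runif(nSingleMolecules, margin, nXY - margin)
        xM <- runif(nSingleMolecules, margin, nXY - margin)
        for (m in seq_len(nSingleMolecules))
          vol <- .renderSpot(vol, zM[m], yM[m], xM[m],
                             singleMoleculeIntensity, spec@psfSigmaXyPx,
                             spec@psfSigmaZPlanes)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, type = "molecule", z = zM, y = yM, x = xM,
          intensity = singleMoleculeIntensity)
      }
      vol <- vol * bleach[f]
      if (spec@cameraNoiseSd > 0 || spec@backgroundLevel > 0)
        vol <- vol + rnorm(length(vol),
                           sd = sqrt(pmax(vol, 0) + spec@cameraNoiseSd^2))
      stack[f, , , ] <- vol
      gt[[f]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    clipped <- any(stack > spec@saturationLevel)
    stack[stack > spec@saturationLevel] <- spec@saturationLevel
    list(stack = stack,
         groundTruth = do.call(rbind, gt),
         bleach = bleach, clipped = clipped, spec = spec)
  })
}

#' Simulate a single-molecule calibration stack
#'
#' Emulates the higher-power 3D stack acquired at movie end to measure
#' single-molecule intensities: finer z-sampling (21 planes by default),
#' no bleaching within the single stack, optional illumination scaling.
#'
#' @param spec a \linkS4class{MovieSpec} providing the lateral geometry,
#'   PSF, background and noise settings.
#' @param nMolecules molecules planted in the stack.
#' @param singleMoleculeIntensity integrated intensity per molecule before
#'   illumination scaling (a.u.).
#' @param tsIntensity optional TS intensity (RNA equivalents) rendered at
#'   the stack centre.
#' @param nZ number of planes (default 21, spaced 300 nm).
#' @param powerFactor illumination scaling applied to all fluorescence.
#' @param margin border kept free of molecules, px.
#' @param seed integer seed, or NULL.
#' @return A list with \code{stack} (3D array z, y, x), \code{groundTruth}
#'   and the scaled \code{singleMoleculeIntensity}.
#' @export
simulateCalibrationStack <- function(spec, nMolecules = 30,
                                     singleMoleculeIntensity = 800,
                                     tsIntensity = 0, nZ = 21,
                                     powerFactor = 1, margin = 6,
                                     seed = NULL) {
  stopifnot(is(spec, "MovieSpec"))
  nXY <- as.integer(spec@xySizePx)
  withSeed(seed, {
    vol <- array(spec@backgroundLevel, dim = c(nZ, nXY, nXY))
    zM <- runif(nMolecules, 1.5, nZ - 0.5)
    yM <- runif(nMolecules, margin, nXY - margin)
    xM <- runif(nMolecules, margin, nXY - margin)
    for (m in seq_len(nMolecules))
      vol <- .renderSpot(vol, zM[m], yM[m], xM[m], singleMoleculeIntensity,
                         spec@psfSigmaXyPx, spec@psfSigmaZPlanes)
    smI <- singleMoleculeIntensity * powerFactor
    gt <- data.frame(frame = 1L, type = "molecule", z = zM, y = yM, x = xM,
                     intensity = smI)
    if (tsIntensity > 0) {
      ctr <- c((nZ + 1) / 2, nXY / 2, nXY / 2)
      vol <- .renderSpot(vol, ctr[1L], ctr[2L], ctr[3L],
                         tsIntensity * singleMoleculeIntensity,
                         spec@psfSigmaXyPx, spec@psfSigmaZPlanes)
      gt <- rbind(gt, data.frame(frame = 1L, type = "TS", z = ctr[1L],
                                 y = ctr[2L], x = ctr[3L],
                                 intensity = tsIntensity * smI))
    }
    vol <- vol * powerFactor  # illumination scales all fluorescence
    if (spec@cameraNoiseSd > 0 || spec@backgroundLevel > 0)
      vol <- vol + rnorm(length(vol),
                         sd = sqrt(pmax(vol, 0) + spec@cameraNoiseSd^2))
    list(stack = vol, groundTruth = gt, singleMoleculeIntensity = smI)
  })
}
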