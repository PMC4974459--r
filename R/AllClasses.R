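## Central S4 data objects of the package. Validity methods enforce the
## model invariants; constructors are the exported camelCase functions.

#' ConvoyParams: kinetic parameters of a polymerase convoy
#'
#' Holds the four key parameters of the convoy model of transcription-site
#' (TS) intensity: the number of polymerases in the convoy, their temporal
#' spacing, their elongation rate and the 3'-end processing/release time.
#'
#' @slot nPol integer-valued number of polymerases (>= 1).
#' @slot tSpace seconds between successive initiations (>= 0).
#' @slot vEl elongation rate in kb/min (> 0).
#' @slot tProc seconds between arrival at the cleavage site and release (>= 0).
#' @export
setClass("ConvoyParams",
  representation(nPol = "numeric", tSpace = "numeric",
                 vEl = "numeric", tProc = "numeric"))

setValidity("ConvoyParams", function(object) {
  msg <- character()
  if (length(object@nPol) != 1L || !is.finite(object@nPol) ||
      object@nPol < 1 || object@nPol != round(object@nPol))
    msg <- c(msg, "nPol must be a single integer >= 1")
  if (length(object@tSpace) != 1L || !is.finite(object@tSpace) || object@tSpace < 0)
    msg <- c(msg, "tSpace must be a single number >= 0")
  if (length(object@vEl) != 1L || !is.finite(object@vEl) || object@vEl <= 0)
    msg <- c(msg, "vEl must be a single number > 0")
  if (length(object@tProc) != 1L || !is.finite(object@tProc) || object@tProc < 0)
    msg <- c(msg, "tProc must be a single number >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a ConvoyParams object
#'
#' @param nPol number of polymerases in the convoy (integer >= 1).
#' @param tSpace initiation spacing in seconds.
#' @param vEl elongation rate in kb/min.
#' @param tProc 3'-end processing/release time in seconds.
#' @return A \linkS4class{ConvoyParams} object.
#' @examples
#' convoyParams(nPol = 19, tSpace = 4.1, vEl = 4.1, tProc = 103)
#' @export
convoyParams <- function(nPol, tSpace, vEl, tProc)
  new("ConvoyParams", nPol = as.numeric(nPol), tSpace = as.numeric(tSpace),
      vEl = as.numeric(vEl), tProc = as.numeric(tProc))

#' GeneGeometry: reporter layout in nucleotides
#'
#' Describes the MS2 reporter gene as three segments: the region upstream of
#' the MS2 repeat (invisible to the coat protein), the MS2 repeat itself, and
#' the region from the repeat end to the cleavage/polyA site.
#'
#' @slot lPre nucleotides from the initiation site to the MS2 repeat start.
#' @slot lMs2 nucleotides of the MS2 repeat (> 0).
#' @slot lPost nucleotides from the repeat end to the cleavage site.
#' @export
setClass("GeneGeometry",
  representation(lPre = "numeric", lMs2 = "numeric", lPost = "numeric"))

setValidity("GeneGeometry", function(object) {
  msg <- character()
  for (s in c("lPre", "lMs2", "lPost")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, paste(s, "must be a single number >= 0"))
  }
  if (length(object@lMs2) == 1L && is.finite(object@lMs2) && object@lMs2 <= 0)
    msg <- c(msg, "lMs2 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a GeneGeometry object
#'
#' The defaults describe a 128-stem-loop MS2 reporter: ~2 kb of 5' sequence
#' before the repeat, a 2.8 kb repeat (128 loops of ~22 nt with 3 nt linkers)
#' and 4.5 kb from the repeat end to the cleavage site.
#'
#' @param lPre,lMs2,lPost segment lengths in nucleotides.
#' @return A \linkS4class{GeneGeometry} object.
#' @export
geneGeometry <- function(lPre = 2000, lMs2 = 2800, lPost = 4500)
  new("GeneGeometry", lPre = as.numeric(lPre), lMs2 = as.numeric(lMs2),
      lPost = as.numeric(lPost))

#' IntensityTrace: regularly sampled TS intensity over time
#'
#' @slot times frame times in seconds, strictly increasing, regular spacing.
#' @slot values intensity per frame (arbitrary units or RNA equivalents).
#' @slot units one of \code{"arbitrary"} or \code{"rna_equivalents"}.
#' @slot flags character vector of quality flags (e.g.
#'   \code{"duration_truncated"} when a simulated trace does not cover the
#'   full transcription cycle).
#' @export
setClass("IntensityTrace",
  representation(times = "numeric", values = "numeric",
                 units = "character", flags = "character"))

setValidity("IntensityTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n != length(object@values))
    msg <- c(msg, "times and values must have the same length")
  if (n < 2L)
    msg <- c(msg, "trace needs at least two frames")
  else {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    else if (diff(range(dt)) > 1e-6 * mean(dt))
      msg <- c(msg, "frame spacing must be regular")
  }
  if (length(object@units) != 1L ||
      !object@units %in% c("arbitrary", "rna_equivalents"))
    msg <- c(msg, "units must be 'arbitrary' or 'rna_equivalents'")
  if (length(msg)) msg else TRUE
})

#' Create an IntensityTrace object
#'
#' @param times frame times in seconds (regular spacing).
#' @param values per-frame intensity.
#' @param units \code{"arbitrary"} or \code{"rna_equivalents"}.
#' @param flags optional character vector of quality flags.
#' @return An \linkS4class{IntensityTrace} object.
#' @export
intensityTrace <- function(times, values, units = c("rna_equivalents", "arbitrary"),
                           flags = character()) {
  units <- match.arg(units)
  new("IntensityTrace", times = as.numeric(times), values = as.numeric(values),
      units = units, flags = as.character(flags))
}

#' NoiseModel: per-frame measurement noise on intensity traces
#'
#' @slot additiveSd sd of zero-mean Gaussian noise, in intensity units.
#' @slot multiplicativeSd fractional (multiplicative) intensity noise.
#' @export
setClass("NoiseModel",
  representation(additiveSd = "numeric", multiplicativeSd = "numeric"))

setValidity("NoiseModel", function(object) {
  if (object@additiveSd < 0 || object@multiplicativeSd < 0)
    "noise sds must be >= 0" else TRUE
})

#' Create a NoiseModel object
#' @param additiveSd sd of additive Gaussian noise (intensity units).
#' @param multiplicativeSd sd of fractional multiplicative noise.
#' @return A \linkS4class{NoiseModel} object.
#' @export
noiseModel <- function(additiveSd = 0, multiplicativeSd = 0)
  new("NoiseModel", additiveSd = as.numeric(additiveSd),
      multiplicativeSd = as.numeric(multiplicativeSd))

#' MovieSpec: geometry, optics and noise of a synthetic 4D movie
#'
#' Defaults mirror a typical widefield live-cell acquisition: 11 z-planes
#' spaced 0.6 um, one 3D stack every 3 s, an EMCCD-like Poisson-Gaussian
#' camera and slow tri-exponential photobleaching.
#'
#' @slot nFrames number of time points.
#' @slot nZ number of z planes (>= 3).
#' @slot zStepUm z spacing in micrometres.
#' @slot frameIntervalS seconds between 3D stacks.
#' @slot xySizePx lateral image size in pixels (square).
#' @slot psfSigmaXyPx lateral PSF sd in pixels.
#' @slot psfSigmaZPlanes axial PSF sd in planes.
#' @slot backgroundLevel mean fluorescent background per voxel.
#' @slot cameraNoiseSd additive (read) noise sd per voxel.
#' @slot bleachAmplitudes three amplitudes summing to 1.
#' @slot bleachRates three bleaching rates in 1/s.
#' @slot saturationLevel voxel value at which the camera clips.
#' @export
setClass("MovieSpec",
  representation(nFrames = "numeric", nZ = "numeric", zStepUm = "numeric",
                 frameIntervalS = "numeric", xySizePx = "numeric",
                 psfSigmaXyPx = "numeric", psfSigmaZPlanes = "numeric",
                 backgroundLevel = "numeric", cameraNoiseSd = "numeric",
                 bleachAmplitudes = "numeric", bleachRates = "numeric",
                 saturationLevel = "numeric"))

setValidity("MovieSpec", function(object) {
  msg <- character()
  if (object@nZ < 3) msg <- c(msg, "nZ must be >= 3")
  if (object@nFrames < 1) msg <- c(msg, "nFrames must be >= 1")
  if (object@backgroundLevel < 0 || object@cameraNoiseSd < 0)
    msg <- c(msg, "background and noise levels must be >= 0")
  if (length(object@bleachAmplitudes) != 3L || length(object@bleachRates) != 3L)
    msg <- c(msg, "bleachAmplitudes and bleachRates must have length 3")
  else {
    if (abs(sum(object@bleachAmplitudes) - 1) > 1e-8)
      msg <- c(msg, "bleachAmplitudes must sum to 1")
    if (any(object@bleachAmplitudes < 0) || any(object@bleachRates < 0))
      msg <- c(msg, "bleach amplitudes and rates must be >= 0")
  }
  if (object@psfSigmaXyPx <= 0 || object@psfSigmaZPlanes <= 0)
    msg <- c(msg, "PSF sigmas must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a MovieSpec object
#'
#' @param nFrames,nZ,zStepUm,frameIntervalS,xySizePx acquisition geometry.
#' @param psfSigmaXyPx,psfSigmaZPlanes PSF standard deviations.
#' @param backgroundLevel,cameraNoiseSd fluorescent background mean and
#'   additive read-noise sd per voxel.
#' @param bleachAmplitudes,bleachRates tri-exponential photobleaching:
#'   fraction of fluorescence bleaching with each rate (1/s).
#' @param saturationLevel camera clipping value.
#' @return A \linkS4class{MovieSpec} object.
#' @export
movieSpec <- function(nFrames = 40, nZ = 11, zStepUm = 0.6, frameIntervalS = 3,
                      xySizePx = 64, psfSigmaXyPx = 1.3, psfSigmaZPlanes = 1.0,
                      backgroundLevel = 50, cameraNoiseSd = 3,
                      bleachAmplitudes = c(0.25, 0.35, 0.40),
                      bleachRates = c(1 / 30, 1 / 300, 1 / 3000),
                      saturationLevel = 65535)
  new("MovieSpec", nFrames = as.numeric(nFrames), nZ = as.numeric(nZ),
      zStepUm = as.numeric(zStepUm), frameIntervalS = as.numeric(frameIntervalS),
      xySizePx = as.numeric(xySizePx), psfSigmaXyPx = as.numeric(psfSigmaXyPx),
      psfSigmaZPlanes = as.numeric(psfSigmaZPlanes),
      backgroundLevel = as.numeric(backgroundLevel),
      cameraNoiseSd = as.numeric(cameraNoiseSd),
      bleachAmplitudes = as.numeric(bleachAmplitudes),
      bleachRates = as.numeric(bleachRates),
      saturationLevel = as.numeric(saturationLevel))

#' DwellMixture: mixture of exponential dwell-time components
#'
#' @slot taus component time constants in seconds (> 0).
#' @slot weights component weights in (0, 1], summing to 1.
#' @export
setClass("DwellMixture",
  representation(taus = "numeric", weights = "numeric"))

setValidity("DwellMixture", function(object) {
  msg <- character()
  if (length(object@taus) != length(object@weights) || !length(object@taus))
    msg <- c(msg, "taus and weights must be non-empty and of equal length")
  if (any(object@taus <= 0)) msg <- c(msg, "taus must be > 0")
  if (any(object@weights <= 0) || any(object@weights > 1) ||
      abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must lie in (0,1] and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Create a DwellMixture object
#' @param taus time constants in seconds.
#' @param weights mixture weights summing to 1.
#' @return A \linkS4class{DwellMixture} object.
#' @examples
#' # the bi-exponential non-permissive regime: 9 min (77%) and 34 min (23%)
#' dwellMixture(taus = c(540, 2040), weights = c(0.77, 0.23))
#' @export
dwellMixture <- function(taus, weights = rep(1 / length(taus), length(taus)))
  new("DwellMixture", taus = as.numeric(taus), weights = as.numeric(weights))

#' PromoterModel: four-state promoter with RNA birth, release and decay
#'
#' States are ON, OFF1, OFF2a and OFF2b arranged as a linear chain with a
#' branched deep-OFF state: ON <-> OFF1 -> {OFF2a, OFF2b} -> OFF1. Convoys
#' form while ON (initiations at rate \code{kIni}); nascent RNAs convert to
#' mature at \code{kRelease} per molecule and mature RNAs decay at
#' \code{kDeg} per molecule.
#'
#' @slot kOn1 OFF1 -> ON rate (1/s).
#' @slot kOff1 ON -> OFF1 rate (1/s).
#' @slot kOff2 OFF1 -> OFF2 total entry rate (1/s), split by \code{f1}.
#' @slot f1 fraction of OFF2 entries going to OFF2a.
#' @slot kOn2a OFF2a -> OFF1 rate (1/s).
#' @slot kOn2b OFF2b -> OFF1 rate (1/s).
#' @slot kIni initiation rate while ON (1/s).
#' @slot kRelease nascent -> mature conversion rate per molecule (1/s).
#' @slot kDeg mature decay rate per molecule (1/s).
#' @export
setClass("PromoterModel",
  representation(kOn1 = "numeric", kOff1 = "numeric", kOff2 = "numeric",
                 f1 = "numeric", kOn2a = "numeric", kOn2b = "numeric",
                 kIni = "numeric", kRelease = "numeric", kDeg = "numeric"))

setValidity("PromoterModel", function(object) {
  msg <- character()
  for (s in c("kOn1", "kOff1", "kOff2", "kOn2a", "kOn2b", "kIni",
              "kRelease", "kDeg")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, paste(s, "must be a single finite rate >= 0"))
  }
  if (length(object@f1) != 1L || object@f1 < 0 || object@f1 > 1)
    msg <- c(msg, "f1 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a PromoterModel object
#'
#' All rates are in 1/s. \code{kOff2} is the total OFF1 -> OFF2 exit rate;
#' a fraction \code{f1} of those transitions enter OFF2a and the rest OFF2b.
#'
#' @param kOn1,kOff1,kOff2,f1,kOn2a,kOn2b,kIni,kRelease,kDeg see slots.
#' @return A \linkS4class{PromoterModel} object.
#' @export
promoterModel <- function(kOn1, kOff1, kOff2 = 0, f1 = 1, kOn2a = 1 / 300,
                          kOn2b = 1 / 1800, kIni = 0, kRelease = 0,
                          kDeg = 0) {
  new("PromoterModel", kOn1 = as.numeric(kOn1), kOff1 = as.numeric(kOff1),
      kOff2 = as.numeric(kOff2), f1 = as.numeric(f1),
      kOn2a = as.numeric(kOn2a), kOn2b = as.numeric(kOn2b),
      kIni = as.numeric(kIni), kRelease = as.numeric(kRelease),
      kDeg = as.numeric(kDeg))
}

#' CellCounts: per-cell nascent and mature pre-mRNA counts
#'
#' @slot nascent integer vector, nascent (TS-attached) RNAs per cell.
#' @slot mature integer vector, released (nucleoplasmic) RNAs per cell.
#' @export
setClass("CellCounts",
  representation(nascent = "integer", mature = "integer"))

setValidity("CellCounts", function(object) {
  msg <- character()
  if (length(object@nascent) != length(object@mature))
    msg <- c(msg, "nascent and mature must have the same length")
  if (any(object@nascent < 0, na.rm = TRUE) || any(object@mature < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Create a CellCounts object
#' @param nascent,mature non-negative integer vectors of equal length.
#' @return A \linkS4class{CellCounts} object.
#' @export
cellCounts <- function(nascent, mature)
  new("CellCounts", nascent = as.integer(round(nascent)),
      mature = as.integer(round(mature)))

#' PopulationSummary: population means targeted by rate constraints
#'
#' @slot meanMature average number of released pre-mRNAs per cell.
#' @slot meanNascent average number of nascent pre-mRNAs per cell.
#' @export
setClass("PopulationSummary",
  representation(meanMature = "numeric", meanNascent = "numeric"))

setValidity("PopulationSummary", function(object) {
  if (object@meanMature < 0 || object@meanNascent < 0)
    "population means must be >= 0" else TRUE
})

#' Create a PopulationSummary object
#' @param meanMature,meanNascent population means (per cell).
#' @return A \linkS4class{PopulationSummary} object.
#' @export
populationSummary <- function(meanMature, meanNascent)
  new("PopulationSummary", meanMature = as.numeric(meanMature),
      meanNascent = as.numeric(meanNascent))

#' GridSpec: parameter grid for population fitting
#'
#' Value lists for the free parameters of the four-state model; \code{kOn2a}
#' and \code{kDeg} are held fixed. \code{defaultGridSpec()} returns the full
#' 8 x 4 x 4 x 4 x 5 grid used for the HIV-1 reporter fits.
#'
#' @slot invKIniS values of 1/kIni in seconds.
#' @slot f1 values of the OFF2a entry fraction.
#' @slot invKOn2bMin values of 1/kOn2b in minutes.
#' @slot kOff1PerS values of kOff1 in 1/s.
#' @slot invKOn1Min values of 1/kOn1 in minutes.
#' @slot invKOn2aMin fixed 1/kOn2a in minutes.
#' @slot kDegPerMin fixed mature decay rate in 1/min.
#' @export
setClass("GridSpec",
  representation(invKIniS = "numeric", f1 = "numeric", invKOn2bMin = "numeric",
                 kOff1PerS = "numeric", invKOn1Min = "numeric",
                 invKOn2aMin = "numeric", kDegPerMin = "numeric"))

setValidity("GridSpec", function(object) {
  msg <- character()
  for (s in c("invKIniS", "f1", "invKOn2bMin", "kOff1PerS", "invKOn1Min"))
    if (!length(slot(object, s)) || any(slot(object, s) <= 0 & s != "f1"))
      msg <- c(msg, paste(s, "must be a non-empty positive list"))
  if (any(object@f1 < 0) || any(object@f1 > 1))
    msg <- c(msg, "f1 values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a GridSpec object
#' @param invKIniS,f1,invKOn2bMin,kOff1PerS,invKOn1Min value lists.
#' @param invKOn2aMin fixed 1/kOn2a in minutes.
#' @param kDegPerMin fixed mature decay rate in 1/min.
#' @return A \linkS4class{GridSpec} object.
#' @export
gridSpec <- function(invKIniS, f1, invKOn2bMin, kOff1PerS, invKOn1Min,
                     invKOn2aMin = 5, kDegPerMin = 1 / 75)
  new("GridSpec", invKIniS = as.numeric(invKIniS), f1 = as.numeric(f1),
      invKOn2bMin = as.numeric(invKOn2bMin), kOff1PerS = as.numeric(kOff1PerS),
      invKOn1Min = as.numeric(invKOn1Min), invKOn2aMin = as.numeric(invKOn2aMin),
      kDegPerMin = as.numeric(kDegPerMin))

#' @rdname gridSpec
#' @export
defaultGridSpec <- function()
  gridSpec(invKIniS = c(2.3, 2.6, 3.0, 3.4, 3.7, 4.0, 4.3, 4.6),
           f1 = c(0.6, 0.7, 0.8, 0.9),
           invKOn2bMin = c(20, 30, 40, 50),
           kOff1PerS = c(1 / 90, 1 / 110, 1 / 130, 1 / 160),
           invKOn1Min = c(1, 1.5, 2, 2.5, 3))

#' TranscriptionCycle: an isolated TS intensity peak
#'
#' Phase boundaries are descriptive estimates from the thresholded segment
#' (10%/90%-of-peak crossings); the model fit refines them implicitly.
#'
#' @slot frameStart,frameEnd first/last frame of the above-threshold segment.
#' @slot upStart,upEnd,downStart,downEnd frame indices of the estimated
#'   UP-ramp and DOWN-ramp boundaries (NA when not estimated).
#' @slot isolated TRUE when the segment is flanked by silent periods on both
#'   sides (i.e. does not touch the trace boundaries).
#' @export
setClass("TranscriptionCycle",
  representation(frameStart = "integer", frameEnd = "integer",
                 upStart = "integer", upEnd = "integer",
                 downStart = "integer", downEnd = "integer",
                 isolated = "logical"),
  prototype(upStart = NA_integer_, upEnd = NA_integer_,
            downStart = NA_integer_, downEnd = NA_integer_))

setValidity("TranscriptionCycle", function(object) {
  msg <- character()
  if (object@frameStart > object@frameEnd)
    msg <- c(msg, "frameStart must be <= frameEnd")
  b <- c(object@upStart, object@upEnd, object@downStart, object@downEnd)
  if (!anyNA(b)) {
    if (!(b[1L] < b[2L] && b[2L] <= b[3L] && b[3L] < b[4L]))
      msg <- c(msg, "phase boundaries must satisfy upStart < upEnd <= downStart < downEnd")
  }
  if (length(msg)) msg else TRUE
})

#' FittedConvoy: convoy-model fit of a transcription cycle
#'
#' @slot params fitted \linkS4class{ConvoyParams}.
#' @slot t0 fitted initiation time of the first polymerase (s).
#' @slot vElIsLowerBound TRUE when the residual profile over vEl is flat and
#'   only a minimal elongation rate could be determined.
#' @slot residualNorm root-mean-square residual of the fit.
#' @slot uncertainty approximate per-parameter standard errors.
#' @export
setClass("FittedConvoy",
  representation(params = "ConvoyParams", t0 = "numeric",
                 vElIsLowerBound = "logical", residualNorm = "numeric",
                 uncertainty = "numeric"))

setValidity("FittedConvoy", function(object) {
  if (any(object@uncertainty < 0, na.rm = TRUE))
    "uncertainties must be >= 0" else TRUE
})

#' DwellFit: maximum-likelihood exponential dwell-time fit
#'
#' @slot model \code{"mono"} or \code{"bi"}.
#' @slot taus fitted time constants (s).
#' @slot weights fitted component weights (sum to 1).
#' @slot logLik maximised log-likelihood.
#' @export
setClass("DwellFit",
  representation(model = "character", taus = "numeric",
                 weights = "numeric", logLik = "numeric"))

setValidity("DwellFit", function(object) {
  msg <- character()
  if (any(object@taus <= 0)) msg <- c(msg, "taus must be > 0")
  if (abs(sum(object@weights) - 1) > 1e-6)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' OnOffConfig: configuration for threshold ON/OFF segmentation
#'
#' @slot threshold intensity above which the TS is considered active.
#' @slot smoothWindow moving-average window in frames (odd, default 3).
#' @slot minStateFrames minimum consecutive frames for a state (default 2).
#' @export
setClass("OnOffConfig",
  representation(threshold = "numeric", smoothWindow = "integer",
                 minStateFrames = "integer"))

setValidity("OnOffConfig", function(object) {
  msg <- character()
  if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
    msg <- c(msg, "smoothWindow must be odd and >= 1")
  if (object@minStateFrames < 1L)
    msg <- c(msg, "minStateFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create an OnOffConfig object
#' @param threshold intensity threshold separating active from silent frames,
#'   typically set from the mean single-molecule intensity.
#' @param smoothWindow odd moving-average window in frames.
#' @param minStateFrames minimum run length of a state in frames.
#' @return An \linkS4class{OnOffConfig} object.
#' @export
onOffConfig <- function(threshold, smoothWindow = 3L, minStateFrames = 2L)
  new("OnOffConfig", threshold = as.numeric(threshold),
      smoothWindow = as.integer(smoothWindow),
      minStateFrames = as.integer(minStateFrames))

#' CalibrationRecord: quantities linking a.u. intensity to nascent counts
#'
#' @slot iMs2 per-frame TS intensity in arbitrary units.
#' @slot iFinal mean intensity of the last four movie frames (a.u.).
#' @slot nNascFinal nascent-transcript count estimated from the calibration
#'   stack acquired at movie end.
#' @slot singleMoleculeIntensity mean integrated intensity of a single RNA
#'   molecule in the calibration stack (a.u.).
#' @export
setClass("CalibrationRecord",
  representation(iMs2 = "numeric", iFinal = "numeric", nNascFinal = "numeric",
                 singleMoleculeIntensity = "numeric"))

setValidity("CalibrationRecord", function(object) {
  if (object@nNascFinal < 0) "nNascFinal must be >= 0" else TRUE
})

#' Create a CalibrationRecord object
#' @param iMs2 per-frame TS intensity trace in a.u.
#' @param iFinal mean of the last four frames, a.u.
#' @param nNascFinal nascent count at movie end from the calibration stack.
#' @param singleMoleculeIntensity single-molecule intensity, a.u. (optional).
#' @return A \linkS4class{CalibrationRecord} object.
#' @export
calibrationRecord <- function(iMs2, iFinal, nNascFinal,
                              singleMoleculeIntensity = NA_real_)
  new("CalibrationRecord", iMs2 = as.numeric(iMs2), iFinal = as.numeric(iFinal),
      nNascFinal = as.numeric(nNascFinal),
      singleMoleculeIntensity = as.numeric(singleMoleculeIntensity))
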