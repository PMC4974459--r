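## Deterministic forward model of transcription-site intensity produced by a
## polymerase convoy. Intensity is expressed in RNA equivalents: one unit is
## the signal of a transcript carrying the complete MS2 repeat.

## nt/s from kb/min
.ntPerS <- function(vEl) vEl * 1000 / 60

## Signal of polymerases initiating at `initTimes`, evaluated at times `t`.
## Per polymerase: 0 before it reaches the repeat, linear 0->1 across the
## repeat (continuum approximation of the discrete stem loops), 1 until
## release at (gene length)/speed + tProc after initiation, then 0.
.convoySignal <- function(t, initTimes, geom, vEl, tProc) {
  v <- .ntPerS(vEl)
  tEnter <- initTimes + geom@lPre / v
  transit <- geom@lMs2 / v
  tRelease <- initTimes + (geom@lPre + geom@lMs2 + geom@lPost) / v + tProc
  s <- outer(t, tEnter, "-") / transit
  s[s < 0] <- 0
  s[s > 1] <- 1
  s[outer(t, tRelease, ">=")] <- 0
  rowSums(s)
}

#' Transcription-site intensity of a polymerase convoy
#'
#' Computes the deterministic TS intensity (in RNA equivalents) produced by a
#' convoy of regularly spaced polymerases. Polymerase \eqn{i} (0-based)
#' initiates at \code{t0 + i * tSpace}, synthesises MS2 signal linearly while
#' traversing the repeat, carries one full RNA equivalent until it reaches
#' the cleavage site plus the processing delay, and then releases its
#' transcript instantaneously. The resulting curve is tri-phasic: a linear
#' UP ramp, a plateau at the convoy size, and a linear DOWN ramp.
#'
#' @param t numeric vector of times in seconds.
#' @param params a \linkS4class{ConvoyParams} object.
#' @param geom a \linkS4class{GeneGeometry} object.
#' @param t0 initiation time of the first polymerase (s).
#' @return Numeric vector of intensities in RNA equivalents (between 0 and
#'   \code{nPol(params)}).
#' @examples
#' p <- convoyParams(nPol = 3, tSpace = 10, vEl = 1, tProc = 30)
#' g <- geneGeometry(lPre = 0, lMs2 = 1000, lPost = 1000)
#' tsIntensity(60, p, g)   # 1 + 0.8333 + 0.6667 = 2.5
#' @seealso [analyticDurations()] for the phase durations in closed form.
#' @export
tsIntensity <- function(t, params, geom, t0 = 0) {
  stopifnot(is(params, "ConvoyParams"), is(geom, "GeneGeometry"))
  validObject(params); validObject(geom)
  if (!all(is.finite(t))) stop("'t' must be finite")
  initTimes <- t0 + (seq_len(params@nPol) - 1) * params@tSpace
  .convoySignal(t, initTimes, geom, params@vEl, params@tProc)
}

#' Analytic phase durations of a convoy transcription cycle
#'
#' Closed-form durations of the UP ramp, plateau and DOWN ramp of the
#' tri-phasic intensity curve, for regular polymerase spacing. A full
#' plateau at \code{nPol} exists iff
#' \code{(nPol - 1) * tSpace <= lPost / vEl + tProc}; otherwise the plateau
#' is clamped to zero and the cycle is flagged as truncated (the curve peaks
#' below the convoy size).
#'
#' @inheritParams tsIntensity
#' @return A list with elements \code{up_ramp}, \code{plateau},
#'   \code{down_ramp}, \code{visible_total} (all in seconds) and the logical
#'   \code{truncated}.
#' @export
analyticDurations <- function(params, geom) {
  stopifnot(is(params, "ConvoyParams"), is(geom, "GeneGeometry"))
  validObject(params); validObject(geom)
  v <- .ntPerS(params@vEl)
  spread <- (params@nPol - 1) * params@tSpace
  up <- spread + geom@lMs2 / v
  plateauRaw <- geom@lPost / v + params@tProc - spread
  plateau <- max(0, plateauRaw)
  down <- spread
  list(up_ramp = up, plateau = plateau, down_ramp = down,
       visible_total = up + plateau + down,
       truncated = plateauRaw < 0)
}

#' Convert temporal polymerase spacing to nucleotides
#'
#' @param tSpace spacing between successive initiations, seconds.
#' @param vEl elongation rate, kb/min.
#' @return Spacing along the gene in nucleotides,
#'   \code{tSpace * vEl * 1000 / 60}.
#' @examples
#' nucleotideSpacing(4.1, 4.1)  # ~280 nt
#' @export
nucleotideSpacing <- function(tSpace, vEl) {
  if (any(tSpace < 0) || any(vEl < 0)) stop("inputs must be non-negative")
  tSpace * .ntPerS(vEl)
}
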