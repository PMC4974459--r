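## Accessor generics. Slot access from user code goes through these.

#' Accessors for ConvoyQuant S4 objects
#'
#' @param object an S4 object from this package.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nPol", function(object) standardGeneric("nPol"))
#' @rdname accessors
#' @export
setGeneric("tSpace", function(object) standardGeneric("tSpace"))
#' @rdname accessors
#' @export
setGeneric("vEl", function(object) standardGeneric("vEl"))
#' @rdname accessors
#' @export
setGeneric("tProc", function(object) standardGeneric("tProc"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("traceUnits", function(object) standardGeneric("traceUnits"))
#' @rdname accessors
#' @export
setGeneric("traceFlags", function(object) standardGeneric("traceFlags"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nascentCounts", function(object) standardGeneric("nascentCounts"))
#' @rdname accessors
#' @export
setGeneric("matureCounts", function(object) standardGeneric("matureCounts"))
#' @rdname accessors
#' @export
setGeneric("convoyEstimates", function(object) standardGeneric("convoyEstimates"))
#' @rdname accessors
#' @export
setGeneric("dwellTaus", function(object) standardGeneric("dwellTaus"))
#' @rdname accessors
#' @export
setGeneric("dwellWeights", function(object) standardGeneric("dwellWeights"))

#' @rdname accessors
#' @export
setMethod("nPol", "ConvoyParams", function(object) object@nPol)
#' @rdname accessors
#' @export
setMethod("tSpace", "ConvoyParams", function(object) object@tSpace)
#' @rdname accessors
#' @export
setMethod("vEl", "ConvoyParams", function(object) object@vEl)
#' @rdname accessors
#' @export
setMethod("tProc", "ConvoyParams", function(object) object@tProc)

#' @rdname accessors
#' @export
setMethod("nPol", "FittedConvoy", function(object) object@params@nPol)
#' @rdname accessors
#' @export
setMethod("tSpace", "FittedConvoy", function(object) object@params@tSpace)
#' @rdname accessors
#' @export
setMethod("vEl", "FittedConvoy", function(object) object@params@vEl)
#' @rdname accessors
#' @export
setMethod("tProc", "FittedConvoy", function(object) object@params@tProc)
#' @rdname accessors
#' @export
setMethod("convoyEstimates", "FittedConvoy", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("traceTimes", "IntensityTrace", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("traceValues", "IntensityTrace", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("traceUnits", "IntensityTrace", function(object) object@units)
#' @rdname accessors
#' @export
setMethod("traceFlags", "IntensityTrace", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("frameInterval", "IntensityTrace",
          function(object) mean(diff(object@times)))

#' @rdname accessors
#' @export
setMethod("nascentCounts", "CellCounts", function(object) object@nascent)
#' @rdname accessors
#' @export
setMethod("matureCounts", "CellCounts", function(object) object@mature)

#' @rdname accessors
#' @export
setMethod("dwellTaus", "DwellMixture", function(object) object@taus)
#' @rdname accessors
#' @export
setMethod("dwellWeights", "DwellMixture", function(object) object@weights)
#' @rdname accessors
#' @export
setMethod("dwellTaus", "DwellFit", function(object) object@taus)
#' @rdname accessors
#' @export
setMethod("dwellWeights", "DwellFit", function(object) object@weights)

#' @rdname accessors
#' @param x a \linkS4class{CellCounts} object.
#' @export
setMethod("length", "CellCounts", function(x) length(x@nascent))

setMethod("show", "ConvoyParams", function(object) {
  cat(sprintf(
    "ConvoyParams: %d polymerase(s), t_space = %.3g s, v_el = %.3g kb/min, t_proc = %.3g s\n",
    as.integer(object@nPol), object@tSpace, object@vEl, object@tProc))
})

setMethod("show", "GeneGeometry", function(object) {
  cat(sprintf("GeneGeometry: pre %g nt | MS2 %g nt | post %g nt\n",
              object@lPre, object@lMs2, object@lPost))
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace: %d frames, dt = %.3g s, units = %s\n",
              length(object@times), mean(diff(object@times)), object@units))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "PromoterModel", function(object) {
  cat("PromoterModel (rates in 1/s):\n")
  cat(sprintf("  OFF1<->ON   : k_on1 = %.4g, k_off1 = %.4g\n",
              object@kOn1, object@kOff1))
  cat(sprintf("  OFF1 ->OFF2 : k_off2 = %.4g (f1 = %.2f), k_on2a = %.4g, k_on2b = %.4g\n",
              object@kOff2, object@f1, object@kOn2a, object@kOn2b))
  cat(sprintf("  RNA         : k_ini = %.4g, k_release = %.4g, k_deg = %.4g\n",
              object@kIni, object@kRelease, object@kDeg))
})

setMethod("show", "CellCounts", function(object) {
  cat(sprintf("CellCounts: %d cells, mean nascent %.2f, mean mature %.2f\n",
              length(object@nascent), mean(object@nascent), mean(object@mature)))
})

setMethod("show", "FittedConvoy", function(object) {
  cat("FittedConvoy fit:\n  ")
  show(object@params)
  cat(sprintf("  t0 = %.3g s, RMS residual = %.3g%s\n", object@t0,
              object@residualNorm,
              if (isTRUE(object@vElIsLowerBound)) " (v_el is a lower bound)" else ""))
})

setMethod("show", "DwellFit", function(object) {
  cat(sprintf("DwellFit (%s): tau = %s s, weights = %s, logLik = %.2f\n",
              object@model, paste(signif(object@taus, 4), collapse = ", "),
              paste(signif(object@weights, 3), collapse = ", "),
              object@logLik))
})
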