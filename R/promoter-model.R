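## Analytic machinery of the four-state promoter model: stationary
## distribution, stationary RNA means and the steady-state rate constraints
## used to complete partially specified models.

## Unnormalised stationary weights in order (ON, OFF1, OFF2a, OFF2b).
## The state graph is a tree, so detailed balance gives the weights directly
## with OFF1 as reference:
##   w_ON    = k_on1 / k_off1
##   w_OFF2a = f1 * k_off2 / k_on2a
##   w_OFF2b = (1 - f1) * k_off2 / k_on2b
.stationaryWeights <- function(model) {
  wOn <- if (model@kOff1 > 0) model@kOn1 / model@kOff1
         else if (model@kOn1 > 0) Inf else 0
  w2a <- if (model@f1 * model@kOff2 > 0) model@f1 * model@kOff2 / model@kOn2a
         else 0
  w2b <- if ((1 - model@f1) * model@kOff2 > 0)
           (1 - model@f1) * model@kOff2 / model@kOn2b else 0
  w <- c(ON = wOn, OFF1 = 1, OFF2a = w2a, OFF2b = w2b)
  if (is.infinite(wOn)) {
    w <- c(ON = 1, OFF1 = 0, OFF2a = 0, OFF2b = 0)
    attr(w, "absorbing") <- TRUE
  }
  w / sum(w)
}

#' Stationary distribution and RNA means of the promoter model
#'
#' Solves the four-state promoter CTMC in closed form (the state graph is a
#' tree, so detailed balance applies) and derives the stationary mean
#' nascent and mature RNA counts. Initiations occur at rate \code{kIni}
#' while ON; each nascent RNA converts to mature at \code{kRelease} and each
#' mature RNA decays at \code{kDeg}, so by Little's law
#' \code{mean_nascent = kIni * pi_ON / kRelease} and
#' \code{mean_mature = kIni * pi_ON / kDeg}. In particular
#' \code{mean_mature / mean_nascent = kRelease / kDeg} for any valid model.
#'
#' @param model a \linkS4class{PromoterModel}.
#' @return A list with \code{pi} (named stationary probabilities over ON,
#'   OFF1, OFF2a, OFF2b), \code{mean_nascent} and \code{mean_mature}.
#'   When \code{kOff1 = 0} with \code{kOn1 > 0} the ON state is absorbing;
#'   \code{pi} is the point mass on ON and a warning is raised.
#' @export
stationaryStats <- function(model) {
  stopifnot(is(model, "PromoterModel"))
  validObject(model)
  w <- .stationaryWeights(model)
  if (isTRUE(attr(w, "absorbing")))
    warning("kOff1 = 0 with kOn1 > 0: ON state is absorbing, pi_ON = 1")
  piOn <- unname(w["ON"])
  flux <- model@kIni * piOn
  list(pi = w[],
       mean_nascent = if (model@kRelease > 0) flux / model@kRelease else
                        if (flux == 0) 0 else Inf,
       mean_mature = if (model@kDeg > 0) flux / model@kDeg else
                       if (flux == 0) 0 else Inf)
}

#' Complete a promoter model from steady-state population constraints
#'
#' Given all rates except \code{kRelease} and \code{kOff2}, solves the two
#' steady-state constraints used when fitting the model to smFISH-like
#' count data: \code{kRelease = kDeg * meanMat / meanNasc} (from
#' \code{kRelease / kDeg = meanMat / meanNasc}) and \code{kOff2} chosen so
#' that the stationary mean mature count equals \code{meanMat}. The second
#' constraint is linear in \code{kOff2}: writing
#' \code{C = f1 / kOn2a + (1 - f1) / kOn2b}, the ON occupancy is
#' \code{pi_ON = wOn / (1 + wOn + C * kOff2)} with \code{wOn = kOn1/kOff1},
#' so \code{kOff2 = (kIni * wOn / (kDeg * meanMat) - 1 - wOn) / C}.
#' Negative solutions mean the requested mean is unreachable even with the
#' promoter never visiting OFF2; such parameter combinations are reported as
#' infeasible rather than raising an error, so grid searches can skip them.
#'
#' @param model a \linkS4class{PromoterModel} whose \code{kOff2} and
#'   \code{kRelease} slots are ignored and re-derived.
#' @param target a \linkS4class{PopulationSummary} with positive means.
#' @return A list with \code{model} (the completed
#'   \linkS4class{PromoterModel}, or NULL when infeasible), \code{status}
#'   (\code{"ok"} or \code{"infeasible_negative_koff2"}) and the solved
#'   \code{kOff2} value (possibly negative, for diagnostics).
#' @export
solveConstrainedRates <- function(model, target) {
  stopifnot(is(model, "PromoterModel"), is(target, "PopulationSummary"))
  validObject(model); validObject(target)
  if (target@meanMature <= 0 || target@meanNascent <= 0)
    stop("target means must be > 0")
  if (model@kDeg <= 0 || model@kOff1 <= 0 || model@kOn1 <= 0 || model@kIni <= 0)
    stop("kDeg, kOff1, kOn1 and kIni must be > 0 to solve the constraints")
  kRelease <- model@kDeg * target@meanMature / target@meanNascent
  wOn <- model@kOn1 / model@kOff1
  C <- model@f1 / model@kOn2a + (1 - model@f1) / model@kOn2b
  kOff2 <- (model@kIni * wOn / (model@kDeg * target@meanMature) - 1 - wOn) / C
  if (kOff2 < 0)
    return(list(model = NULL, status = "infeasible_negative_koff2",
                kOff2 = kOff2))
  out <- model
  out@kOff2 <- kOff2
  out@kRelease <- kRelease
  validObject(out)
  list(model = out, status = "ok", kOff2 = kOff2)
}

#' Build a promoter model from grid coordinates
#'
#' Converts one point of a \linkS4class{GridSpec} (values in the mixed
#' units the grid is specified in) to a \linkS4class{PromoterModel} in 1/s,
#' leaving \code{kOff2} and \code{kRelease} at 0 for
#' [solveConstrainedRates()] to fill in.
#'
#' @param invKIniS 1/kIni in seconds.
#' @param f1 OFF2a entry fraction.
#' @param invKOn2bMin 1/kOn2b in minutes.
#' @param kOff1PerS kOff1 in 1/s.
#' @param invKOn1Min 1/kOn1 in minutes.
#' @param invKOn2aMin 1/kOn2a in minutes.
#' @param kDegPerMin mature decay rate in 1/min.
#' @return A \linkS4class{PromoterModel}.
#' @export
gridPointModel <- function(invKIniS, f1, invKOn2bMin, kOff1PerS, invKOn1Min,
                           invKOn2aMin = 5, kDegPerMin = 1 / 75) {
  promoterModel(kOn1 = 1 / (invKOn1Min * 60), kOff1 = kOff1PerS,
                kOff2 = 0, f1 = f1,
                kOn2a = 1 / (invKOn2aMin * 60), kOn2b = 1 / (invKOn2bMin * 60),
                kIni = 1 / invKIniS, kRelease = 0, kDeg = kDegPerMin / 60)
}
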