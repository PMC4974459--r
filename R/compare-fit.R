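## Comparison of simulated and observed copy-number distributions, and the
## grid-search fit of the promoter model with top-10 averaging.

#' Compare simulated and observed per-cell RNA count distributions
#'
#' Mature (released) counts are compared with a two-sample
#' Kolmogorov-Smirnov test; nascent counts with a chi-squared test on
#' integer-count bins pooled so that every expected cell is at least 5
#' (nascent distributions contain many tied values, e.g. zeros from silent
#' TS, which makes KS unsuitable there). The two p-values are multiplied to
#' give the ranking score used by [gridSearchFit()].
#'
#' @param sim,obs \linkS4class{CellCounts} objects.
#' @return A list with \code{p_mature}, \code{ks_statistic},
#'   \code{p_nascent}, \code{chi2_statistic} and \code{p_product}.
#' @export
compareDistributions <- function(sim, obs) {
  stopifnot(is(sim, "CellCounts"), is(obs, "CellCounts"))
  if (!length(sim) || !length(obs)) stop("both samples must be non-empty")
  ks <- suppressWarnings(ks.test(matureCounts(sim), matureCounts(obs)))
  chi <- .pooledChisq(nascentCounts(sim), nascentCounts(obs))
  list(p_mature = unname(ks$p.value), ks_statistic = unname(ks$statistic),
       p_nascent = chi$p.value, chi2_statistic = chi$statistic,
       p_product = unname(ks$p.value) * chi$p.value)
}

## Two-sample chi-squared on integer counts with left-to-right pooling of
## bins until every expected cell is >= 5.
.pooledChisq <- function(x, y) {
  vals <- 0:max(x, y)
  cx <- tabulate(x + 1L, nbins = length(vals))
  cy <- tabulate(y + 1L, nbins = length(vals))
  nx <- sum(cx); ny <- sum(cy); n <- nx + ny
  ## expected cell for pooled column total ct: ct * nx / n and ct * ny / n
  minRow <- min(nx, ny)
  needed <- 5 * n / minRow   # column total needed for min expected >= 5
  pooledX <- integer(0); pooledY <- integer(0)
  accX <- 0L; accY <- 0L
  for (i in seq_along(vals)) {
    accX <- accX + cx[i]; accY <- accY + cy[i]
    if ((accX + accY) >= needed) {
      pooledX <- c(pooledX, accX); pooledY <- c(pooledY, accY)
      accX <- 0L; accY <- 0L
    }
  }
  if (accX + accY > 0L) {
    if (length(pooledX)) {
      pooledX[length(pooledX)] <- pooledX[length(pooledX)] + accX
      pooledY[length(pooledY)] <- pooledY[length(pooledY)] + accY
    } else {
      pooledX <- accX; pooledY <- accY
    }
  }
  if (length(pooledX) < 2L)
    stop("fewer than 2 bins remain after pooling; chi-squared undefined")
  res <- suppressWarnings(chisq.test(rbind(pooledX, pooledY)))
  list(p.value = unname(res$p.value), statistic = unname(res$statistic),
       bins = length(pooledX))
}

#' Grid-search fit of the promoter model to observed count distributions
#'
#' For every point of the parameter grid, completes the model via the
#' steady-state constraints (matching the observed mean mature count and
#' the mature/nascent ratio), simulates a cell population, scores the
#' simulated nascent and mature distributions against the observations with
#' [compareDistributions()], ranks all feasible combinations by the product
#' of the two p-values (highest first) and averages the parameters of the
#' 10 best-fitting combinations.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param obs observed \linkS4class{CellCounts} (e.g. smFISH-like data).
#' @param nCells cells per simulated population.
#' @param nSteps,dt fixed-step settings (see [simulatePopulation()]).
#' @param scheme simulation scheme passed to [simulatePopulation()].
#' @param seed integer seed; per-combination seeds are derived from it.
#' @param target optional \linkS4class{PopulationSummary}; defaults to the
#'   observed means.
#' @return A list with \code{table} (one row per grid point, sorted by
#'   descending \code{p_product}, including feasibility status),
#'   \code{top10} (named means of the parameters over the 10 best feasible
#'   combinations) and \code{n_infeasible}.
#' @export
gridSearchFit <- function(grid, obs, nCells = 500, nSteps = 36000, dt = 1,
                          scheme = c("fixed_step", "exact"), seed = NULL,
                          target = NULL) {
  stopifnot(is(grid, "GridSpec"), is(obs, "CellCounts"))
  validObject(grid)
  scheme <- match.arg(scheme)
  if (is.null(target))
    target <- populationSummary(mean(matureCounts(obs)),
                                mean(nascentCounts(obs)))
  combos <- expand.grid(invKIniS = grid@invKIniS, f1 = grid@f1,
                        invKOn2bMin = grid@invKOn2bMin,
                        kOff1PerS = grid@kOff1PerS,
                        invKOn1Min = grid@invKOn1Min,
                        KEEP.OUT.ATTRS = FALSE)
  nC <- nrow(combos)
  seeds <- withSeed(seed, sample.int(2^30, nC))
  res <- vector("list", nC)
  for (i in seq_len(nC)) {
    cm <- combos[i, ]
    m0 <- gridPointModel(cm$invKIniS, cm$f1, cm$invKOn2bMin, cm$kOff1PerS,
                         cm$invKOn1Min, grid@invKOn2aMin, grid@kDegPerMin)
    sol <- solveConstrainedRates(m0, target)
    if (sol$status != "ok") {
      res[[i]] <- data.frame(cm, kOff2 = sol$kOff2, kRelease = NA_real_,
                             status = sol$status, p_nascent = NA_real_,
                             p_mature = NA_real_, p_product = NA_real_)
      next
    }
    sim <- simulatePopulation(sol$model, nCells = nCells, nSteps = nSteps,
                              dt = dt, seed = seeds[i], scheme = scheme)
    sc <- compareDistributions(sim, obs)
    res[[i]] <- data.frame(cm, kOff2 = sol$kOff2,
                           kRelease = sol$model@kRelease, status = "ok",
                           p_nascent = sc$p_nascent, p_mature = sc$p_mature,
                           p_product = sc$p_product)
  }
  tab <- do.call(rbind, res)
  feasible <- tab$status == "ok"
  if (!any(feasible))
    stop("all grid combinations are infeasible (negative kOff2)")
  ord <- order(!feasible, -tab$p_product)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  topN <- head(which(tab$status == "ok"), 10L)
  pars <- c("invKIniS", "f1", "invKOn2bMin", "kOff1PerS", "invKOn1Min",
            "kOff2", "kRelease")
  top10 <- vapply(pars, function(p) mean(tab[[p]][topN]), numeric(1))
  list(table = tab, top10 = top10, n_infeasible = sum(!feasible))
}
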