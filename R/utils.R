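#' @useDynLib ConvoyQuant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx chisq.test coef cor dexp ks.test lm mad median
#'   nls optim rbinom rexp rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

## Run `expr` under a temporary RNG state seeded with `seed`; restore the
## caller's RNG afterwards so generators are pure functions of (args, seed).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Centered moving average with edge replication, window must be odd.
movingAverage <- function(x, window) {
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be odd and >= 1")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  if (n < window) stop("series shorter than smoothing window")
  xp <- c(rep(x[1L], h), x, rep(x[n], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1L):(h + n)]
}

## 1-D Gaussian kernel truncated at 3 sigma, normalised to sum 1.
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## Convolve a vector with a kernel using reflective boundaries.
convolveReflect1d <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(x * k)
  n <- length(x)
  left <- x[pmin(n, pmax(1L, (r:1) + 1L))]      # reflect about first element
  right <- x[pmin(n, pmax(1L, (n - 1L) - 0:(r - 1L)))]
  xp <- c(left, x, right)
  as.numeric(stats::filter(xp, rev(k), sides = 2))[(r + 1L):(r + n)]
}

## Separable Gaussian blur of a 3-D array (z, y, x), anisotropic sigma.
gaussBlur3d <- function(a, sigma_xy, sigma_z) {
  d <- dim(a)
  kz <- gaussKernel1d(sigma_z)
  kxy <- gaussKernel1d(sigma_xy)
  out <- a
  if (length(kz) > 1L)
    for (iy in seq_len(d[2L])) for (ix in seq_len(d[3L]))
      out[, iy, ix] <- convolveReflect1d(out[, iy, ix], kz)
  if (length(kxy) > 1L) {
    for (iz in seq_len(d[1L])) {
      sl <- out[iz, , ]
      sl <- apply(sl, 2L, convolveReflect1d, k = kxy)       # along y
      sl <- t(apply(sl, 1L, convolveReflect1d, k = kxy))    # along x
      out[iz, , ] <- sl
    }
  }
  out
}

## Run-length encoding of a logical/integer vector into (value, start, length).
runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths)
}
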