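## Serialisation of the package's data objects in plain interchange
## formats: traces and counts as CSV, parameters/models as JSON, movie
## stacks as multi-page float TIFF with a JSON sidecar.

#' Read and write intensity traces as CSV
#'
#' Traces are stored with header columns \code{time_s,intensity,units}.
#'
#' @param trace an \linkS4class{IntensityTrace}.
#' @param path file path.
#' @return \code{writeIntensityTrace} returns \code{path} invisibly;
#'   \code{readIntensityTrace} returns an \linkS4class{IntensityTrace}.
#' @export
writeIntensityTrace <- function(trace, path) {
  stopifnot(is(trace, "IntensityTrace"))
  df <- data.frame(time_s = traceTimes(trace),
                   intensity = traceValues(trace),
                   units = traceUnits(trace))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIntensityTrace
#' @export
readIntensityTrace <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  intensityTrace(df$time_s, df$intensity, units = df$units[1L])
}

#' Read and write convoy parameters and gene geometry as JSON
#'
#' @param params a \linkS4class{ConvoyParams}.
#' @param geom a \linkS4class{GeneGeometry}.
#' @param path file path.
#' @return The writer returns \code{path} invisibly; the reader a list
#'   with elements \code{params} and \code{geom}.
#' @export
writeConvoyJson <- function(params, geom, path) {
  stopifnot(is(params, "ConvoyParams"), is(geom, "GeneGeometry"))
  obj <- list(params = list(n_pol = params@nPol, t_space_s = params@tSpace,
                            v_el_kb_min = params@vEl, t_proc_s = params@tProc),
              geometry = list(l_pre_nt = geom@lPre, l_ms2_nt = geom@lMs2,
                              l_post_nt = geom@lPost))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConvoyJson
#' @export
readConvoyJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = convoyParams(obj$params$n_pol, obj$params$t_space_s,
                             obj$params$v_el_kb_min, obj$params$t_proc_s),
       geom = geneGeometry(obj$geometry$l_pre_nt, obj$geometry$l_ms2_nt,
                           obj$geometry$l_post_nt))
}

#' Read and write per-cell counts as CSV
#'
#' Columns \code{cell_id,nascent,mature}.
#'
#' @param counts a \linkS4class{CellCounts}.
#' @param path file path.
#' @return The writer returns \code{path} invisibly; the reader a
#'   \linkS4class{CellCounts}.
#' @export
writeCellCounts <- function(counts, path) {
  stopifnot(is(counts, "CellCounts"))
  df <- data.frame(cell_id = seq_len(length(counts)),
                   nascent = nascentCounts(counts),
                   mature = matureCounts(counts))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCellCounts
#' @export
readCellCounts <- function(path) {
  df <- read.csv(path)
  cellCounts(df$nascent, df$mature)
}

#' Read and write a promoter model as JSON (rates in 1/s)
#'
#' @param model a \linkS4class{PromoterModel}.
#' @param path file path.
#' @return The writer returns \code{path} invisibly; the reader a
#'   \linkS4class{PromoterModel}.
#' @export
writePromoterModel <- function(model, path) {
  stopifnot(is(model, "PromoterModel"))
  sl <- c("kOn1", "kOff1", "kOff2", "f1", "kOn2a", "kOn2b", "kIni",
          "kRelease", "kDeg")
  obj <- setNames(lapply(sl, function(s) slot(model, s)), sl)
  obj$units <- "per_second"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePromoterModel
#' @export
readPromoterModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  promoterModel(kOn1 = o$kOn1, kOff1 = o$kOff1, kOff2 = o$kOff2, f1 = o$f1,
                kOn2a = o$kOn2a, kOn2b = o$kOn2b, kIni = o$kIni,
                kRelease = o$kRelease, kDeg = o$kDeg)
}

#' Write and read a 4D movie stack as multi-page float TIFF
#'
#' Pages are ordered t-major then z (page = (t-1)*nZ + z); the dimension
#' order and sizes are recorded in a JSON sidecar next to the TIFF.
#'
#' @param stack 4D array (t, z, y, x).
#' @param path TIFF file path; the sidecar is \code{<path>.json}.
#' @return The writer returns \code{path} invisibly; the reader the 4D
#'   array.
#' @export
writeMovieStack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 4L)
  d <- dim(stack)
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (f in seq_len(d[1L])) for (z in seq_len(d[2L])) {
    pages[[k]] <- stack[f, z, , ]
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(dim_order = "tzyx", n_t = d[1L], n_z = d[2L],
                            n_y = d[3L], n_x = d[4L]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMovieStack
#' @export
readMovieStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(meta$n_t, meta$n_z, meta$n_y, meta$n_x))
  k <- 1L
  for (f in seq_len(meta$n_t)) for (z in seq_len(meta$n_z)) {
    stack[f, z, , ] <- pages[[k]]
    k <- k + 1L
  }
  stack
}
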