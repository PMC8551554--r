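#' Frequency band definition
#'
#' A named frequency band with lower and upper edges in Hz. Band edges are
#' treated as half-open `[f_lo, f_hi)` conventions throughout: a shared edge
#' between adjacent bands is never counted twice.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param f_lo Lower edge in Hz (must be > 0).
#' @param f_hi Upper edge in Hz (must be > `f_lo`).
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    stop("band edges must satisfy 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = as.numeric(f_lo), f_hi = as.numeric(f_hi)),
            class = "band_definition")
}

#' Canonical analysis bands
#'
#' The four bands used throughout the pipeline: theta (4-8 Hz), alpha
#' (8-13 Hz), beta1 (13-20 Hz) and beta2 (20-30 Hz).
#'
#' @return Named list of [band_definition] objects.
#' @export
canonical_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta1 = band_definition("beta1", 13, 20),
       beta2 = band_definition("beta2", 20, 30))
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

## resolve a band given as band_definition, canonical name, or c(lo, hi)
as_band <- function(band) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) {
    bands <- canonical_bands()
    if (!band %in% names(bands))
      stop("unknown band name: ", band, " (canonical: ",
           paste(names(bands), collapse = ", "), ")")
    return(bands[[band]])
  }
  if (is.numeric(band) && length(band) == 2L)
    return(band_definition("custom", band[1], band[2]))
  stop("band must be a band_definition, a canonical band name, or c(f_lo, f_hi)")
}
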