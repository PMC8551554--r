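#' Instantaneous phase of a band-limited signal
#'
#' Zero-phase band-pass to the requested band, analytic signal via the
#' Hilbert transform (FFT construction), phase as the argument. One second is
#' trimmed from each end to discard filter and Hilbert edge effects.
#'
#' @param ts Numeric vector or matrix (rows = series).
#' @param band Band (definition, canonical name, or `c(f_lo, f_hi)`).
#' @param fs Sampling rate in Hz; must exceed `2 * f_hi`.
#' @param trim_s Seconds trimmed per side (default 1).
#' @return Phase series (vector or matrix), in radians, wrapped to `(-pi, pi]`.
#' @export
instantaneous_phase <- function(ts, band, fs, trim_s = 1) {
  band <- as_band(band)
  if (fs <= 2 * band$f_hi) stop("fs must exceed twice the band's upper edge")
  x <- if (is.matrix(ts)) ts else matrix(ts, 1)
  n <- ncol(x)
  tr <- round(trim_s * fs)
  if (n - 2 * tr < 2) stop("series too short after edge trimming")
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  xf <- t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
  ## analytic signal: one-sided spectrum doubling
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 } else
    h[2:((n + 1) / 2)] <- 2
  X <- stats::mvfft(t(xf))                       # n x series, fft per column
  a <- t(stats::mvfft(X * h, inverse = TRUE) / n)
  ph <- atan2(Im(a), Re(a))
  ph <- ph[, (tr + 1):(n - tr), drop = FALSE]
  if (is.matrix(ts)) ph else ph[1, ]
}

#' Phase-locking value
#'
#' `PLV = | mean( exp(i (phi_x - phi_y)) ) |`: modulus of the time-averaged
#' unit phasor of the phase difference. 1 = perfect locking (any constant
#' lag), 0 = no consistent phase relation.
#'
#' @param phase_x,phase_y Phase series in radians, equal length >= 100.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 100) stop("need at least 100 phase samples")
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Phase lag index
#'
#' `PLI = | mean( sign( sin(phi_x - phi_y) ) ) |`: consistency of the sign of
#' the phase lag. Insensitive to zero-lag (volume-conduction-like) coupling:
#' a strictly zero phase difference gives PLI = 0 while PLV = 1.
#'
#' @inheritParams plv
#' @return PLI in `[0, 1]`.
#' @export
pli <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 100) stop("need at least 100 phase samples")
  Mod(mean(sign(sin(phase_x - phase_y))))
}

#' Band-specific phase-synchronization connectivity matrix
#'
#' Computes PLV (default) or PLI between all region pairs of a
#' [source_activity] in one frequency band. Two epoch schemes: `"epochs"`
#' (default) computes the measure per non-overlapping epoch and averages
#' across epochs, mirroring the epoch structure of preprocessing;
#' `"whole"` uses the entire recording at once (the scheme under which the
#' simulator's closed-form expected PLV applies).
#'
#' @param src A [source_activity].
#' @param band Band (definition, canonical name, or `c(f_lo, f_hi)`).
#' @param measure `"plv"` or `"pli"`.
#' @param epoch_scheme `"epochs"` or `"whole"`.
#' @param epoch_s Epoch length in seconds for the `"epochs"` scheme (default 2).
#' @return Object of class `connectivity_matrix`: symmetric `values` in
#'   `[0, 1]` with unit diagonal (PLV) or zero diagonal (PLI), plus band and
#'   measure metadata.
#' @export
connectivity_matrix <- function(src, band, measure = c("plv", "pli"),
                                epoch_scheme = c("epochs", "whole"),
                                epoch_s = 2) {
  stopifnot(inherits(src, "source_activity"))
  measure <- match.arg(measure)
  epoch_scheme <- match.arg(epoch_scheme)
  band <- as_band(band)
  if (anyNA(src$data)) stop("NaN/NA in source activity")
  ph <- instantaneous_phase(src$data, band, src$fs)
  n <- nrow(ph); m <- ncol(ph)
  if (epoch_scheme == "whole") {
    vals <- phase_sync_block(ph, measure)
  } else {
    spe <- round(epoch_s * src$fs)
    n_ep <- floor(m / spe)
    if (n_ep < 1) stop("recording shorter than one epoch after trimming")
    vals <- matrix(0, n, n)
    for (e in seq_len(n_ep)) {
      blk <- ph[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
      vals <- vals + phase_sync_block(blk, measure)
    }
    vals <- vals / n_ep
  }
  diag(vals) <- if (measure == "plv") 1 else 0
  dimnames(vals) <- list(src$region_labels, src$region_labels)
  structure(list(values = vals, band = band, measure = measure,
                 epoch_scheme = epoch_scheme),
            class = "connectivity_matrix")
}

## all-pairs synchrony on one phase block; PLV via one complex cross-product
phase_sync_block <- function(ph, measure) {
  if (measure == "plv") {
    z <- exp(1i * ph)
    v <- Mod(z %*% Conj(t(z))) / ncol(ph)
  } else {
    n <- nrow(ph)
    v <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      s <- sign(sin(ph[i, ] - t(ph[(i + 1):n, , drop = FALSE])))
      v[i, (i + 1):n] <- abs(colMeans(s))
      v[(i + 1):n, i] <- v[i, (i + 1):n]
    }
  }
  v <- (v + t(v)) / 2           # enforce exact symmetry
  pmin(pmax(v, 0), 1)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, %s, band %s (%g-%g Hz), scheme %s\n",
              nrow(x$values), ncol(x$values), toupper(x$measure),
              x$band$name, x$band$f_lo, x$band$f_hi, x$epoch_scheme))
  invisible(x)
}
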