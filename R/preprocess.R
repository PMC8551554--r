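#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase, effective 8th order magnitude response).
#'
#' @param rec A [recording].
#' @param f_lo,f_hi Band edges in Hz; must satisfy `f_lo < f_hi < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered [recording].
#' @export
bandpass_filter <- function(rec, f_lo = 1, f_hi = 30, order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (!(f_lo < f_hi)) stop("band edges must satisfy f_lo < f_hi")
  if (f_hi >= rec$fs / 2) stop("f_hi must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(f_lo, f_hi) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Split a recording into non-overlapping epochs
#'
#' Cuts the recording into contiguous, non-overlapping epochs of `length_s`
#' seconds; a trailing remainder shorter than one epoch is discarded.
#'
#' @param rec A [recording].
#' @param length_s Epoch length in seconds (default 2).
#' @return An object of class `eeg_epochs`: array `data`
#'   (epochs x channels x samples), `fs`, `epoch_length`, `channel_labels`
#'   and logical `kept_mask` (all `TRUE` initially).
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "recording"))
  if (length_s <= 0) stop("epoch length must be positive")
  spe <- round(length_s * rec$fs)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1) stop("recording shorter than one epoch")
  a <- array(NA_real_, c(n_ep, nrow(rec$data), spe))
  for (e in seq_len(n_ep))
    a[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
  structure(list(data = a, fs = rec$fs, epoch_length = length_s,
                 channel_labels = rec$channel_labels,
                 kept_mask = rep(TRUE, n_ep), meta = rec$meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s each), %d kept\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$epoch_length,
              sum(x$kept_mask)))
  invisible(x)
}

#' Reject artifact-contaminated epochs
#'
#' Drops every epoch whose peak-to-peak amplitude on any channel exceeds
#' `peak_to_peak_limit` (microvolts). Surviving epochs are untouched.
#'
#' @param ep An [epoch_recording] result.
#' @param peak_to_peak_limit Rejection threshold in microvolts (default 150).
#' @return `eeg_epochs` containing only the surviving epochs; `kept_mask`
#'   records the decision per original epoch.
#' @export
reject_artifact_epochs <- function(ep, peak_to_peak_limit = 150) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (peak_to_peak_limit <= 0) stop("no data survives: peak-to-peak limit must be > 0")
  p2p <- apply(ep$data, 1, function(e) max(apply(e, 1, function(ch) diff(range(ch)))))
  keep <- p2p <= peak_to_peak_limit
  if (!any(keep)) stop("no data survives artifact rejection at limit ",
                       peak_to_peak_limit, " microvolts")
  out <- ep
  out$data <- ep$data[keep, , , drop = FALSE]
  out$kept_mask <- keep
  out
}

#' Concatenate surviving epochs back into a continuous recording
#'
#' Used before spectral estimation: the Welch window (4 s) is longer than the
#' analysis epochs (2 s), so surviving epochs are re-concatenated first.
#'
#' @param ep An `eeg_epochs` object.
#' @return A [recording].
#' @export
epochs_to_recording <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$data)
  out <- matrix(aperm(ep$data, c(2, 3, 1)), d[2], d[1] * d[3])
  recording(out, ep$fs, ep$channel_labels, meta = ep$meta)
}

#' Interpolate bad channels
#'
#' Replaces each channel listed in `bad_channels` with the inverse-distance
#' weighted average of its `k` nearest good channels. Requires sensor
#' positions on the recording.
#'
#' @param rec A [recording] with non-empty `bad_channels` and `positions`.
#' @param k Number of nearest good channels to average (default 4).
#' @return [recording] with bad channels replaced and `bad_channels` cleared.
#' @export
interpolate_bad_channels <- function(rec, k = 4) {
  stopifnot(inherits(rec, "recording"))
  if (!length(rec$bad_channels)) stop("bad_channels is empty; nothing to interpolate")
  if (is.null(rec$positions)) stop("sensor positions required for interpolation")
  bad <- match(rec$bad_channels, rec$channel_labels)
  good <- setdiff(seq_along(rec$channel_labels), bad)
  if (!length(good)) stop("all channels are bad; cannot interpolate")
  k <- min(k, length(good))
  out <- rec
  for (b in bad) {
    d <- sqrt(colSums((t(rec$positions[good, , drop = FALSE]) - rec$positions[b, ])^2))
    nn <- good[order(d)[seq_len(k)]]
    w <- 1 / pmax(d[order(d)[seq_len(k)]], 1e-9)
    out$data[b, ] <- as.numeric(w %*% rec$data[nn, , drop = FALSE] / sum(w))
  }
  out$bad_channels <- character()
  out
}

#' Full sensor-space preprocessing
#'
#' Convenience wrapper: optional bad-channel interpolation, band-pass
#' filtering, epoching and amplitude-based artifact rejection.
#'
#' @param rec A [recording].
#' @param f_lo,f_hi Band-pass edges in Hz (default 1-30).
#' @param epoch_s Epoch length in seconds (default 2).
#' @param p2p_limit Peak-to-peak rejection limit in microvolts (default 150).
#' @return `eeg_epochs` of clean data.
#' @export
preprocess_recording <- function(rec, f_lo = 1, f_hi = 30, epoch_s = 2,
                                 p2p_limit = 150) {
  if (length(rec$bad_channels) && !is.null(rec$positions))
    rec <- interpolate_bad_channels(rec)
  rec <- bandpass_filter(rec, f_lo, f_hi)
  ep <- epoch_recording(rec, epoch_s)
  reject_artifact_epochs(ep, p2p_limit)
}
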