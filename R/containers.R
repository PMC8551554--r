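#' Sensor-space EEG recording
#'
#' Container for a multichannel EEG recording: a channels-by-samples numeric
#' matrix with sampling rate, channel labels, an optional set of bad-channel
#' labels and optional 3-D sensor positions (needed for bad-channel
#' interpolation).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @param bad_channels Character vector of labels flagged as bad.
#' @param positions Optional channels x 3 matrix of sensor positions.
#' @param meta Optional list of free-form metadata (group, condition, seed...).
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, bad_channels = character(),
                      positions = NULL, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%03d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must match row count of data")
  if (!all(bad_channels %in% channel_labels))
    stop("bad_channels must be a subset of channel_labels")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3L)
      stop("positions must be a channels x 3 matrix")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 bad_channels = bad_channels, positions = positions, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$bad_channels)) cat(sprintf(", %d bad", length(x$bad_channels)))
  cat("\n")
  invisible(x)
}

#' Region-level source activity
#'
#' Regions-by-samples matrix of reconstructed (or simulated) cortical time
#' series after parcellation.
#'
#' @param data Numeric matrix, regions x samples.
#' @param fs Sampling rate in Hz.
#' @param region_labels Character vector of region names.
#' @return An object of class `source_activity`.
#' @export
source_activity <- function(data, fs, region_labels = NULL) {
  data <- as.matrix(data)
  if (is.null(region_labels)) region_labels <- sprintf("region%02d", seq_len(nrow(data)))
  if (length(region_labels) != nrow(data))
    stop("region_labels length must match row count")
  rownames(data) <- region_labels
  structure(list(data = data, fs = fs, region_labels = region_labels),
            class = "source_activity")
}

#' @export
print.source_activity <- function(x, ...) {
  cat(sprintf("<source_activity> %d regions x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Desikan-Killiany region labels
#'
#' The canonical 68-region cortical parcellation label list (34 regions per
#' hemisphere, `lh_`/`rh_` prefixed), in the fixed ordering used by all
#' pipeline outputs.
#'
#' @return Character vector of length 68.
#' @export
dk_region_labels <- function() {
  path <- system.file("extdata", "desikan_killiany_68.txt",
                      package = "eegsourcenet", mustWork = TRUE)
  readLines(path)
}
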