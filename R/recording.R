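#' Continuous multichannel EEG recording
#'
#' A `Recording` holds a channels-by-samples matrix of EEG amplitudes in
#' microvolts together with its sampling rate and channel names. It is the
#' container every stage of the pipeline consumes and produces.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per row of `data`.
#' @param meta named list of free-form provenance (condition label, seed, ...).
#'
#' @return An object of class `Recording`.
#' @export
new_recording <- function(data, fs, channel_names, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("Recording data must be numeric")
  if (nrow(data) != length(channel_names))
    stop("Recording has ", nrow(data), " rows but ", length(channel_names),
         " channel names")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (!all(is.finite(data))) stop("Recording data contains non-finite values")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 meta = meta),
            class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!is.null(x$meta$condition))
    cat("  condition:", x$meta$condition, "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `Recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Extract a time interval from a recording
#'
#' @param recording a `Recording`.
#' @param t0,t1 interval bounds in seconds; half-open `[t0, t1)` on the
#'   sample grid.
#' @return a `Recording` covering the requested span.
#' @export
crop_recording <- function(recording, t0, t1) {
  i0 <- round(t0 * recording$fs) + 1L
  i1 <- round(t1 * recording$fs)
  if (i0 < 1L || i1 > ncol(recording$data) || i0 > i1)
    stop("crop interval [", t0, ", ", t1, ") outside recording")
  new_recording(recording$data[, i0:i1, drop = FALSE], recording$fs,
                recording$channel_names, recording$meta)
}

#' Set of fixed-length epochs cut from a recording
#'
#' Epochs are stored as an array `epochs x channels x samples`; `tmin` gives
#' the time of the first sample relative to the lock point. The sample grid is
#' half-open `[tmin, tmax)`: an epoch from -0.2 to 1.0 s at 500 Hz has exactly
#' 600 samples.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param tmin time of the first sample relative to the lock point (s).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel names.
#' @param metadata data.frame with one row per epoch (columns such as
#'   `stimulus`, `condition`, `onset`, `retained`).
#'
#' @return An object of class `EpochSet`.
#' @export
new_epochset <- function(data, tmin, fs, channel_names, metadata) {
  if (length(dim(data)) != 3L) stop("EpochSet data must be a 3-d array")
  if (dim(data)[1] != nrow(metadata))
    stop("metadata has ", nrow(metadata), " rows for ", dim(data)[1], " epochs")
  if (dim(data)[2] != length(channel_names))
    stop("channel dimension does not match channel_names")
  structure(list(data = data, tmin = tmin, fs = fs,
                 channel_names = channel_names, metadata = metadata),
            class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples (%g Hz, tmin=%g s)\n",
              d[1], d[2], d[3], x$fs, x$tmin))
  if ("stimulus" %in% names(x$metadata))
    print(table(x$metadata$stimulus, x$metadata$condition))
  invisible(x)
}

#' Number of epochs in an EpochSet
#' @param epochs an `EpochSet`.
#' @return integer epoch count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Time axis of an EpochSet
#' @param epochs an `EpochSet`.
#' @return vector of sample times in seconds relative to the lock point.
#' @export
epoch_times <- function(epochs) {
  x <- epochs
  x$tmin + (seq_len(dim(x$data)[3]) - 1L) / x$fs
}

#' Subset an EpochSet by epoch index
#' @param epochs an `EpochSet`.
#' @param idx integer or logical index over epochs.
#' @return an `EpochSet` with the selected epochs.
#' @export
subset_epochs <- function(epochs, idx) {
  new_epochset(epochs$data[idx, , , drop = FALSE], epochs$tmin, epochs$fs,
               epochs$channel_names, epochs$metadata[idx, , drop = FALSE])
}
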