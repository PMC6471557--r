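#' Cut stimulus-locked epochs from a continuous recording
#'
#' Epochs span the half-open window `[tmin, tmax)` on the sample grid, so a
#' -0.2 to 1.0 s epoch at 500 Hz has exactly 600 samples. Events whose
#' window falls partly outside the recording are dropped (not an error); the
#' number dropped is attached as attribute `n_dropped`.
#'
#' @param recording a `Recording`.
#' @param events an `EventStream`.
#' @param tmin,tmax epoch window relative to stimulus onset (s), `tmin < tmax`.
#' @param lock which stimuli to epoch: `"all"`, `"target"` or `"standard"`.
#' @return an `EpochSet` with metadata columns `stimulus`, `condition`,
#'   `onset`, `retained`.
#' @export
extract_epochs <- function(recording, events, tmin = -0.2, tmax = 1.0,
                           lock = c("all", "target", "standard")) {
  lock <- match.arg(lock)
  stopifnot(tmin < tmax)
  if (lock != "all") events <- events[events$stimulus == lock, , drop = FALSE]
  fs <- recording$fs
  n <- ncol(recording$data)
  n_samp <- round((tmax - tmin) * fs)
  i_on <- round(events$onset * fs)
  i_first <- i_on + round(tmin * fs) + 1L
  ok <- i_first >= 1L & (i_first + n_samp - 1L) <= n
  n_dropped <- sum(!ok)
  keep <- which(ok)
  arr <- array(0, dim = c(length(keep), nrow(recording$data), n_samp))
  for (j in seq_along(keep)) {
    idx <- i_first[keep[j]]:(i_first[keep[j]] + n_samp - 1L)
    arr[j, , ] <- recording$data[, idx]
  }
  md <- data.frame(stimulus = events$stimulus[keep],
                   condition = events$condition[keep],
                   onset = events$onset[keep],
                   retained = TRUE)
  out <- new_epochset(arr, tmin, fs, recording$channel_names, md)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -200 to 0 ms before stimulus onset).
#'
#' @param epochs an `EpochSet`.
#' @param window numeric length-2, baseline window `[t0, t1)` in s.
#' @return the corrected `EpochSet`.
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  tt <- epoch_times(epochs)
  sel <- tt >= window[1] & tt < window[2]
  if (!any(sel)) stop("baseline window [", window[1], ", ", window[2],
                      ") is outside the epoch span")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over 3rd dim
  epochs
}

#' Downsample epochs by integer decimation
#'
#' Keeps every `fs / target_fs`-th sample starting at the first. The signal
#' must already be band-limited below `target_fs / 2` (in the pipeline, by
#' the prior 1-15 Hz filter).
#'
#' @param epochs an `EpochSet`.
#' @param target_fs target sampling rate (Hz); must divide `fs`.
#' @return the decimated `EpochSet`.
#' @export
downsample_epochs <- function(epochs, target_fs = 50) {
  factor <- epochs$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs = ", epochs$fs, " is not an integer multiple of target_fs = ",
         target_fs)
  factor <- as.integer(round(factor))
  keep <- seq(1L, dim(epochs$data)[3], by = factor)
  new_epochset(epochs$data[, , keep, drop = FALSE], epochs$tmin, target_fs,
               epochs$channel_names, epochs$metadata)
}

#' Segment a continuous recording into fixed non-overlapping epochs
#'
#' Yields `floor(duration / window_s)` contiguous 0-based epochs; the
#' trailing remainder is discarded. The condition label is inherited from
#' the recording metadata.
#'
#' @param recording a `Recording`.
#' @param window_s epoch length (s).
#' @param skip_s lead-in to skip (s), e.g. the calibration segment.
#' @return an `EpochSet` (tmin = 0, stimulus = `NA`).
#' @export
segment_continuous <- function(recording, window_s = 2.0, skip_s = 0) {
  fs <- recording$fs
  i0 <- round(skip_s * fs)
  n <- ncol(recording$data) - i0
  len <- round(window_s * fs)
  if (n < len) stop("recording shorter than one window")
  k <- floor(n / len)
  arr <- array(0, dim = c(k, nrow(recording$data), len))
  for (j in seq_len(k))
    arr[j, , ] <- recording$data[, (i0 + (j - 1L) * len + 1L):(i0 + j * len)]
  md <- data.frame(stimulus = NA_character_,
                   condition = recording$meta$condition %||% NA_character_,
                   onset = skip_s + (seq_len(k) - 1L) * window_s,
                   retained = TRUE)
  new_epochset(arr, 0, fs, recording$channel_names, md)
}
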