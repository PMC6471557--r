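#' Parameters of the raw-data cleaning criteria
#'
#' Defaults follow the standard clean-raw settings used with ASR: flatline
#' criterion 5 s, QC high-pass transition band 0.25-0.75 Hz, channel
#' correlation 0.85, line-noise z-score 4, burst criterion k = 70, window
#' criterion 0.10.
#'
#' @param flatline_s seconds of constant signal after which a channel is
#'   removed.
#' @param highpass_band transition band (Hz) of the QC high-pass filter.
#' @param channel_correlation minimum correlation between a channel and its
#'   prediction from the remaining channels (per 1-s window).
#' @param line_noise_z line-noise z-score beyond which a channel is flagged.
#' @param burst_k ASR burst criterion (passed to [asr_calibrate()]).
#' @param window_bad_fraction fraction of flagged channels above which a
#'   window is dropped.
#' @return a validated list of class `CleanRawParams`.
#' @export
clean_raw_params <- function(flatline_s = 5, highpass_band = c(0.25, 0.75),
                             channel_correlation = 0.85, line_noise_z = 4,
                             burst_k = 70, window_bad_fraction = 0.10) {
  stopifnot(flatline_s > 0,
            length(highpass_band) == 2, highpass_band[1] < highpass_band[2],
            channel_correlation >= 0, channel_correlation <= 1,
            line_noise_z > 0, burst_k > 0,
            window_bad_fraction >= 0, window_bad_fraction <= 1)
  structure(list(flatline_s = flatline_s, highpass_band = highpass_band,
                 channel_correlation = channel_correlation,
                 line_noise_z = line_noise_z, burst_k = burst_k,
                 window_bad_fraction = window_bad_fraction),
            class = "CleanRawParams")
}

#' Remove channels with long constant runs
#'
#' @param recording a `Recording`.
#' @param flatline_s run length (s) of near-constant signal after which a
#'   channel is removed.
#' @return list with `recording` (flat channels dropped) and `removed`
#'   (channel names).
#' @export
remove_flatlines <- function(recording, flatline_s = 5) {
  x <- recording$data
  max_run <- round(flatline_s * recording$fs)
  flat <- vapply(seq_len(nrow(x)), function(i) {
    r <- rle(abs(diff(x[i, ])) < 1e-12)
    any(r$lengths[r$values] + 1L >= max_run)
  }, logical(1))
  if (all(flat)) stop("all channels are flat; nothing to analyse")
  removed <- recording$channel_names[flat]
  rec <- if (any(flat))
    new_recording(x[!flat, , drop = FALSE], recording$fs,
                  recording$channel_names[!flat], recording$meta)
  else recording
  list(recording = rec, removed = removed)
}

#' QC high-pass filter with the clean-raw transition band
#'
#' Hamming-windowed sinc high-pass whose cutoff sits at the centre of
#' `band`; the order is chosen so the transition width matches the band.
#'
#' @param recording a `Recording`.
#' @param band transition band (Hz).
#' @return the filtered `Recording`.
#' @export
qc_highpass <- function(recording, band = c(0.25, 0.75)) {
  width <- band[2] - band[1]
  order <- ceiling(3.3 * recording$fs / width)
  order <- order + order %% 2
  apply_filter(recording, design_fir(c(mean(band), NA), order, recording$fs))
}

#' Flag bad 1-s windows by channel-prediction correlation and line noise
#'
#' Per 1-s window and channel: the channel is flagged if its correlation
#' with a leave-one-out least-squares prediction from the other channels
#' falls below `channel_correlation`, or if its line-noise score (SD of the
#' high-frequency residual over SD of the smoothed signal, z-scored across
#' channels) exceeds `line_noise_z`. A window is dropped when the flagged
#' fraction exceeds `window_bad_fraction`. The recording should be
#' high-passed with [qc_highpass()] first.
#'
#' @param recording a `Recording`.
#' @param params a [clean_raw_params()].
#' @return list with `retained` (logical per window), `flagged` (channels x
#'   windows logical matrix), `window_s` (1).
#' @export
reject_bad_windows <- function(recording, params = clean_raw_params()) {
  x <- recording$data
  fs <- recording$fs
  n_ch <- nrow(x)
  win <- round(fs)
  n_win <- floor(ncol(x) / win)
  flagged <- matrix(FALSE, n_ch, n_win)
  noisiness <- matrix(0, n_ch, n_win)
  # smoothing kernel separating the line-noise band from EEG
  sm_len <- max(round(fs / 50), 3)
  for (w in seq_len(n_win)) {
    seg <- x[, ((w - 1L) * win + 1L):(w * win), drop = FALSE]
    smoothed <- t(apply(seg, 1, function(v)
      stats::filter(v, rep(1 / sm_len, sm_len), sides = 2)))
    ok <- !is.na(smoothed[1, ])
    resid_sd <- apply(seg[, ok, drop = FALSE] - smoothed[, ok, drop = FALSE],
                      1, stats::sd)
    smooth_sd <- pmax(apply(smoothed[, ok, drop = FALSE], 1, stats::sd), 1e-12)
    noisiness[, w] <- resid_sd / smooth_sd
    for (c_i in seq_len(n_ch)) {
      others <- t(seg[-c_i, , drop = FALSE])
      fit <- stats::lm.fit(cbind(1, others), seg[c_i, ])
      pred <- seg[c_i, ] - fit$residuals
      r <- suppressWarnings(stats::cor(seg[c_i, ], pred))
      if (is.na(r)) r <- 0
      flagged[c_i, w] <- r < params$channel_correlation
    }
  }
  # line-noise z-score against the recording-wide noisiness distribution
  z <- (noisiness - stats::median(noisiness)) /
    max(stats::mad(noisiness), 1e-12)
  flagged <- flagged | z > params$line_noise_z
  retained <- colMeans(flagged) <= params$window_bad_fraction
  list(retained = retained, flagged = flagged, window_s = 1)
}
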