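#' Gaussian P300 kernel
#'
#' The target-evoked P300 is modeled as a Gaussian-windowed positive
#' deflection: peak value `amplitude` at `latency`, standard deviation
#' `width`, support truncated at `latency + 3 * width`. The kernel starts at
#' the stimulus onset (t = 0).
#'
#' @param amplitude peak amplitude (uV).
#' @param latency peak latency after stimulus onset (s).
#' @param width Gaussian SD (s).
#' @param fs sampling rate (Hz).
#' @return numeric vector of samples (uV), first sample at t = 0.
#' @export
erp_kernel <- function(amplitude, latency = 0.45, width = 0.06, fs = 500) {
  stopifnot(width > 0, latency >= 0, fs > 0)
  t <- seq(0, latency + 3 * width, by = 1 / fs)
  k <- amplitude * exp(-(t - latency)^2 / (2 * width^2))
  k[abs(t - latency) > 3 * width] <- 0
  k
}

# Fixed scalp geometry of the six-site dry montage (schematic 10-20 coords)
# used for the spatially-smooth background sources and artifact topographies.
channel_coords <- function(channel_names) {
  coords <- rbind(Fz = c(0, 0.7), Cz = c(0, 0.2), Pz = c(0, -0.35),
                  Oz = c(0, -0.8), P3 = c(-0.4, -0.35), P4 = c(0.4, -0.35))
  missing <- setdiff(channel_names, rownames(coords))
  if (length(missing)) {
    # unknown montage sites get arbitrary distinct positions on a circle
    ang <- seq_along(missing) * 2.39996
    coords <- rbind(coords, matrix(c(cos(ang), sin(ang)), ncol = 2,
                                   dimnames = list(missing, NULL)))
  }
  coords[channel_names, , drop = FALSE]
}

# Spatial mixing of K diffuse cortical sources into the montage: Gaussian
# falloff from four fixed loci, so neighbouring channels share signal the way
# volume conduction makes them in real EEG.
background_mixing <- function(channel_names) {
  pos <- channel_coords(channel_names)
  src <- rbind(c(0, 0.5), c(0, -0.1), c(-0.3, -0.5), c(0.3, -0.5))
  d2 <- outer(seq_len(nrow(pos)), seq_len(nrow(src)),
              function(i, j) rowSums((pos[i, , drop = FALSE] - src[j, , drop = FALSE])^2))
  M <- exp(-d2 / (2 * 0.45^2))
  rownames(M) <- channel_names
  M
}

# Frontal-dominant blink topography (ocular dipole seen from above).
blink_weights <- function(channel_names) {
  pos <- channel_coords(channel_names)
  w <- exp(-((pos[, 2] - 1.1)^2 + pos[, 1]^2) / (2 * 0.55^2))
  w / max(w)
}

# One 1/f^a amplitude-spectrum noise trace, unit RMS, via spectral shaping
# of white Gaussian noise; the spectrum is flattened below 1 Hz so the trace
# stays drift-bounded.
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white / stats::sd(white))
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index
  shape <- 1 / pmax(f, 1)^exponent
  x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Generate a continuous oddball EEG recording for one load condition
#'
#' Builds the clean signal as (i) a spatially-correlated 1/f background
#' scaled to `noise_rms` per channel, (ii) fixed-amplitude band oscillators
#' (delta/theta/alpha/beta at 2.5/6/10/14 Hz) with a fresh uniform random
#' phase every 1-s block, amplitudes from `band_power_map[, , condition]`,
#' and (iii) the Gaussian P300 kernel added at every target onset with a
#' parietal-dominant topography (Pz 1.0, P3/P4 0.8, Oz 0.6, Cz 0.5, Fz 0.3)
#' scaled by `p300_amplitude[condition]`. Blink and burst artifacts are then
#' injected outside the calibration lead-in.
#'
#' @param config a [sim_config()].
#' @param events an `EventStream` from [generate_events()]; may be `NULL`
#'   for a stimulus-free recording.
#' @param condition `"low"` or `"high"`.
#' @param seed RNG seed; defaults to a condition-specific offset of
#'   `config$seed`.
#' @return list with elements `recording` (artifacts injected), `clean`
#'   (pre-injection signal), and `artifacts` (the `ArtifactLog`).
#' @export
generate_recording <- function(config, events = NULL,
                               condition = c("low", "high"), seed = NULL) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  if (is.null(seed))
    seed <- config$seed + ifelse(condition == "low", 101L, 202L)
  set.seed(seed)
  fs <- config$fs
  ch <- config$channel_names
  n_ch <- length(ch)
  n <- round(config$duration_per_condition * fs)
  t <- (seq_len(n) - 1L) / fs

  # spatially-correlated background: diffuse sources + 20% sensor noise
  M <- background_mixing(ch)
  sources <- vapply(seq_len(ncol(M)), function(k) pink_noise(n, config$noise_exponent),
                    numeric(n))
  x <- M %*% t(sources)
  sensor_frac <- 0.2
  for (c_i in seq_len(n_ch)) {
    common_rms <- sqrt(mean(x[c_i, ]^2))
    if (common_rms > 0) x[c_i, ] <- x[c_i, ] / common_rms
    x[c_i, ] <- x[c_i, ] + sensor_frac * pink_noise(n, config$noise_exponent)
    x[c_i, ] <- x[c_i, ] * config$noise_rms / sqrt(mean(x[c_i, ]^2))
  }

  # band oscillators: common phase across channels, redrawn per 1-s block
  freqs <- band_center_freqs()
  bands <- rownames(config$band_power_map)
  n_blocks <- ceiling(config$duration_per_condition)
  block <- pmin(floor(t) + 1L, n_blocks)
  amp <- t(config$band_power_map[bands, ch, condition])  # ch x band
  waves <- matrix(0, length(bands), n)
  for (b_i in seq_along(bands)) {
    phase <- stats::runif(n_blocks, 0, 2 * pi)
    waves[b_i, ] <- sin(2 * pi * freqs[bands[b_i]] * t + phase[block])
  }
  x <- x + amp %*% waves

  # target-locked P300, parietal-dominant, larger under low load
  if (!is.null(events) && nrow(events) > 0) {
    topo <- c(Fz = 0.3, Cz = 0.5, Pz = 1.0, Oz = 0.6, P3 = 0.8, P4 = 0.8)
    w <- ifelse(ch %in% names(topo), topo[ch], 0.1)
    kern <- erp_kernel(config$p300_amplitude[[condition]],
                       config$p300_latency, config$p300_width, fs)
    for (on in events$onset[events$stimulus == "target"]) {
      i0 <- round(on * fs) + 1L
      idx <- i0:min(i0 + length(kern) - 1L, n)
      x[, idx] <- x[, idx] + outer(w, kern[seq_along(idx)])
    }
  }

  clean <- new_recording(x, fs, ch,
                         meta = list(condition = condition, seed = seed))
  out <- inject_artifacts(clean, config)
  list(recording = out$recording, clean = clean, artifacts = out$artifacts)
}

#' Inject blink and motion-burst artifacts into a recording
#'
#' Blinks are low-frequency biphasic pulses with a frontal-dominant
#' topography (Fz largest); bursts are broadband high-amplitude noise
#' segments on a random channel subset. Counts are Poisson at
#' `artifact_rates` per minute; every injected interval is placed after the
#' calibration lead-in and logged.
#'
#' @param recording a clean `Recording`.
#' @param config a [sim_config()] (rates, amplitudes, calibration lead-in).
#' @return list with `recording` (artifacts added) and `artifacts`, a
#'   data.frame of class `ArtifactLog` with columns `onset`, `duration`,
#'   `kind`, `channels`, `peak_uv`.
#' @export
inject_artifacts <- function(recording, config) {
  fs <- recording$fs
  x <- recording$data
  n <- ncol(x)
  ch <- recording$channel_names
  minutes <- (n / fs - config$calibration_duration) / 60
  log <- list()
  if (minutes > 0) {
    for (kind in c("blink", "burst")) {
      rate <- config$artifact_rates[[kind]]
      if (is.null(rate) || rate <= 0) next
      k <- stats::rpois(1, rate * minutes)
      if (k == 0) next
      dur <- switch(kind, blink = stats::runif(k, 0.25, 0.4),
                    burst = stats::runif(k, 0.3, 0.6))
      onset <- stats::runif(k, config$calibration_duration,
                            n / fs - max(dur) - 0.1)
      for (j in seq_len(k)) {
        i0 <- round(onset[j] * fs) + 1L
        len <- round(dur[j] * fs)
        idx <- i0:(i0 + len - 1L)
        tt <- seq(0, 1, length.out = len)
        if (kind == "blink") {
          # biphasic: dominant positive lobe then small negative rebound
          pulse <- config$blink_amplitude *
            (exp(-(tt - 0.35)^2 / (2 * 0.12^2)) -
             0.3 * exp(-(tt - 0.75)^2 / (2 * 0.15^2)))
          w <- blink_weights(ch)
          x[, idx] <- x[, idx] + outer(w, pulse)
          affected <- ch
          peak <- config$blink_amplitude
        } else {
          n_aff <- sample(2:length(ch), 1)
          aff <- sort(sample(seq_along(ch), n_aff))
          taper <- sin(pi * tt)^2
          seg <- matrix(stats::rnorm(n_aff * len), n_aff, len) *
            config$burst_amplitude
          x[aff, idx] <- x[aff, idx] + seg * rep(taper, each = n_aff)
          affected <- ch[aff]
          peak <- max(abs(seg))
        }
        log[[length(log) + 1L]] <-
          data.frame(onset = onset[j], duration = dur[j], kind = kind,
                     channels = paste(affected, collapse = ","),
                     peak_uv = peak)
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(onset = numeric(), duration = numeric(), kind = character(),
               channels = character(), peak_uv = numeric())
  log <- log[order(log$onset), , drop = FALSE]
  rownames(log) <- NULL
  class(log) <- c("ArtifactLog", "data.frame")
  list(recording = new_recording(x, fs, ch, recording$meta), artifacts = log)
}

#' Simulate a full two-condition oddball session
#'
#' Convenience wrapper generating, for each load condition, its event stream
#' and recording. At the defaults this yields 320 stimuli (80 targets)
#' across the two conditions, ~500 s of 6-channel 500 Hz EEG each, with a
#' 30-s artifact-free calibration lead-in per recording.
#'
#' @param config a [sim_config()].
#' @return named list (`low`, `high`) of lists with `recording`, `clean`,
#'   `events`, `artifacts`.
#' @export
simulate_session <- function(config = sim_config()) {
  out <- lapply(c(low = "low", high = "high"), function(cond) {
    events <- generate_events(config, cond)
    rec <- generate_recording(config, events, cond)
    list(recording = rec$recording, clean = rec$clean, events = events,
         artifacts = rec$artifacts)
  })
  out
}
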