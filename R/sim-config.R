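#' Default per-band oscillator amplitudes
#'
#' Amplitudes (microvolts) of the fixed-amplitude band oscillators per
#' condition, channel and band. The defaults encode the two planted load
#' effects the analysis is built to recover: parietal alpha (Pz) and occipital
#' theta (Oz) are twice as large under low load as under high load, mirroring
#' the lower-arousal signature of passive monitoring; all other entries are
#' load-independent resting-level amplitudes.
#'
#' @param channel_names channel names the map covers.
#' @return numeric array `band x channel x condition` of amplitudes in uV.
#' @export
default_band_power_map <- function(channel_names = c("Fz", "Cz", "Pz", "Oz", "P3", "P4")) {
  bands <- c("delta", "theta", "alpha", "beta")
  m <- array(0, dim = c(length(bands), length(channel_names), 2L),
             dimnames = list(bands, channel_names, c("low", "high")))
  m["delta", , ] <- 1.5
  m["theta", , ] <- 1.5
  m["alpha", , ] <- 2.0
  m["beta", , ] <- 1.0
  if ("Pz" %in% channel_names) {
    m["alpha", "Pz", "low"] <- 4.0
    m["alpha", "Pz", "high"] <- 2.0
  }
  if ("Oz" %in% channel_names) {
    m["theta", "Oz", "low"] <- 3.0
    m["theta", "Oz", "high"] <- 1.5
  }
  m
}

#' Center frequencies of the simulated band oscillators
#' @return named numeric vector (Hz).
#' @export
band_center_freqs <- function() {
  c(delta = 2.5, theta = 6, alpha = 10, beta = 14)
}

#' Simulation configuration for synthetic oddball flight EEG
#'
#' Bundles every knob of the generator: montage and sampling rate, oddball
#' structure (stimulus count, target fraction, inter-trial interval and
#' jitter), the load-dependent P300 and band-power effects, the 1/f
#' background, artifact rates, and the artifact-free calibration lead-in.
#' `n_stimuli` counts stimuli over a full two-condition session; each
#' condition's stream carries half of them.
#'
#' @param fs sampling rate (Hz).
#' @param channel_names ordered montage; parietal sites carry the P300.
#' @param duration_per_condition seconds of recording per load condition.
#' @param n_stimuli total stimulus count over the two-condition session.
#' @param target_fraction proportion of targets (exact split, not Bernoulli).
#' @param iti_mean mean inter-trial interval (ms).
#' @param iti_jitter half-range of the uniform ITI jitter (ms).
#' @param band_power_map array `band x channel x condition` of oscillator
#'   amplitudes (uV); see [default_band_power_map()].
#' @param p300_amplitude named vector, peak target-ERP amplitude (uV) at the
#'   strongest parietal site per condition.
#' @param p300_latency P300 peak latency (s), inside the 0.35-0.6 s window.
#' @param p300_width Gaussian width (SD, s) of the P300 deflection.
#' @param noise_exponent slope of the 1/f^a background amplitude spectrum.
#' @param noise_rms per-channel RMS of the background (uV).
#' @param artifact_rates named vector, events per minute for `blink` and
#'   `burst` artifacts.
#' @param blink_amplitude peak blink amplitude at Fz (uV).
#' @param burst_amplitude RMS amplitude of broadband bursts (uV).
#' @param calibration_duration artifact-free lead-in used for ASR
#'   calibration (s).
#' @param seed RNG seed making the whole simulation reproducible.
#'
#' @return a validated list of class `SimulationConfig`.
#' @export
sim_config <- function(fs = 500,
                       channel_names = c("Fz", "Cz", "Pz", "Oz", "P3", "P4"),
                       duration_per_condition = 500,
                       n_stimuli = 320,
                       target_fraction = 0.25,
                       iti_mean = 2000,
                       iti_jitter = 1000,
                       band_power_map = default_band_power_map(channel_names),
                       p300_amplitude = c(low = 8, high = 4),
                       p300_latency = 0.45,
                       p300_width = 0.06,
                       noise_exponent = 1,
                       noise_rms = 10,
                       artifact_rates = c(blink = 6, burst = 2),
                       blink_amplitude = 150,
                       burst_amplitude = 100,
                       calibration_duration = 30,
                       seed = 1L) {
  cfg <- list(fs = fs, channel_names = channel_names,
              duration_per_condition = duration_per_condition,
              n_stimuli = n_stimuli, target_fraction = target_fraction,
              iti_mean = iti_mean, iti_jitter = iti_jitter,
              band_power_map = band_power_map,
              p300_amplitude = p300_amplitude,
              p300_latency = p300_latency, p300_width = p300_width,
              noise_exponent = noise_exponent, noise_rms = noise_rms,
              artifact_rates = artifact_rates,
              blink_amplitude = blink_amplitude,
              burst_amplitude = burst_amplitude,
              calibration_duration = calibration_duration,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$fs > 0,
            cfg$target_fraction >= 0, cfg$target_fraction <= 1,
            cfg$iti_jitter <= cfg$iti_mean, cfg$iti_jitter >= 0,
            all(cfg$band_power_map >= 0),
            all(cfg$p300_amplitude >= 0),
            cfg$p300_width > 0, cfg$p300_latency >= 0,
            cfg$noise_rms >= 0,
            all(cfg$artifact_rates >= 0),
            cfg$calibration_duration >= 0)
  invisible(cfg)
}

#' Read a simulation configuration from a YAML key-value file
#'
#' Scalar fields override the defaults of [sim_config()]; the band power map
#' may be given as nested `band: channel: {low: x, high: y}` entries.
#'
#' @param path path to a YAML file.
#' @return a `SimulationConfig`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::yaml.load_file(path)
  bpm <- NULL
  if (!is.null(raw$band_power_map)) {
    ch <- raw$channel_names %||% c("Fz", "Cz", "Pz", "Oz", "P3", "P4")
    bpm <- default_band_power_map(ch)
    for (band in names(raw$band_power_map))
      for (chan in names(raw$band_power_map[[band]]))
        for (cond in names(raw$band_power_map[[band]][[chan]]))
          bpm[band, chan, cond] <- raw$band_power_map[[band]][[chan]][[cond]]
    raw$band_power_map <- bpm
  }
  for (nm in c("p300_amplitude", "artifact_rates"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
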