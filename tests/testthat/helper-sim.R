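# shared fixtures: everything is generated in code at test time

rms <- function(x) sqrt(mean(x^2))

# a short, artifact-free configuration for fast structural tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_stimuli = 40, duration_per_condition = 100,
         artifact_rates = c(blink = 0, burst = 0)),
    list(...))
  do.call(sim_config, args)
}

# Welch band power of a vector via averaged periodograms
welch_band_power <- function(x, fs, band, seg = 2 * fs) {
  n_seg <- floor(length(x) / seg)
  ps <- 0
  for (i in seq_len(n_seg)) {
    v <- x[((i - 1) * seg + 1):(i * seg)]
    v <- v - mean(v)
    w <- 0.5 - 0.5 * cos(2 * pi * seq_along(v) / (length(v) + 1))
    V <- abs(stats::fft(v * w))^2 / sum(w^2)
    freqs <- (seq_along(V) - 1) * fs / length(V)
    ps <- ps + sum(V[freqs >= band[1] & freqs < band[2]]) / length(v)
  }
  ps / max(n_seg, 1)
}

# sample intervals of logical mask covering logged artifacts (+ guard)
artifact_mask <- function(log, n, fs, guard_s = 0) {
  m <- rep(FALSE, n)
  for (i in seq_len(nrow(log))) {
    i0 <- max(1, round((log$onset[i] - guard_s) * fs))
    i1 <- min(n, round((log$onset[i] + log$duration[i] + guard_s) * fs))
    m[i0:i1] <- TRUE
  }
  m
}
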