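#' Design a Hamming-windowed sinc FIR filter
#'
#' Linear-phase windowed-sinc design (Octave-compatible, via
#' [signal::fir1()]). The order must be even so the group delay
#' `order / 2` is a whole number of samples and [apply_filter()] can
#' compensate it exactly. Band edges are in Hz; use `NA` for an open end
#' (`c(NA, 30)` low-pass, `c(0.5, NA)` high-pass).
#'
#' @param band numeric length-2, `(low, high)` in Hz; open ends as `NA` or 0.
#' @param order filter order (even); the kernel has `order + 1` taps.
#' @param fs sampling rate (Hz).
#' @return a `FilterKernel`: list with `coefficients`, `order`, `band`, `fs`.
#' @export
design_fir <- function(band, order = 250, fs = 500) {
  if (order %% 2 != 0) stop("order must be even for integral group delay")
  low <- band[1]; high <- band[2]
  nyq <- fs / 2
  if (is.na(low) || low <= 0) {
    if (is.na(high) || high <= 0 || high >= nyq)
      stop("invalid band edges: (", low, ", ", high, ")")
    h <- signal::fir1(order, high / nyq, type = "low")
  } else if (is.na(high) || high >= nyq) {
    if (low >= nyq) stop("invalid band edges: low >= Nyquist")
    # spectral inversion of a DC-normalized low-pass: DC gain is exactly 0
    # whatever the order, which matters for the 0.5 Hz drift filter
    h <- signal::fir1(order, low / nyq, type = "low")
    h <- -h / sum(h)
    h[order / 2 + 1] <- h[order / 2 + 1] + 1
  } else {
    if (low >= high) stop("invalid band edges: low >= high")
    h <- signal::fir1(order, c(low, high) / nyq, type = "pass")
  }
  structure(list(coefficients = as.numeric(h), order = order,
                 band = c(low = low, high = high), fs = fs,
                 design = "hamming-windowed sinc"),
            class = "FilterKernel")
}

# Row-wise zero-phase FIR filtering of a samples-in-columns matrix:
# reflection padding at both ends, single-pass FFT convolution, output
# shifted left by the group delay order/2 so it aligns with the input.
fir_filter_matrix <- function(x, kernel) {
  k <- kernel$coefficients
  L <- kernel$order / 2
  n <- ncol(x)
  if (n <= 3 * length(k))
    stop("signal too short to filter: ", n, " samples for a ",
         length(k), "-tap kernel")
  if (L > 0) {
    left <- x[, (L + 1):2, drop = FALSE]
    right <- x[, (n - 1):(n - L), drop = FALSE]
    xp <- cbind(left, x, right)
  } else xp <- x
  np <- ncol(xp)
  nfft <- stats::nextn(np + length(k) - 1L, 2)
  K <- stats::fft(c(k, rep(0, nfft - length(k))))
  XP <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nfft - np))))
  y <- Re(stats::mvfft(XP * K, inverse = TRUE)) / nfft
  # full convolution index (2L + i) is the zero-phase output for sample i
  t(y)[, (2 * L + 1):(2 * L + n), drop = FALSE]
}

#' Apply an FIR kernel with exact group-delay compensation
#'
#' Single-pass convolution; the output is shifted left by `order / 2`
#' samples and the edges are reflection-padded, so the result has the same
#' length as the input and zero phase lag at steady state.
#'
#' @param x a `Recording` or an `EpochSet`.
#' @param kernel a `FilterKernel` from [design_fir()].
#' @return an object of the same class, filtered.
#' @export
apply_filter <- function(x, kernel) UseMethod("apply_filter")

#' @export
apply_filter.Recording <- function(x, kernel) {
  new_recording(fir_filter_matrix(x$data, kernel), x$fs, x$channel_names,
                x$meta)
}

#' @export
apply_filter.EpochSet <- function(x, kernel) {
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[1] * d[2],
                 ncol = d[3], byrow = TRUE)
  out <- fir_filter_matrix(flat, kernel)
  arr <- aperm(array(t(out), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  new_epochset(arr, x$tmin, x$fs, x$channel_names, x$metadata)
}

#' @export
apply_filter.matrix <- function(x, kernel) fir_filter_matrix(x, kernel)

#' Magnitude response of a filter kernel
#' @param kernel a `FilterKernel`.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return numeric vector of magnitudes.
#' @export
filter_response <- function(kernel, freqs) {
  k <- kernel$coefficients
  n <- seq_along(k) - 1
  vapply(freqs, function(f) {
    Mod(sum(k * exp(-2i * pi * f * n / kernel$fs)))
  }, numeric(1))
}
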