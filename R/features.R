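#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-12 and (low) beta 12-16 Hz.
#'
#' @return named list of `c(low, high)` edges in Hz.
#' @export
band_set <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 16))
}

#' Feature matrix with provenance
#'
#' @param values numeric matrix, epochs x features.
#' @param feature_names character, one per column (e.g. `erp:Pz:t0.120`,
#'   `pow:alpha:csp1`).
#' @param labels per-epoch condition labels.
#' @return a `FeatureMatrix`.
#' @export
new_feature_matrix <- function(values, feature_names, labels) {
  values <- as.matrix(values)
  if (ncol(values) != length(feature_names))
    stop("feature_names length does not match column count")
  if (nrow(values) != length(labels))
    stop("labels length does not match epoch count")
  if (!all(is.finite(values))) stop("feature matrix contains non-finite values")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = labels),
            class = "FeatureMatrix")
}

#' Combine feature matrices column-wise
#' @param ... `FeatureMatrix` objects over the same epochs.
#' @return a `FeatureMatrix`.
#' @export
cbind_features <- function(...) {
  fms <- list(...)
  labels <- fms[[1]]$labels
  for (fm in fms)
    if (!identical(fm$labels, labels)) stop("feature matrices differ in labels")
  new_feature_matrix(do.call(cbind, lapply(fms, `[[`, "values")),
                     unlist(lapply(fms, `[[`, "feature_names")), labels)
}

#' ERP sample-vector features
#'
#' Concatenates, per epoch, the samples in `[window[1], window[2])` of every
#' channel (channel-major order) into one feature vector. In the
#' stimulus-locked pipeline the epochs arrive 1-15 Hz filtered,
#' baseline-corrected and downsampled to 50 Hz, so the 0-0.6 s window over
#' 6 channels yields 180 features.
#'
#' @param epochs an `EpochSet`.
#' @param window time window `[t0, t1)` in s relative to stimulus onset.
#' @return a `FeatureMatrix` with names `erp:<channel>:t<seconds>`.
#' @export
erp_features <- function(epochs, window = c(0, 0.6)) {
  tt <- epoch_times(epochs)
  sel <- which(tt >= window[1] & tt < window[2])
  if (!length(sel) || tt[1] > window[1] + 1e-9 ||
      utils::tail(tt, 1) < window[2] - 1 / epochs$fs - 1e-9)
    stop("epoch span does not cover the feature window [", window[1], ", ",
         window[2], ")")
  d <- dim(epochs$data)
  vals <- matrix(0, d[1], d[2] * length(sel))
  names_out <- character(d[2] * length(sel))
  for (c_i in seq_len(d[2])) {
    cols <- (c_i - 1L) * length(sel) + seq_along(sel)
    vals[, cols] <- epochs$data[, c_i, sel]
    names_out[cols] <- sprintf("erp:%s:t%.3f", epochs$channel_names[c_i],
                               tt[sel])
  }
  new_feature_matrix(vals, names_out, epochs$metadata$condition)
}

# per-epoch covariance of band-filtered samples inside a window; the
# quadratic form w' C w is exactly the mean squared CSP-filtered signal, so
# CSP fitting and log band-power features both run off these arrays.
epoch_band_cov <- function(epochs, band, order = 250, window = NULL) {
  filt <- apply_filter(epochs, design_fir(band, order, epochs$fs))
  tt <- epoch_times(epochs)
  sel <- if (is.null(window)) seq_along(tt) else
    which(tt >= window[1] & tt < window[2])
  if (!length(sel)) stop("window outside epoch span")
  d <- dim(filt$data)
  covs <- array(0, dim = c(d[2], d[2], d[1]))
  for (i in seq_len(d[1])) {
    seg <- matrix(filt$data[i, , sel], d[2], length(sel))
    covs[, , i] <- tcrossprod(seg) / length(sel)
  }
  covs
}

#' Per-epoch band covariances for every band
#'
#' Band-pass filters the epochs per band (order-250 windowed sinc) and
#' returns the per-epoch sample covariance over the analysis window; these
#' arrays are sufficient statistics for both CSP fitting and the log
#' band-power features.
#'
#' @param epochs an `EpochSet`.
#' @param bands a [band_set()].
#' @param window analysis window `[t0, t1)` in s, or `NULL` for the full
#'   epoch.
#' @param order FIR order for the band filters.
#' @return named list (per band) of `channels x channels x epochs` arrays.
#' @export
epoch_band_covariances <- function(epochs, bands = band_set(), window = NULL,
                                   order = 250) {
  lapply(bands, function(b) epoch_band_cov(epochs, b, order, window))
}

#' CSP log band-power features
#'
#' Per band: band-pass filter (order-250 windowed sinc), apply the band's
#' CSP filters, square, average over the analysis window, natural-log
#' transform. With 4 bands and 2 CSP pairs this yields the 16 features of
#' the frequency pipeline.
#'
#' @param epochs an `EpochSet`.
#' @param csp_bank named list (per band) of `CSPModel`s from [fit_csp()].
#' @param window analysis window `[t0, t1)` in s, or `NULL` for the full
#'   epoch (continuous pipeline).
#' @param band_covs optional precomputed [epoch_band_covariances()]; skips
#'   the filtering.
#' @return a `FeatureMatrix` with names `pow:<band>:csp<j>`.
#' @export
bandpower_features <- function(epochs, csp_bank, window = c(0, 0.6),
                               band_covs = NULL) {
  if (is.null(band_covs))
    band_covs <- lapply(band_set()[names(csp_bank)], function(b)
      epoch_band_cov(epochs, b, 250, window))
  vals <- NULL
  names_out <- character()
  for (band in names(csp_bank)) {
    model <- csp_bank[[band]]
    if (is.null(model$filters)) stop("CSP model for band ", band,
                                     " is not fitted")
    covs <- band_covs[[band]]
    W <- model$filters
    p <- matrix(vapply(seq_len(dim(covs)[3]), function(i)
      log(pmax(diag(t(W) %*% covs[, , i] %*% W), 1e-300)),
      numeric(ncol(W))), nrow = ncol(W))
    vals <- cbind(vals, t(p))
    names_out <- c(names_out,
                   sprintf("pow:%s:csp%d", band, seq_len(ncol(W))))
  }
  new_feature_matrix(vals, names_out, epochs$metadata$condition)
}

#' Morlet-wavelet band power
#'
#' Continuous wavelet transform with a 6-cycle complex Morlet mother
#' wavelet. Per scale, the squared magnitude is normalized by the wavelet's
#' noise-equivalent bandwidth into a one-sided PSD estimate; band power is
#' that PSD averaged over the scales whose centre frequencies fall inside
#' the band (1-Hz spaced) and integrated over the band width, in uV^2 (so a
#' pure tone contributes its mean-square power and white-noise band power
#' grows with bandwidth).
#'
#' @param x a `Recording` or `EpochSet`.
#' @param bands a [band_set()].
#' @param channel channel name; `NULL` for all channels.
#' @param n_cycles wavelet cycles (time-frequency trade-off).
#' @return for a `Recording`: named list per band of channels x samples
#'   power matrices. For an `EpochSet`: array `epochs x channels x bands`
#'   of epoch-mean power.
#' @export
morlet_bandpower <- function(x, bands = band_set(), channel = NULL,
                             n_cycles = 6) UseMethod("morlet_bandpower")

morlet_power_matrix <- function(mat, fs, bands, n_cycles) {
  n <- ncol(mat)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::mvfft(t(cbind(mat, matrix(0, nrow(mat), nfft - n))))
  fgrid <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  lapply(bands, function(b) {
    if (b[2] > fs / 2) stop("band above Nyquist")
    freqs <- seq(b[1] + 0.5, b[2] - 0.5, by = 1)
    pow <- matrix(0, nrow(mat), n)
    for (f in freqs) {
      sigma <- n_cycles / (2 * pi * f)
      # frequency-domain Morlet (analytic, gain 2 at the centre frequency)
      H <- exp(-2 * pi^2 * sigma^2 * (fgrid - f)^2) * 2
      W <- stats::mvfft(X * H, inverse = TRUE) / nfft
      # |W|^2/2 estimates tone mean-square power; dividing by the wavelet's
      # noise-equivalent bandwidth turns it into a one-sided PSD estimate
      neb <- 1 / (2 * sigma * sqrt(pi))
      pow <- pow + Mod(t(W[seq_len(n), , drop = FALSE]))^2 / (2 * neb)
    }
    # PSD averaged over scales, integrated over the band width (uV^2)
    pow * (b[2] - b[1]) / length(freqs)
  })
}

#' @export
morlet_bandpower.Recording <- function(x, bands = band_set(), channel = NULL,
                                       n_cycles = 6) {
  mat <- x$data
  if (!is.null(channel)) mat <- mat[channel, , drop = FALSE]
  morlet_power_matrix(mat, x$fs, bands, n_cycles)
}

#' @export
morlet_bandpower.EpochSet <- function(x, bands = band_set(), channel = NULL,
                                      n_cycles = 6) {
  d <- dim(x$data)
  chans <- if (is.null(channel)) x$channel_names else channel
  out <- array(0, dim = c(d[1], length(chans), length(bands)),
               dimnames = list(NULL, chans, names(bands)))
  for (i in seq_len(d[1])) {
    mat <- matrix(x$data[i, match(chans, x$channel_names), ],
                  length(chans), d[3])
    pw <- morlet_power_matrix(mat, x$fs, bands, n_cycles)
    for (b in seq_along(bands)) out[i, , b] <- rowMeans(pw[[b]])
  }
  out
}
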