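## Artifact Subspace Reconstruction.
##
## Calibration learns, from a clean segment, (i) the covariance of resting
## EEG (arithmetic mean of per-window covariances for the classic variant,
## Riemannian geometric mean for the rASR variant), whose principal square
## root is the mixing matrix, and (ii) per-component amplitude statistics
## that set the burst-detection thresholds (mean + k * SD of windowed
## component RMS, with the lenient default k = 70). Processing slides
## half-overlapping windows over the data, eigendecomposes each window
## covariance, flags eigencomponents whose variance exceeds the calibrated
## threshold projected into the window's eigenbasis, and reconstructs the
## flagged subspace from the clean calibration mixing.

# symmetric eigendecomposition helpers for SPD matrices
spd_fun <- function(C, f) {
  e <- eigen(C, symmetric = TRUE)
  vals <- f(pmax(e$values, 0))
  e$vectors %*% (vals * t(e$vectors))
}
spd_sqrt <- function(C) spd_fun(C, sqrt)
spd_invsqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0) stop("matrix is not positive definite")
  e$vectors %*% (1 / sqrt(e$values) * t(e$vectors))
}
spd_log <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0) stop("matrix is not positive definite")
  e$vectors %*% (log(e$values) * t(e$vectors))
}
spd_exp <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Riemannian (geometric) mean of SPD matrices
#'
#' Karcher mean on the SPD manifold under the affine-invariant metric,
#' computed by fixed-point iteration warm-started at the arithmetic mean.
#'
#' @param covs list of symmetric positive-definite matrices.
#' @param tol convergence tolerance on the Frobenius norm of the tangent
#'   mean.
#' @param max_iter iteration cap.
#' @return the geometric mean matrix.
#' @export
riemannian_mean <- function(covs, tol = 1e-6, max_iter = 50) {
  X <- Reduce(`+`, covs) / length(covs)
  for (it in seq_len(max_iter)) {
    Xs <- spd_sqrt(X)
    Xis <- spd_invsqrt(X)
    S <- Reduce(`+`, lapply(covs, function(C) spd_log(Xis %*% C %*% Xis))) /
      length(covs)
    X <- Xs %*% spd_exp(S) %*% Xs
    X <- (X + t(X)) / 2
    if (sqrt(sum(S^2)) < tol) break
  }
  X
}

# Spectral pre-emphasis for detection statistics: a first-difference
# high-pass y[t] = x[t] - a x[t-1] that flattens the 1/f background, so the
# windowed component-RMS distribution is narrow and mean + k SD thresholds
# sit well below broadband bursts even at the lenient k = 70. Detection
# runs on the shaped signal; reconstruction is applied to the raw signal.
asr_preemphasis <- function(x, a = 0.95) {
  cbind((1 - a) * x[, 1, drop = FALSE],
        x[, -1, drop = FALSE] - a * x[, -ncol(x), drop = FALSE])
}

# per-window sample covariances over sliding windows (50% overlap)
window_covariances <- function(x, win, hop) {
  n <- ncol(x)
  starts <- seq(1L, max(n - win + 1L, 1L), by = hop)
  lapply(starts, function(s) {
    seg <- x[, s:min(s + win - 1L, n), drop = FALSE]
    tcrossprod(seg) / ncol(seg)
  })
}

#' Calibrate an ASR model on clean EEG
#'
#' @param calibration a `Recording` of artifact-free EEG (e.g. the 30-s
#'   lead-in recorded before the task).
#' @param cutoff_k burst criterion: components are flagged beyond
#'   `mean + cutoff_k * SD` of their calibration RMS.
#' @param window_len sliding-window length (s).
#' @param variant `"riemannian"` (geometric-mean covariance, rASR) or
#'   `"classic"` (arithmetic mean).
#' @return an `ASRModel`: mixing matrix (principal square root of the
#'   calibration covariance), component basis, per-component RMS thresholds.
#' @export
asr_calibrate <- function(calibration, cutoff_k = 70, window_len = 0.5,
                          variant = c("riemannian", "classic")) {
  variant <- match.arg(variant)
  fs <- calibration$fs
  win <- round(window_len * fs)
  if (ncol(calibration$data) < 10 * win)
    stop("calibration too short: need at least ", 10 * window_len, " s")
  if (any(apply(calibration$data, 1, stats::sd) == 0))
    stop("calibration contains a flat channel")
  x <- asr_preemphasis(calibration$data)
  covs <- window_covariances(x, win, win %/% 2L)
  C <- switch(variant,
              classic = Reduce(`+`, covs) / length(covs),
              riemannian = riemannian_mean(covs))
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= .Machine$double.eps * max(e$values) * 100)
    stop("rank-deficient calibration covariance; check for duplicate or ",
         "disconnected channels")
  V <- e$vectors
  mixing <- V %*% (sqrt(e$values) * t(V))
  # windowed RMS per component over the calibration
  comp <- t(V) %*% x
  starts <- seq(1L, ncol(x) - win + 1L, by = win %/% 2L)
  rms <- vapply(starts, function(s)
    sqrt(rowMeans(comp[, s:(s + win - 1L), drop = FALSE]^2)),
    numeric(nrow(x)))
  thresholds <- rowMeans(rms) + cutoff_k * apply(rms, 1, stats::sd)
  structure(list(mixing = mixing, basis = V, cov = C,
                 thresholds = thresholds, cutoff_k = cutoff_k,
                 window_len = window_len, calibration_fs = fs,
                 variant = variant,
                 channel_names = calibration$channel_names),
            class = "ASRModel")
}

#' @export
print.ASRModel <- function(x, ...) {
  cat(sprintf("ASRModel (%s): %d channels, k = %g, window = %g s\n",
              x$variant, length(x$thresholds), x$cutoff_k, x$window_len))
  cat("  component RMS thresholds (uV):",
      paste(signif(sort(x$thresholds, decreasing = TRUE), 3), collapse = ", "),
      "\n")
  invisible(x)
}

# clean one window against the model; detection uses the pre-emphasized
# segment, reconstruction remixes the raw one
asr_clean_window <- function(seg, seg_shaped, model) {
  Cw <- tcrossprod(seg_shaped) / ncol(seg_shaped)
  ew <- eigen(Cw, symmetric = TRUE)
  # calibrated threshold projected into this window's eigenbasis
  Tm <- model$basis %*% diag(model$thresholds)
  lim <- colSums((t(Tm) %*% ew$vectors)^2)
  keep <- ew$values <= lim
  if (all(keep)) return(list(seg = seg, flagged = FALSE))
  if (!any(keep)) {
    # whole space is artifactual; nothing reconstructible
    return(list(seg = matrix(0, nrow(seg), ncol(seg)), flagged = TRUE))
  }
  V <- ew$vectors
  M <- model$mixing
  VM <- t(V) %*% M
  VM[!keep, ] <- 0
  R <- M %*% MASS_ginv(VM) %*% t(V)
  list(seg = R %*% seg, flagged = TRUE)
}

# Moore-Penrose pseudo-inverse via SVD (tiny matrices only)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(t(X) * 0)
  s$v[, pos, drop = FALSE] %*% (1 / s$d[pos] * t(s$u[, pos, drop = FALSE]))
}

#' Detect and reconstruct artifactual subspaces
#'
#' Slides half-overlapping windows over the signal; windows whose component
#' variances stay inside the calibrated bounds pass through bit-identically
#' (up to the raised-cosine overlap-add blend at flagged neighbours), while
#' flagged subspaces are replaced by their projection through the clean
#' calibration mixing.
#'
#' @param x a `Recording` or an `EpochSet` (per-epoch processing with the
#'   shared calibration model).
#' @param model an `ASRModel` from [asr_calibrate()].
#' @return list with `cleaned` (same class as `x`) and `flags` (logical,
#'   one per window, or a list per epoch).
#' @export
asr_process <- function(x, model) UseMethod("asr_process")

#' @export
asr_process.Recording <- function(x, model) {
  if (!identical(x$channel_names, model$channel_names))
    stop("channel set differs from the calibration: ",
         paste(x$channel_names, collapse = ","), " vs ",
         paste(model$channel_names, collapse = ","))
  res <- asr_process_matrix(x$data, x$fs, model)
  list(cleaned = new_recording(res$x, x$fs, x$channel_names, x$meta),
       flags = res$flags)
}

#' @export
asr_process.EpochSet <- function(x, model) {
  if (!identical(x$channel_names, model$channel_names))
    stop("channel set differs from the calibration")
  d <- dim(x$data)
  flags <- vector("list", d[1])
  out <- x$data
  for (i in seq_len(d[1])) {
    res <- asr_process_matrix(matrix(x$data[i, , ], d[2], d[3]), x$fs, model)
    out[i, , ] <- res$x
    flags[[i]] <- res$flags
  }
  list(cleaned = new_epochset(out, x$tmin, x$fs, x$channel_names, x$metadata),
       flags = flags)
}

asr_process_matrix <- function(x, fs, model) {
  n <- ncol(x)
  win <- round(model$window_len * fs)
  hop <- win %/% 2L
  xs <- asr_preemphasis(x)
  if (n < win) {
    res <- asr_clean_window(x, xs, model)
    return(list(x = res$seg, flags = res$flagged))
  }
  starts <- seq(1L, n - win + 1L, by = hop)
  if (utils::tail(starts, 1) + win - 1L < n)
    starts <- c(starts, n - win + 1L)
  acc <- matrix(0, nrow(x), n)
  wacc <- numeric(n)
  flags <- logical(length(starts))
  taper <- sin(pi * (seq_len(win) - 0.5) / win)^2   # raised cosine
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + win - 1L)
    res <- asr_clean_window(x[, idx, drop = FALSE],
                            xs[, idx, drop = FALSE], model)
    flags[j] <- res$flagged
    acc[, idx] <- acc[, idx] + res$seg * rep(taper, each = nrow(x))
    wacc[idx] <- wacc[idx] + taper
  }
  list(x = acc / rep(wacc, each = nrow(x)), flags = flags)
}
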