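#' Paired sign-flip bootstrap contrast
#'
#' Tests, per time point (or band/channel), whether the paired condition
#' difference differs from zero: the observed statistic is the mean over
#' subjects of `A - B`; the null distribution is built by randomly
#' sign-flipping each subject's difference `n_boot` times. Two-sided
#' p-values use the add-one estimator `(1 + #{|null| >= |obs|}) /
#' (n_boot + 1)`, which is valid (conservative) by construction.
#'
#' @param values_A,values_B numeric matrices, subjects x points, paired by
#'   row.
#' @param n_boot resampling iterations (default 10000).
#' @param alpha significance level for the returned mask.
#' @param seed RNG seed.
#' @return a `ContrastResult`: `statistic`, `p`, `significant`, `n_boot`,
#'   `alpha`.
#' @export
bootstrap_paired_contrast <- function(values_A, values_B, n_boot = 10000,
                                      alpha = 0.01, seed = 1) {
  A <- rbind(values_A); B <- rbind(values_B)
  if (!all(dim(A) == dim(B)))
    stop("condition matrices differ in shape: ", nrow(A), "x", ncol(A),
         " vs ", nrow(B), "x", ncol(B))
  n_sub <- nrow(A)
  if (n_sub < 5) stop("need at least 5 subjects, got ", n_sub)
  D <- A - B
  obs <- colMeans(D)
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_boot * n_sub, replace = TRUE),
                  n_boot, n_sub)
  null_stats <- (flips %*% D) / n_sub          # n_boot x points
  exceed <- colSums(abs(null_stats) >= rep(abs(obs), each = n_boot))
  p <- (1 + exceed) / (n_boot + 1)
  structure(list(statistic = obs, p = p, significant = p < alpha,
                 n_boot = n_boot, alpha = alpha, n_subjects = n_sub),
            class = "ContrastResult")
}

#' Per-subject condition-mean ERP waveforms and P300 window means
#'
#' Averages baseline-corrected epochs per subject, condition and stimulus
#' type, and reduces each average to a scalar P300 amplitude: the mean over
#' the 0.35-0.6 s window. The per-subject target-minus-standard P300
#' difference per condition is what feeds [bootstrap_paired_contrast()].
#'
#' @param epoch_sets list (one per subject) of `EpochSet`s carrying both
#'   conditions and stimulus labels.
#' @param channel channel for the scalar summary (default `"Pz"`).
#' @param window P300 window in s.
#' @return list with `waveforms` (subject x condition x stimulus list of
#'   mean traces) and `p300` (data.frame: subject, condition, stimulus,
#'   amplitude).
#' @export
erp_condition_waveforms <- function(epoch_sets, channel = "Pz",
                                    window = c(0.35, 0.6)) {
  rows <- list(); waves <- list()
  excluded <- character()
  for (s in seq_along(epoch_sets)) {
    ep <- epoch_sets[[s]]
    ch <- match(channel, ep$channel_names)
    if (is.na(ch)) stop("channel ", channel, " not present")
    tt <- epoch_times(ep)
    sel <- tt >= window[1] & tt < window[2]
    for (cond in unique(ep$metadata$condition)) {
      for (stim in unique(ep$metadata$stimulus)) {
        idx <- ep$metadata$condition == cond & ep$metadata$stimulus == stim &
          ep$metadata$retained
        if (!any(idx)) {
          warning("subject ", s, " has no retained ", stim, " epochs in ",
                  cond, " load; excluded")
          excluded <- c(excluded, paste(s, cond, stim))
          next
        }
        m <- apply(ep$data[idx, ch, , drop = FALSE], 3, mean)
        waves[[paste(s, cond, stim, sep = ".")]] <- m
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, condition = cond, stimulus = stim,
                     amplitude = mean(m[sel]))
      }
    }
  }
  list(waveforms = waves, p300 = do.call(rbind, rows), window = window,
       channel = channel, excluded = excluded)
}

#' Per-subject target-minus-standard P300 amplitudes
#'
#' Runs the ERP statistics path on one subject's session: 0.5-30 Hz FIR
#' filter, continuous rASR (calibrated on the lead-in), -0.2..1 s epochs,
#' baseline correction, then the target-minus-standard mean amplitude in
#' the P300 window per condition at the given channel.
#'
#' @param session two-condition session list (see [run_pipeline1()]).
#' @param channel channel of interest (default `"Pz"`).
#' @param window P300 window (s).
#' @param apply_asr run rASR before epoching.
#' @param calibration_s rASR calibration lead-in (s).
#' @return named numeric `c(low = ..., high = ...)` amplitudes (uV).
#' @export
subject_p300_amplitudes <- function(session, channel = "Pz",
                                    window = c(0.35, 0.6), apply_asr = TRUE,
                                    calibration_s = 30) {
  out <- c(low = NA_real_, high = NA_real_)
  for (cond in c("low", "high")) {
    rec <- session[[cond]]$recording
    rec <- apply_filter(rec, design_fir(c(0.5, 30), 250, rec$fs))
    if (apply_asr) {
      model <- asr_calibrate(crop_recording(rec, 0, calibration_s))
      rec <- asr_process(rec, model)$cleaned
    }
    ep <- extract_epochs(rec, session[[cond]]$events, -0.2, 1)
    ep <- baseline_correct(ep, c(-0.2, 0))
    tt <- epoch_times(ep)
    sel <- tt >= window[1] & tt < window[2]
    ch <- match(channel, ep$channel_names)
    tgt <- ep$metadata$stimulus == "target"
    out[cond] <- mean(ep$data[tgt, ch, sel]) - mean(ep$data[!tgt, ch, sel])
  }
  out
}

#' Write a contrast result as a tab-separated table
#' @param contrast a `ContrastResult`.
#' @param path output path.
#' @param point_names optional names for the tested points.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path, point_names = NULL) {
  tab <- data.frame(point = point_names %||% seq_along(contrast$statistic),
                    mean_difference = contrast$statistic,
                    p = contrast$p, significant = contrast$significant)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
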