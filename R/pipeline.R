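## End-to-end workload-classification pipelines.
##
## Pipeline 1 is stimulus-locked: -1..+1 s epochs around every oddball
## stimulus, per-epoch rASR with the 30-s calibration model, then an ERP
## branch (1-15 Hz, baseline, 0-0.6 s at 50 Hz -> 180 sample features)
## and/or a frequency branch (4 bands x 4 CSP filters -> 16 log band-power
## features), optionally fused by per-fold mRMR-20. Pipeline 2 ignores the
## stimuli: non-overlapping 2-s windows, per-epoch rASR, the 16 band-power
## features over the full window.

pipeline_inputs <- function(session) {
  stopifnot(all(c("low", "high") %in% names(session)))
  for (cond in c("low", "high"))
    if (is.null(session[[cond]]$recording))
      stop("session$", cond, " lacks a recording")
  session
}

#' Load a session from EDF + events files
#'
#' @param recording_paths named list/vector (`low`, `high`) of EDF paths.
#' @param event_paths named list/vector of events-file paths (optional for
#'   the continuous pipeline).
#' @param expected_channels channel validation passed to [read_edf()].
#' @return session list consumable by [run_pipeline1()]/[run_pipeline2()].
#' @export
load_session <- function(recording_paths, event_paths = NULL,
                         expected_channels = c("Fz", "Cz", "Pz", "Oz", "P3", "P4")) {
  out <- lapply(c(low = "low", high = "high"), function(cond) {
    rec <- read_edf(recording_paths[[cond]], expected_channels)
    rec$meta$condition <- cond
    ev <- if (!is.null(event_paths)) read_events(event_paths[[cond]]) else NULL
    list(recording = rec, events = ev)
  })
  out
}

calibrate_on_leadin <- function(recording, calibration_s, params, variant) {
  calib <- crop_recording(recording, 0, calibration_s)
  asr_calibrate(calib, cutoff_k = params$burst_k, variant = variant)
}

#' Run the stimulus-locked classification pipeline
#'
#' @param session named list (`low`, `high`) with `recording` and `events`
#'   per condition, e.g. from [simulate_session()] or [load_session()].
#' @param pipeline feature set: `"erp"`, `"freq"`, or `"fused"` (mRMR-20
#'   over the concatenation).
#' @param calibration_s seconds of lead-in used to calibrate rASR.
#' @param params a [clean_raw_params()].
#' @param variant ASR variant (`"riemannian"` or `"classic"`).
#' @param n_folds,seed cross-validation folds and seed.
#' @param apply_asr set `FALSE` to skip artifact correction.
#' @return a `ClassificationReport`; attribute `log` carries per-stage
#'   counts.
#' @export
run_pipeline1 <- function(session, pipeline = c("fused", "erp", "freq"),
                          calibration_s = 30, params = clean_raw_params(),
                          variant = "riemannian", n_folds = 5, seed = 1,
                          apply_asr = TRUE) {
  pipeline <- match.arg(pipeline)
  session <- pipeline_inputs(session)
  log <- list(pipeline = pipeline, stages = list())
  eps <- list()
  for (cond in c("low", "high")) {
    rec <- session[[cond]]$recording
    ev <- session[[cond]]$events
    if (is.null(ev)) stop("pipeline 1 requires events for the ", cond,
                          " condition")
    ep <- extract_epochs(rec, ev, tmin = -1, tmax = 1, lock = "all")
    log$stages[[paste0("epoch_", cond)]] <-
      list(n = n_epochs(ep), dropped_boundary = attr(ep, "n_dropped"))
    if (apply_asr) {
      model <- calibrate_on_leadin(rec, calibration_s, params, variant)
      res <- asr_process(ep, model)
      ep <- res$cleaned
      log$stages[[paste0("asr_", cond)]] <-
        list(epochs_touched = sum(vapply(res$flags, any, logical(1))))
    }
    eps[[cond]] <- ep
  }
  epochs <- merge_epochsets(eps$low, eps$high)
  labels <- epochs$metadata$condition

  erp <- NULL
  if (pipeline %in% c("erp", "fused")) {
    e <- apply_filter(epochs, design_fir(c(1, 15), 250, epochs$fs))
    e <- baseline_correct(e, c(-0.2, 0))
    e <- downsample_epochs(e, 50)
    erp <- erp_features(e, c(0, 0.6))
    log$stages$erp_features <- list(n_features = ncol(erp$values))
  }
  band_covs <- NULL
  if (pipeline %in% c("freq", "fused")) {
    band_covs <- epoch_band_covariances(epochs, band_set(),
                                        window = c(0, 0.6))
    log$stages$band_covariances <- list(bands = names(band_covs))
  }
  report <- crossvalidate(labels, erp = erp, band_covs = band_covs,
                          n_folds = n_folds,
                          select_k = if (pipeline == "fused") 20 else NULL,
                          positive = "high", seed = seed,
                          channel_names = epochs$channel_names)
  attr(report, "log") <- log
  report
}

#' Run the continuous (stimulus-free) classification pipeline
#'
#' Non-overlapping 2-s windows cut after the calibration lead-in, per-epoch
#' rASR, 16 log band-power features over the full window, stratified
#' cross-validated sLDA.
#'
#' @inheritParams run_pipeline1
#' @param window_s segmentation window (s).
#' @return a `ClassificationReport` with attribute `log`.
#' @export
run_pipeline2 <- function(session, window_s = 2, calibration_s = 30,
                          params = clean_raw_params(), variant = "riemannian",
                          n_folds = 5, seed = 1, apply_asr = TRUE) {
  session <- pipeline_inputs(session)
  log <- list(pipeline = "continuous", stages = list())
  eps <- list()
  for (cond in c("low", "high")) {
    rec <- session[[cond]]$recording
    ep <- segment_continuous(rec, window_s, skip_s = calibration_s)
    log$stages[[paste0("segment_", cond)]] <- list(n = n_epochs(ep))
    if (apply_asr) {
      model <- calibrate_on_leadin(rec, calibration_s, params, variant)
      res <- asr_process(ep, model)
      ep <- res$cleaned
      log$stages[[paste0("asr_", cond)]] <-
        list(epochs_touched = sum(vapply(res$flags, any, logical(1))))
    }
    eps[[cond]] <- ep
  }
  epochs <- merge_epochsets(eps$low, eps$high)
  band_covs <- epoch_band_covariances(epochs, band_set(), window = NULL)
  report <- crossvalidate(epochs$metadata$condition, band_covs = band_covs,
                          n_folds = n_folds, positive = "high", seed = seed,
                          channel_names = epochs$channel_names)
  attr(report, "log") <- log
  report
}

#' Concatenate two EpochSets over epochs
#' @param a,b `EpochSet`s with matching geometry.
#' @return the combined `EpochSet`.
#' @export
merge_epochsets <- function(a, b) {
  stopifnot(identical(a$channel_names, b$channel_names),
            a$fs == b$fs, isTRUE(all.equal(a$tmin, b$tmin)),
            dim(a$data)[3] == dim(b$data)[3])
  d <- dim(a$data)
  arr <- array(0, dim = c(d[1] + dim(b$data)[1], d[2], d[3]))
  arr[seq_len(d[1]), , ] <- a$data
  arr[d[1] + seq_len(dim(b$data)[1]), , ] <- b$data
  new_epochset(arr, a$tmin, a$fs, a$channel_names,
               rbind(a$metadata, b$metadata))
}

#' Serialize a classification report to JSON
#'
#' @param report a `ClassificationReport`.
#' @param path output path; `NULL` returns the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
write_report <- function(report, path = NULL) {
  out <- list(
    n_folds = report$n_folds,
    positive_class = report$positive,
    mean = as.list(report$mean),
    sd = as.list(report$sd),
    per_fold = lapply(report$per_fold, function(f)
      list(metrics = as.list(f$metrics), n_test = f$n_test,
           selected_features = f$selected_names)),
    log = attr(report, "log"))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
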