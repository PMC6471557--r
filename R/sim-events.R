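#' Oddball event stream
#'
#' An `EventStream` is a data.frame with columns `onset` (seconds from the
#' start of the recording), `duration` (seconds; 0 for instantaneous tones),
#' `stimulus` (`"target"` or `"standard"`) and `condition` (`"low"` or
#' `"high"`). Onsets are strictly increasing.
#'
#' @param onset numeric vector of onsets (s), strictly increasing.
#' @param stimulus character vector from `{"target", "standard"}`.
#' @param condition character vector from `{"low", "high"}` (recycled).
#' @param duration numeric vector of event durations (s).
#' @return a data.frame of class `EventStream`.
#' @export
new_event_stream <- function(onset, stimulus, condition, duration = 0) {
  ev <- data.frame(onset = as.numeric(onset), duration = duration,
                   stimulus = as.character(stimulus),
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  validate_event_stream(ev)
  class(ev) <- c("EventStream", "data.frame")
  ev
}

validate_event_stream <- function(ev) {
  if (nrow(ev) > 1L && any(diff(ev$onset) <= 0)) {
    bad <- which(diff(ev$onset) <= 0)[1] + 1L
    stop("event onsets must be strictly increasing; row ", bad,
         " (onset ", ev$onset[bad], ") does not increase")
  }
  unknown <- setdiff(unique(ev$stimulus), c("target", "standard"))
  if (length(unknown))
    stop("unknown stimulus label(s): ", paste(unknown, collapse = ", "))
  invisible(ev)
}

#' Generate the oddball stimulus sequence for one load condition
#'
#' Draws inter-onset intervals uniformly from
#' `[iti_mean - iti_jitter, iti_mean + iti_jitter]` ms, starting after the
#' artifact-free calibration lead-in, and assigns target/standard labels by an
#' exact shuffled split: a stream of `n` stimuli always contains exactly
#' `round(n * target_fraction)` targets. By default each condition carries
#' half of the session's `n_stimuli`, so a full two-condition session at the
#' defaults has 320 stimuli of which 80 are targets.
#'
#' @param config a [sim_config()].
#' @param condition `"low"` or `"high"`.
#' @param n number of stimuli in this stream; defaults to `n_stimuli / 2`.
#' @param seed RNG seed; defaults to a condition-specific offset of
#'   `config$seed` so the two conditions get distinct, reproducible streams.
#' @return an `EventStream`.
#' @export
generate_events <- function(config, condition = c("low", "high"),
                            n = NULL, seed = NULL) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  if (is.null(n)) n <- round(config$n_stimuli / 2)
  if (is.null(seed))
    seed <- config$seed + ifelse(condition == "low", 1L, 2L)
  set.seed(seed)
  n_target <- round(n * config$target_fraction)
  labels <- rep("standard", n)
  labels[sample.int(n, n_target)] <- "target"
  iti <- stats::runif(n, config$iti_mean - config$iti_jitter,
                      config$iti_mean + config$iti_jitter) / 1000
  onset <- config$calibration_duration + cumsum(iti)
  # the final stimulus needs a full post-stimulus epoch inside the recording
  if (n > 0 && onset[n] + 1 > config$duration_per_condition)
    stop("event stream spans ", round(onset[n] + 1, 1),
         " s but duration_per_condition is ", config$duration_per_condition,
         " s; increase the duration or reduce n_stimuli")
  new_event_stream(onset, labels, condition)
}
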