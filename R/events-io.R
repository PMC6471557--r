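#' Write an event stream to a tab-separated file
#'
#' Columns `onset  duration  stimulus  condition`, onsets in seconds with
#' 6-decimal fixed-point precision.
#'
#' @param events an `EventStream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset = sprintf("%.6f", events$onset),
                    duration = sprintf("%.6f", events$duration),
                    stimulus = events$stimulus,
                    condition = events$condition)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event stream from a tab-separated file
#'
#' Validates the header, the stimulus vocabulary and strict onset
#' monotonicity; a header-only file yields an empty stream.
#'
#' @param path events file path.
#' @return an `EventStream`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(onset = "numeric",
                                          duration = "numeric",
                                          stimulus = "character",
                                          condition = "character"))
  required <- c("onset", "duration", "stimulus", "condition")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("events file lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0)
    return(new_event_stream(numeric(), character(), character(), numeric()))
  new_event_stream(tab$onset, tab$stimulus, tab$condition, tab$duration)
}
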