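#' Forward-model activation pattern of a linear decoder
#'
#' For a linear backward model with weights `w`, the corresponding forward
#' (activation) pattern is `Sigma w`, where `Sigma` is the covariance of the
#' decoder's input features. Unlike the weights, the pattern is
#' interpretable as where the decoded signal expresses itself.
#'
#' @param model an `LDAModel`.
#' @param feature_covariance covariance of the features the model was
#'   trained on (training-fold features).
#' @return an `ActivationPattern` (level `"lda"`).
#' @export
lda_activation <- function(model, feature_covariance) {
  if (nrow(feature_covariance) != length(model$weights))
    stop("covariance dimension ", nrow(feature_covariance),
         " does not match weight length ", length(model$weights))
  pattern <- as.vector(feature_covariance %*% model$weights)
  names(pattern) <- model$feature_names
  structure(list(level = "lda", pattern = pattern, model = model),
            class = "ActivationPattern")
}

#' Activation pattern of a CSP filter
#'
#' @param model a `CSPModel`.
#' @param composite_covariance channel covariance to project through;
#'   defaults to the model's own `Sigma_A + Sigma_B`.
#' @param filter index of the CSP filter.
#' @return an `ActivationPattern` (level `"csp"`) over channels.
#' @export
csp_activation <- function(model, composite_covariance = NULL, filter = 1) {
  if (is.null(composite_covariance))
    composite_covariance <- model$composite_cov
  w <- model$filters[, filter]
  if (nrow(composite_covariance) != length(w))
    stop("covariance dimension does not match filter length")
  structure(list(level = "csp",
                 pattern = as.vector(composite_covariance %*% w),
                 model = model, filter = filter),
            class = "ActivationPattern")
}

#' Tally the most informative band and channel across folds
#'
#' Per fold of a frequency-feature report: the feature with the largest
#' absolute sLDA activation-pattern entry names the most informative (band,
#' CSP filter); the channel with the largest absolute entry of that CSP
#' filter's activation pattern names the most informative channel. Ties go
#' to the lowest index. Counts are accumulated over folds and reports.
#'
#' @param reports a `ClassificationReport` or list of them (one per
#'   subject), fitted on frequency features with stored models.
#' @return an `InformativeTally`: data.frame of (band, channel, count) plus
#'   band and channel rank orders.
#' @export
tally_informative <- function(reports) {
  if (inherits(reports, "ClassificationReport")) reports <- list(reports)
  counts <- list()
  for (rep_i in reports) {
    for (f in rep_i$per_fold) {
      if (is.null(f$model) || is.null(f$csp_bank))
        stop("report lacks stored models; rerun crossvalidate with band features")
      act <- lda_activation(f$model, f$feature_cov)$pattern
      pow_idx <- grep("^pow:", names(act))
      if (!length(pow_idx)) stop("no frequency features in the fold model")
      top <- pow_idx[which.max(abs(act[pow_idx]))]
      parts <- strsplit(names(act)[top], ":")[[1]]
      band <- parts[2]
      filt <- as.integer(sub("csp", "", parts[3]))
      cpat <- csp_activation(f$csp_bank[[band]], filter = filt)$pattern
      ch_names <- rep_i$channel_names %||%
        paste0("ch", seq_along(cpat))
      chan <- ch_names[which.max(abs(cpat))]
      key <- paste(band, chan, sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  keys <- do.call(rbind, strsplit(names(counts), "\r"))
  tab <- data.frame(band = keys[, 1], channel = keys[, 2],
                    count = unlist(counts, use.names = FALSE))
  tab <- tab[order(-tab$count), , drop = FALSE]
  rownames(tab) <- NULL
  band_rank <- stats::aggregate(count ~ band, tab, sum)
  band_rank <- band_rank$band[order(-band_rank$count)]
  chan_rank <- stats::aggregate(count ~ channel, tab, sum)
  chan_rank <- chan_rank$channel[order(-chan_rank$count)]
  structure(list(table = tab, band_rank = band_rank,
                 channel_rank = chan_rank, total = sum(tab$count)),
            class = "InformativeTally")
}

#' @export
print.InformativeTally <- function(x, ...) {
  cat("InformativeTally over", x$total, "fold models\n")
  cat("  bands (most informative first):",
      paste(x$band_rank, collapse = " > "), "\n")
  cat("  channels:", paste(x$channel_rank, collapse = " > "), "\n")
  invisible(x)
}

#' Write an informative-feature tally to a tab-separated file
#' @param tally an `InformativeTally`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tally, path) {
  utils::write.table(tally$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
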