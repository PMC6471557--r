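## Minimal European Data Format (EDF) reader/writer.
## EDF: 256-byte ASCII header + 256 bytes per signal, then data records of
## 16-bit little-endian integers; physical values are recovered through the
## per-signal physical/digital calibration ranges. One data record per
## second is written, so fs must be a whole number of samples per second.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)     # left-justified, space-padded
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are stored as 16-bit integers calibrated against a symmetric
#' per-channel physical range, so the round-trip error is bounded by
#' `physical_range / 2^15`. The recording is padded with zeros to a whole
#' number of 1-s data records.
#'
#' @param recording a `Recording` (amplitudes in uV).
#' @param path output path.
#' @param physical_max per-channel symmetric physical range bound (uV);
#'   defaults to slightly above the observed absolute maximum.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_max = NULL) {
  x <- recording$data
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate, got fs = ", fs)
  fs <- as.integer(round(fs))
  ns <- nrow(x)
  if (is.null(physical_max))
    physical_max <- pmax(apply(abs(x), 1, max) * 1.01, 1)
  physical_max <- rep_len(physical_max, ns)
  # the header stores ranges as 8-char ASCII; use the printed value for
  # scaling so writer and reader agree exactly
  pmax_str <- vapply(physical_max, edf_num, "", width = 8)
  pmax_used <- as.numeric(pmax_str)
  if (any(!is.finite(pmax_used) | pmax_used <= 0))
    stop("physical_max not representable in the EDF header")
  n_rec <- as.integer(ceiling(ncol(x) / fs))
  xp <- cbind(x, matrix(0, ns, n_rec * fs - ncol(x)))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad(paste("Startdate 01-JAN-2000 synthetic",
                  recording$meta$condition %||% "X"), 80),
    "01.01.00", "00.00.00",
    edf_num(256 * (1 + ns), 8), edf_pad("", 44),
    edf_num(n_rec, 8), edf_num(1, 8), edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(recording$channel_names, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  writeChar(paste(vapply(-pmax_used, edf_num, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(paste(pmax_str, collapse = ""), con, eos = NULL)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(fs, ns), 8)                        # samples per record
  field(rep("", ns), 32)
  scale <- (2 * pmax_used) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((xp[s, idx] + pmax_used[s]) / scale[s]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' @param path EDF file path.
#' @param expected_channels optional character vector; if given, the file
#'   must contain exactly these channels (any order) and the result is
#'   reordered to match.
#' @return a `Recording` in uV.
#' @export
read_edf <- function(path, expected_channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header: version field is '",
                           version, "', expected '0'")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: signal count")
  if (hdr_bytes != 256 * (1 + ns))
    stop("malformed EDF header: header byte count ", hdr_bytes,
         " does not match ", ns, " signals")
  per <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- per(16); per(80)
  units <- per(8)
  if (any(!units %in% c("uV", "")))
    stop("unit mismatch: expected uV, found ",
         paste(unique(setdiff(units, c("uV", ""))), collapse = ", "))
  p_min <- as.numeric(per(8)); p_max <- as.numeric(per(8))
  d_min <- as.numeric(per(8)); d_max <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  dat <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  if (length(dat) < n_rec * sum(spr))
    stop("malformed EDF: file truncated (", length(dat), " of ",
         n_rec * sum(spr), " samples)")
  x <- matrix(0, ns, n_rec * spr[1])
  dat <- array(dat, dim = c(spr[1], ns, n_rec))
  scale <- (p_max - p_min) / (d_max - d_min)
  for (s in seq_len(ns))
    x[s, ] <- as.vector(dat[, s, ]) * scale[s] + p_min[s] - d_min[s] * scale[s]
  if (!is.null(expected_channels)) {
    missing <- setdiff(expected_channels, labels)
    if (length(missing))
      stop("EDF file is missing expected channel(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(labels, expected_channels)
    if (length(extra))
      stop("EDF file has unexpected channel(s): ",
           paste(extra, collapse = ", "))
    ord <- match(expected_channels, labels)
    x <- x[ord, , drop = FALSE]
    labels <- expected_channels
  }
  new_recording(x, fs, labels, meta = list(source = path))
}
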