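# Minimal European Data Format (EDF) support: fixed-layout ASCII header
# (256 bytes + 256 per signal) followed by 16-bit little-endian data
# records. One-second records are used, so the sampling rate must be an
# integer. Amplitudes are quantized to the 16-bit digital range; the
# round-trip error is bounded by (physical range) / 65534.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes one subject/condition block as plain EDF with 1-second data
#' records. The start date/time fields are fixed placeholders so that
#' rewriting the same recording is byte-identical.
#'
#' @param rec a [recording()] whose `fs` is a positive integer.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate (1-s records)")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record")
  used <- n_rec * fs

  pmin_ <- apply(rec$data[, seq_len(used), drop = FALSE], 1L, min)
  pmax_ <- apply(rec$data[, seq_len(used), drop = FALSE], 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1      # avoid zero physical range
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(rec$subject, 80)
  wr(paste("condition", rec$condition), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (1L + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (lab in rec$labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)                 # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmin_[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmax_[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)                 # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)                 # reserved

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((rec$data[i, idx] - pmin_[i]) * scale[i]) + dmin)
      dig[dig > dmax] <- dmax
      dig[dig < dmin] <- dmin
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads plain EDF written by [write_edf()] (or any EDF whose signals
#' share a common integer sampling rate).
#'
#' @param path EDF file path.
#' @param condition condition label to attach; when `NULL` it is parsed
#'   from the recording-id header field if present, else `"EC"`.
#' @return A [recording()].
#' @export
read_edf <- function(path, condition = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  subject <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                            # date, time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # units
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1L] / dur
  if (abs(fs - round(fs)) > 1e-9) stop("non-integer sampling rate in EDF")

  data <- matrix(0, ns, n_rec * spr[1L])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      data[i, idx] <- (dig - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  if (is.null(condition)) {
    condition <- if (grepl("\\bEO\\b", rec_id)) "EO" else "EC"
  }
  recording(data, round(fs), labels, subject, condition)
}
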