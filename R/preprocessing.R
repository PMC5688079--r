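#' Zero-phase band-pass and notch filtering
#'
#' Offline filtering chain applied per channel: 4th-order Butterworth
#' high-pass at `low_hz`, 4th-order Butterworth low-pass at `high_hz`, and
#' a Butterworth band-stop notch around `notch_hz` (line noise). Every
#' stage is run forward-backward ([signal::filtfilt]) so the filter is
#' zero-phase: downstream phase-based connectivity must not inherit filter
#' phase distortion.
#'
#' @param rec a [recording()].
#' @param low_hz high-pass cutoff, Hz (default 0.5).
#' @param high_hz low-pass cutoff, Hz (default 70).
#' @param notch_hz line frequency to remove, Hz (default 60); `NULL` or
#'   `NA` disables the notch.
#' @param notch_halfwidth_hz half-width of the notch stop band (default 2).
#' @param order Butterworth order for the high/low-pass stages.
#' @return A filtered [recording()].
#' @export
bandpass_notch <- function(rec, low_hz = 0.5, high_hz = 70, notch_hz = 60,
                           notch_halfwidth_hz = 2, order = 4) {
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("need 0 < low_hz < high_hz < fs/2")
  use_notch <- !is.null(notch_hz) && !is.na(notch_hz)
  if (use_notch && notch_hz >= nyq)
    stop("notch_hz must be below the Nyquist frequency")
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  if (use_notch)
    bs <- signal::butter(2, c(notch_hz - notch_halfwidth_hz,
                              notch_hz + notch_halfwidth_hz) / nyq,
                         type = "stop")
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- signal::filtfilt(hp, out[i, ])
    x <- signal::filtfilt(lp, x)
    if (use_notch) x <- signal::filtfilt(bs, x)
    out[i, ] <- x
  }
  rec$data <- out
  rec
}

#' Segment a series into non-overlapping windows
#'
#' Splits a time series (or each channel of a matrix) into contiguous
#' non-overlapping windows of `window_s` seconds; a trailing remainder
#' shorter than one window is discarded.
#'
#' @param x numeric vector, or channels x time matrix.
#' @param fs sampling rate, Hz.
#' @param window_s window length in seconds (default 5, the segment length
#'   used for power-correlation averaging).
#' @return For a vector: a `n_windows x window_len` matrix (one window per
#'   row). For a matrix: a list of channels x window_len matrices, one per
#'   window.
#' @export
segment_windows <- function(x, fs, window_s = 5) {
  wl <- as.integer(round(window_s * fs))
  if (wl < 2L) stop("window_s * fs must be at least 2 samples")
  if (is.matrix(x)) {
    nw <- ncol(x) %/% wl
    if (nw < 1L) stop("series shorter than one window")
    return(lapply(seq_len(nw), function(k)
      x[, ((k - 1L) * wl + 1L):(k * wl), drop = FALSE]))
  }
  nw <- length(x) %/% wl
  if (nw < 1L) stop("series shorter than one window")
  matrix(x[seq_len(nw * wl)], nrow = nw, ncol = wl, byrow = TRUE)
}
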