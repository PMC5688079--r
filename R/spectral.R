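#' Complex Morlet wavelet kernel
#'
#' A complex exponential at frequency `f` tapered by a Gaussian with
#' `sigma_t = n_cycles / (2 * pi * f)`, sampled on \[-support_s, support_s\]
#' and centred at t = 0, which guarantees an odd number of points. A
#' constant number of cycles (7 by default) favours frequency over time
#' precision, appropriate for long resting-state epochs. The kernel is
#' normalized to unit energy.
#'
#' @param f centre frequency, Hz (must be below Nyquist).
#' @param fs sampling rate, Hz.
#' @param n_cycles number of wavelet cycles (>= 3; default 7).
#' @param support_s half-support in seconds (default 1: kernel spans -1..1 s).
#' @return Complex vector of odd length `2 * fs * support_s + 1`, with
#'   attributes `f`, `fs`, `n_cycles`, `sigma_t`.
#' @export
make_morlet <- function(f, fs, n_cycles = 7, support_s = 1) {
  if (f >= fs / 2) stop("wavelet frequency must be below Nyquist (fs/2)")
  if (n_cycles < 3) stop("n_cycles must be >= 3")
  t <- seq(-support_s, support_s, by = 1 / fs)
  sigma_t <- n_cycles / (2 * pi * f)
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  k <- k / sqrt(sum(Mod(k)^2))
  attr(k, "f") <- f
  attr(k, "fs") <- fs
  attr(k, "n_cycles") <- n_cycles
  attr(k, "sigma_t") <- sigma_t
  k
}

#' Wavelet time-frequency decomposition
#'
#' Convolves each channel with a complex Morlet wavelet at each requested
#' frequency (linear FFT convolution, same-length output) to obtain the
#' instantaneous analytic signal: power is `Mod(z)^2`, phase `Arg(z)`.
#' Half a kernel length at each edge is flagged invalid rather than padded,
#' keeping phase estimates unbiased near the edges.
#'
#' @param rec a [recording()].
#' @param frequencies numeric vector of analysis frequencies, Hz (all below
#'   Nyquist; default 2-45 Hz in 1 Hz steps).
#' @param n_cycles wavelet cycles (default 7).
#' @param support_s wavelet half-support, seconds.
#' @return An `analytic_decomposition`: list with complex array `coef`
#'   (channels x frequencies x time), `frequencies`, `fs`, logical
#'   `valid` time mask, `labels`.
#' @export
wavelet_decompose <- function(rec, frequencies = 2:45, n_cycles = 7,
                              support_s = 1) {
  if (length(frequencies) == 0L) stop("empty frequency list")
  if (any(frequencies >= rec$fs / 2))
    stop("all frequencies must be below Nyquist (fs/2)")
  n <- nrow(rec$data)
  N <- ncol(rec$data)
  kernels <- lapply(frequencies, make_morlet, fs = rec$fs,
                    n_cycles = n_cycles, support_s = support_s)
  K <- length(kernels[[1L]])
  half <- (K - 1L) %/% 2L
  L <- N + K - 1L
  kf <- lapply(kernels, function(k) fft(c(k, complex(L - K))))
  coef <- array(0i, c(n, length(frequencies), N),
                dimnames = list(rec$labels, NULL, NULL))
  for (i in seq_len(n)) {
    xf <- fft(c(rec$data[i, ], complex(L - N)))
    for (j in seq_along(kf)) {
      full <- fft(xf * kf[[j]], inverse = TRUE) / L
      coef[i, j, ] <- full[(half + 1L):(half + N)]
    }
  }
  valid <- rep(FALSE, N)
  if (N > 2L * half) valid[(half + 1L):(N - half)] <- TRUE
  structure(list(coef = coef, frequencies = as.numeric(frequencies),
                 fs = rec$fs, valid = valid, labels = rec$labels,
                 subject = rec$subject, condition = rec$condition,
                 n_cycles = n_cycles),
            class = "analytic_decomposition")
}

#' @export
print.analytic_decomposition <- function(x, ...) {
  cat(sprintf("<analytic_decomposition> %d channels x %d frequencies x %d samples (%d valid) @ %g Hz\n",
              dim(x$coef)[1L], dim(x$coef)[2L], dim(x$coef)[3L],
              sum(x$valid), x$fs))
  invisible(x)
}

#' Restrict a decomposition to a frequency band
#'
#' Selects the frequencies of the decomposition falling in `band`
#' (inclusive). Band-level connectivity is computed per frequency and then
#' averaged over the selected frequencies, so this returns the restricted
#' decomposition rather than averaging coefficients (averaging complex
#' coefficients across frequencies would distort phase statistics).
#'
#' @param dec an `analytic_decomposition`.
#' @param band numeric `c(lo, hi)` in Hz; default alpha, 8-12 Hz.
#' @return The decomposition restricted to the band frequencies.
#' @export
band_average <- function(dec, band = c(8, 12)) {
  sel <- which(dec$frequencies >= band[1L] & dec$frequencies <= band[2L])
  if (length(sel) == 0L)
    stop("band [", band[1L], ", ", band[2L],
         "] does not intersect the frequency axis")
  dec$coef <- dec$coef[, sel, , drop = FALSE]
  dec$frequencies <- dec$frequencies[sel]
  dec
}

#' Instantaneous power of a decomposition
#' @param dec an `analytic_decomposition`.
#' @param valid_only drop edge-masked samples (default TRUE).
#' @return array channels x frequencies x time of `Mod(z)^2`.
#' @export
decomposition_power <- function(dec, valid_only = TRUE) {
  p <- Mod(dec$coef)^2
  if (valid_only) p <- p[, , dec$valid, drop = FALSE]
  p
}

#' Instantaneous phase of a decomposition
#' @inheritParams decomposition_power
#' @return array channels x frequencies x time of `Arg(z)` in (-pi, pi].
#' @export
decomposition_phase <- function(dec, valid_only = TRUE) {
  ph <- Arg(dec$coef)
  if (valid_only) ph <- ph[, , dec$valid, drop = FALSE]
  ph
}
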