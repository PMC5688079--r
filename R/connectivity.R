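#' Windowed Spearman correlation of two power series
#'
#' Segments both series into non-overlapping windows, rank-transforms each
#' window and computes the Pearson correlation of the ranks (= Spearman's
#' correlation, with average ranks for ties), then returns the arithmetic
#' mean across windows. Windowing trades a little data for a better
#' signal-to-noise ratio of the correlation estimate. A window in which
#' either series is constant has an undefined correlation and is skipped;
#' if fewer than half the windows are usable an error is raised.
#'
#' @param px,py equal-length numeric power series.
#' @param fs sampling rate, Hz.
#' @param window_s window length in seconds (default 5). `Inf` uses a
#'   single window covering the whole series.
#' @return Mean windowed Spearman correlation in \[-1, 1\], with attribute
#'   `n_windows` (windows used).
#' @export
spearman_power <- function(px, py, fs, window_s = 5) {
  if (length(px) != length(py)) stop("series must have equal length")
  if (is.infinite(window_s)) window_s <- length(px) / fs
  wx <- segment_windows(px, fs, window_s)
  wy <- segment_windows(py, fs, window_s)
  rs <- vapply(seq_len(nrow(wx)), function(k) {
    a <- wx[k, ]; b <- wy[k, ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }, numeric(1))
  ok <- !is.na(rs)
  if (sum(ok) < length(rs) / 2)
    stop("more than half of the windows are degenerate (constant series)")
  structure(mean(rs[ok]), n_windows = sum(ok))
}

#' Fisher-Z transform of a correlation coefficient
#'
#' `z = atanh(r)`, which makes the sampling distribution of a correlation
#' approximately normal; used when averaging or testing correlations.
#'
#' @param r correlation in (-1, 1).
#' @return The transformed value.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop("|r| must be < 1 (Fisher-Z is infinite at r = +/-1)")
  atanh(r)
}

#' @rdname fisher_z
#' @param z a Fisher-Z value.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Intersite phase clustering (ISPC)
#'
#' The modulus of the mean unit vector of phase-angle differences,
#' `| n^-1 sum_t exp(i (phi_x(t) - phi_y(t))) |`, also known as R or the
#' phase-locking value: 1 when the phase difference is constant (perfect
#' clustering in polar space), near 0 when differences are uniform.
#' Sensitive to zero-lag (volume-conducted) coupling.
#'
#' @param phix,phiy equal-length phase series in radians.
#' @return Value in \[0, 1\].
#' @export
ispc <- function(phix, phiy) {
  if (length(phix) == 0L) stop("empty phase series")
  if (length(phix) != length(phiy)) stop("series must have equal length")
  Mod(mean(exp(1i * (phix - phiy))))
}

#' Phase-lag index (PLI)
#'
#' The modulus of the time-averaged sign of the imaginary part of the
#' instantaneous cross-spectrum `S_xy(t) = z_x(t) * Conj(z_y(t))`:
#' `| n^-1 sum_t sgn(Im(S_xy(t))) |`. It measures whether phase-angle
#' differences sit consistently on one side of the imaginary axis, so
#' exact zero-lag (volume-conducted) coupling contributes sgn(0) = 0 and
#' is ignored.
#'
#' @param zx,zy equal-length complex analytic series.
#' @return Value in \[0, 1\].
#' @export
pli <- function(zx, zy) {
  if (length(zx) == 0L) stop("empty input")
  if (length(zx) != length(zy)) stop("series must have equal length")
  Mod(mean(sign(Im(zx * Conj(zy)))))
}

measure_names <- c("spearman_power", "ispc", "pli")

#' Pairwise functional connectivity matrix
#'
#' Assembles the channels x channels matrix for one of the three
#' estimators, computed on the valid (edge-unmasked) samples per band
#' frequency and averaged across the band's frequencies. The 5-s windowing
#' applies to the power measure; phase measures use the whole valid series
#' by default (`phase_window_s` enables windowed phase variants). The
#' diagonal is fixed at 0 and excluded from all downstream statistics.
#'
#' @param dec an `analytic_decomposition`.
#' @param measure `"spearman_power"`, `"ispc"` or `"pli"`.
#' @param band frequency band `c(lo, hi)` in Hz (default alpha 8-12).
#' @param window_s power-correlation window, seconds.
#' @param phase_window_s optional window for phase measures (default
#'   `NULL`: whole series).
#' @return A symmetric matrix of class `connectivity_matrix` with
#'   attributes `measure`, `band`, `n_windows`, `labels`.
#' @export
connectivity_matrix <- function(dec, measure = c("spearman_power", "ispc", "pli"),
                                band = c(8, 12), window_s = 5,
                                phase_window_s = NULL) {
  measure <- match.arg(measure)
  bd <- band_average(dec, band)
  n <- dim(bd$coef)[1L]
  if (n < 2L) stop("connectivity needs at least 2 channels")
  nfreq <- dim(bd$coef)[2L]
  acc <- matrix(0, n, n)
  n_windows <- 1L
  for (j in seq_len(nfreq)) {
    z <- bd$coef[, j, bd$valid, drop = TRUE]
    if (is.null(dim(z))) z <- matrix(z, nrow = n)
    if (measure == "spearman_power") {
      mj <- spearman_power_matrix(Mod(z)^2, bd$fs, window_s)
      n_windows <- attr(mj, "n_windows")
    } else if (measure == "ispc") {
      mj <- ispc_matrix(z, bd$fs, phase_window_s)
    } else {
      mj <- pli_mat(z, bd$fs, phase_window_s)
    }
    acc <- acc + mj
  }
  out <- acc / nfreq
  out <- (out + t(out)) / 2
  diag(out) <- 0
  dimnames(out) <- list(bd$labels, bd$labels)
  structure(out, measure = measure, band = band, n_windows = n_windows,
            labels = bd$labels, class = c("connectivity_matrix", "matrix"))
}

# windowed Spearman over all pairs: power (channels x time), mean of
# per-window rank correlations; NA (constant) windows skipped per pair
spearman_power_matrix <- function(p, fs, window_s) {
  wins <- segment_windows(p, fs, window_s)
  n <- nrow(p)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (w in wins) {
    cw <- suppressWarnings(cor(t(w), method = "spearman"))
    ok <- !is.na(cw)
    cw[!ok] <- 0
    acc <- acc + cw
    cnt <- cnt + ok
  }
  if (any(cnt[upper.tri(cnt)] < length(wins) / 2))
    stop("a channel pair has fewer than half its windows usable")
  out <- acc / pmax(cnt, 1L)
  structure(out, n_windows = length(wins))
}

ispc_matrix <- function(z, fs, window_s = NULL) {
  if (is.null(window_s)) {
    u <- exp(1i * Arg(z))
    return(Mod(u %*% Conj(t(u))) / ncol(z))
  }
  wins <- segment_windows(z, fs, window_s)
  Reduce(`+`, lapply(wins, function(w) {
    u <- exp(1i * Arg(w))
    Mod(u %*% Conj(t(u))) / ncol(w)
  })) / length(wins)
}

pli_mat <- function(z, fs, window_s = NULL) {
  if (is.null(window_s)) return(pli_matrix_cpp(z))
  wins <- segment_windows(z, fs, window_s)
  Reduce(`+`, lapply(wins, pli_matrix_cpp)) / length(wins)
}

#' Per-window connectivity matrices
#'
#' Computes one connectivity matrix per non-overlapping window (all three
#' measures applied within the window, averaged over band frequencies).
#' These window-level matrices are the resampling unit for the permutation
#' tests contrasting conditions.
#'
#' @inheritParams connectivity_matrix
#' @param window_s window length, seconds (default 5).
#' @return List of symmetric matrices, one per window, with attributes
#'   `measure`, `band`, `labels`.
#' @export
connectivity_windows <- function(dec, measure = c("spearman_power", "ispc", "pli"),
                                 band = c(8, 12), window_s = 5) {
  measure <- match.arg(measure)
  bd <- band_average(dec, band)
  n <- dim(bd$coef)[1L]
  if (n < 2L) stop("connectivity needs at least 2 channels")
  nfreq <- dim(bd$coef)[2L]
  per_freq <- lapply(seq_len(nfreq), function(j) {
    z <- bd$coef[, j, bd$valid, drop = TRUE]
    if (is.null(dim(z))) z <- matrix(z, nrow = n)
    wins <- segment_windows(z, bd$fs, window_s)
    lapply(wins, function(w) {
      m <- switch(measure,
        spearman_power = {
          cw <- suppressWarnings(cor(t(Mod(w)^2), method = "spearman"))
          cw[is.na(cw)] <- 0
          cw
        },
        ispc = {
          u <- exp(1i * Arg(w))
          Mod(u %*% Conj(t(u))) / ncol(w)
        },
        pli = pli_matrix_cpp(w))
      diag(m) <- 0
      m
    })
  })
  nw <- length(per_freq[[1L]])
  out <- lapply(seq_len(nw), function(k)
    Reduce(`+`, lapply(per_freq, `[[`, k)) / nfreq)
  out <- lapply(out, function(m) {
    dimnames(m) <- list(bd$labels, bd$labels)
    m
  })
  attr(out, "measure") <- measure
  attr(out, "band") <- band
  attr(out, "labels") <- bd$labels
  out
}

#' Per-window channel connectivity strength
#'
#' For each window, each channel's mean connectivity to all other channels
#' (off-diagonal row mean of the window's connectivity matrix). This is
#' the per-channel summary fed to the window-level permutation test.
#'
#' @inheritParams connectivity_windows
#' @return Matrix windows x channels.
#' @export
channel_strength_windows <- function(dec, measure = c("spearman_power", "ispc", "pli"),
                                     band = c(8, 12), window_s = 5) {
  wins <- connectivity_windows(dec, measure, band, window_s)
  n <- nrow(wins[[1L]])
  out <- t(vapply(wins, function(m) rowSums(m) / (n - 1L), numeric(n)))
  colnames(out) <- attr(wins, "labels")
  out
}
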