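#' Describe an electrode array
#'
#' Specification of one implanted array: a subdural `grid` (rows x cols),
#' a subdural `strip` or a `depth` electrode (both linear). Coordinates are
#' generated in millimetres from `origin` along the given axes; adjacent
#' contacts are separated by `spacing_mm` (10 mm is the typical subdural
#' inter-electrode spacing).
#'
#' @param kind `"grid"`, `"strip"` or `"depth"`.
#' @param n_contacts contact count; for a grid, a length-2 vector
#'   `c(rows, cols)`.
#' @param spacing_mm inter-contact distance in mm (> 0).
#' @param origin length-3 numeric, position of the first contact (mm).
#' @param axes 3 x 2 matrix of unit direction vectors (grid uses both
#'   columns, strip/depth the first). Defaults to the x/y axes.
#' @param region implant region code: one of H, T, F, IH, FP, Grid, D.
#' @param laterality L, R or B.
#' @param label_prefix prefix for generated channel labels.
#' @return A `layout_spec` object.
#' @export
layout_spec <- function(kind = c("grid", "strip", "depth"),
                        n_contacts,
                        spacing_mm = 10,
                        origin = c(0, 0, 0),
                        axes = cbind(c(1, 0, 0), c(0, 1, 0)),
                        region = c("H", "T", "F", "IH", "FP", "Grid", "D"),
                        laterality = c("L", "R", "B"),
                        label_prefix = NULL) {
  kind <- match.arg(kind)
  region <- match.arg(region)
  laterality <- match.arg(laterality)
  n_contacts <- as.integer(n_contacts)
  if (any(n_contacts <= 0L))
    stop("invalid layout spec: contact counts must be positive")
  if (kind == "grid" && length(n_contacts) != 2L)
    stop("invalid layout spec: a grid needs c(rows, cols)")
  if (kind != "grid" && length(n_contacts) != 1L)
    stop("invalid layout spec: strip/depth need a single contact count")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("invalid layout spec: spacing_mm must be > 0")
  if (is.null(label_prefix))
    label_prefix <- paste0(substr(region, 1, 1), substr(kind, 1, 1))
  structure(list(kind = kind, n_contacts = n_contacts,
                 spacing_mm = spacing_mm, origin = as.numeric(origin),
                 axes = axes, region = region, laterality = laterality,
                 label_prefix = label_prefix),
            class = "layout_spec")
}

#' Generate electrode coordinates from an array specification
#'
#' @param spec a [layout_spec()], or a list of them (arrays are
#'   concatenated into one layout, as in a multi-array implant).
#' @return An `electrode_layout` data.frame (label, x_mm, y_mm, z_mm,
#'   region, laterality).
#' @export
make_layout <- function(spec) {
  if (is.list(spec) && !inherits(spec, "layout_spec")) {
    parts <- lapply(spec, make_layout)
    out <- do.call(rbind, lapply(parts, as.data.frame))
    if (anyDuplicated(out$label))
      out$label <- make.unique(out$label, sep = "_")
    return(as_electrode_layout(out))
  }
  u <- spec$axes[, 1L] / sqrt(sum(spec$axes[, 1L]^2))
  if (spec$kind == "grid") {
    v <- spec$axes[, 2L] / sqrt(sum(spec$axes[, 2L]^2))
    idx <- expand.grid(row = seq_len(spec$n_contacts[1L]),
                       col = seq_len(spec$n_contacts[2L]))
    xyz <- t(spec$origin +
               outer(u, (idx$row - 1) * spec$spacing_mm) +
               outer(v, (idx$col - 1) * spec$spacing_mm))
    labels <- sprintf("%s%d_%d", spec$label_prefix, idx$row, idx$col)
  } else {
    k <- seq_len(spec$n_contacts)
    xyz <- t(spec$origin + outer(u, (k - 1) * spec$spacing_mm))
    labels <- sprintf("%s%d", spec$label_prefix, k)
  }
  as_electrode_layout(data.frame(
    label = labels, x_mm = xyz[, 1L], y_mm = xyz[, 2L], z_mm = xyz[, 3L],
    region = spec$region, laterality = spec$laterality,
    stringsAsFactors = FALSE))
}

#' Configuration of the synthetic two-condition iEEG generator
#'
#' The generator emulates 3-minute eyes-closed (EC) / eyes-open (EO)
#' resting-state blocks: a narrow-band alpha oscillation riding on 1/f^beta
#' background noise, with inter-channel coupling produced by mixing each
#' channel's oscillator with a shared driver. Coupling and alpha power are
#' set per condition; the defaults encode the alpha-desynchronization
#' contrast (stronger alpha coupling and power with eyes closed).
#'
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz. The clinical rate is not standardized;
#'   500 Hz is the default.
#' @param duration_s seconds per condition (180 = the 3-minute blocks).
#' @param band_center alpha oscillation frequency in Hz.
#' @param coupling named list with `EC` and `EO` entries; each is either a
#'   scalar in \[0,1\] (uniform off-diagonal coupling) or an
#'   n x n symmetric matrix with zero diagonal and entries in \[0,1\].
#' @param alpha_power_scale named list `EC`/`EO` of non-negative scalars
#'   multiplying the alpha oscillation amplitude.
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param phase_jitter_sd phase-diffusion rate of each oscillator in
#'   rad/sqrt(s); sets the alpha linewidth and how fast uncoupled channels
#'   decorrelate.
#' @param amplitude_uv overall output scale in microvolts.
#' @param seed integer master seed; all randomness derives from it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_channels = 8,
                             fs = 500,
                             duration_s = 180,
                             band_center = 10,
                             coupling = list(EC = 0.8, EO = 0.2),
                             alpha_power_scale = list(EC = 2.0, EO = 1.0),
                             noise_exponent = 1,
                             phase_jitter_sd = 1.5,
                             amplitude_uv = 20,
                             seed = 1L) {
  n <- as.integer(n_channels)
  if (n <= 0L) stop("n_channels must be positive")
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("duration_s * fs must be a positive integer")
  cp <- lapply(coupling, expand_coupling, n = n)
  if (!all(c("EC", "EO") %in% names(cp)))
    stop("coupling must have EC and EO entries")
  aps <- alpha_power_scale
  if (!all(c("EC", "EO") %in% names(aps)) ||
      any(unlist(aps) < 0))
    stop("alpha_power_scale must have non-negative EC and EO entries")
  structure(list(n_channels = n, fs = fs, duration_s = duration_s,
                 band_center = band_center, coupling = cp,
                 alpha_power_scale = aps, noise_exponent = noise_exponent,
                 phase_jitter_sd = phase_jitter_sd,
                 amplitude_uv = amplitude_uv, seed = as.integer(seed)),
            class = "synthetic_config")
}

expand_coupling <- function(cc, n) {
  if (is.matrix(cc)) {
    if (nrow(cc) != n || ncol(cc) != n)
      stop("coupling matrix must be n_channels x n_channels")
    if (max(abs(cc - t(cc))) > 1e-12)
      stop("coupling matrix must be symmetric")
    if (any(diag(cc) != 0)) stop("coupling diagonal must be zero")
    if (any(cc < 0) || any(cc > 1)) stop("coupling entries must be in [0,1]")
    return(cc)
  }
  if (!is.numeric(cc) || length(cc) != 1L || cc < 0 || cc > 1)
    stop("scalar coupling must be in [0,1]")
  m <- matrix(cc, n, n)
  diag(m) <- 0
  m
}

# deterministic child-seed arithmetic: one master seed expands to
# per-subject, per-condition streams (kept below 2^31)
child_seed <- function(seed, subject_idx = 0L, condition = "EC") {
  cond_idx <- if (condition == "EC") 1L else 2L
  as.integer((as.double(seed) * 1009 + subject_idx * 13 + cond_idx) %%
               2147483629)
}

# complex narrow-band oscillator: amplitude-modulated phase-diffusing
# carrier at f0; jitter_sd in rad/sqrt(s)
narrowband_oscillator <- function(n_samp, fs, f0, jitter_sd) {
  t <- seq_len(n_samp) / fs
  psi <- cumsum(rnorm(n_samp, 0, jitter_sd / sqrt(fs)))
  # smooth positive amplitude modulation (~1 s autocorrelation)
  rho <- exp(-1 / (1.0 * fs))
  a <- as.numeric(stats::filter(rnorm(n_samp), rho, method = "recursive"))
  a <- a * sqrt(1 - rho^2)
  amp <- 1 + 0.5 * a
  amp[amp < 0.1] <- 0.1
  amp * exp(1i * (2 * pi * f0 * t + psi))
}

# 1/f^beta noise by spectral shaping, unit standard deviation
colored_noise <- function(n_samp, fs, beta) {
  white <- rnorm(n_samp)
  if (beta == 0) return(white)
  sp <- fft(white)
  freq <- c(0, seq_len(n_samp - 1)) * fs / n_samp
  freq <- pmin(freq, fs - freq)            # two-sided axis
  scale <- ifelse(freq > 0, freq^(-beta / 2), 0)
  x <- Re(fft(sp * scale, inverse = TRUE)) / n_samp
  x / sd(x)
}

#' Simulate one condition block
#'
#' Channels are built as coupled narrow-band alpha oscillators over
#' 1/f^beta noise. Each channel mixes a shared complex driver (weight
#' `w_i = sqrt(max_j C_ij)` from the condition's coupling matrix `C`) with
#' an independent oscillator of its own, so phase jitter relative to the
#' driver decreases as coupling grows; a fixed per-channel phase lag makes
#' the coupling detectable by lag-sensitive measures. Deterministic given
#' the config seed.
#'
#' @param config a [synthetic_config()].
#' @param condition `"EC"` or `"EO"`.
#' @param labels optional channel labels (default CH01..).
#' @param subject subject id stored in the recording.
#' @param subject_idx integer used in child-seed derivation.
#' @return A [recording()].
#' @export
simulate_recording <- function(config, condition = c("EC", "EO"),
                               labels = NULL, subject = "S01",
                               subject_idx = 0L) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config")
  if (!is.character(condition) || !(condition[1L] %in% c("EC", "EO")))
    stop("unknown condition label: ", condition[1L])
  condition <- condition[1L]
  n <- config$n_channels
  n_samp <- as.integer(round(config$duration_s * config$fs))
  C <- config$coupling[[condition]]
  a_scale <- config$alpha_power_scale[[condition]]

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(child_seed(config$seed, subject_idx, condition))

  w <- if (n > 1) sqrt(apply(C, 1L, max)) else 0
  theta <- runif(n, 0.2, 1.2)              # fixed per-channel lag, rad
  driver <- narrowband_oscillator(n_samp, config$fs, config$band_center,
                                  config$phase_jitter_sd)
  data <- matrix(0, n, n_samp)
  for (i in seq_len(n)) {
    own <- narrowband_oscillator(n_samp, config$fs, config$band_center,
                                 config$phase_jitter_sd)
    zi <- w[i] * driver * exp(1i * theta[i]) + sqrt(1 - w[i]^2) * own
    alpha <- a_scale * Re(zi) / sqrt(2)    # unit-RMS oscillator
    noise <- colored_noise(n_samp, config$fs, config$noise_exponent)
    data[i, ] <- config$amplitude_uv * (alpha + noise)
  }
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(n))
  recording(data, config$fs, labels, subject, condition)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Electrode array specifications for a heterogeneous 11-subject cohort
#'
#' Mirrors the implant categories of a typical mesial-temporal-lobe
#' epilepsy cohort: every subject has depth electrodes (mostly
#' hippocampal), most have temporal strips, some frontal/interhemispheral/
#' frontal-polar strips, and two subjects carry an 8 x 8 subdural grid.
#' Layouts differ across subjects.
#'
#' @return A named list of 11 per-subject lists of [layout_spec()]s.
#' @export
default_cohort_specs <- function() {
  strip <- function(n, region, lat, origin, dir = c(1, 0, 0), prefix = NULL)
    layout_spec("strip", n, 10, origin, cbind(dir, c(0, 0, 1)),
                region, lat, label_prefix = prefix)
  depth <- function(n, region, lat, origin, dir = c(0, 0, 1), prefix = NULL)
    layout_spec("depth", n, 10, origin, cbind(dir, c(0, 1, 0)),
                region, lat, label_prefix = prefix)
  grid8 <- function(lat, origin)
    layout_spec("grid", c(8, 8), 10, origin,
                cbind(c(1, 0, 0), c(0, 1, 0)), "Grid", lat)
  list(
    S01 = list(depth(4, "H", "L", c(-30, -20, -10), prefix = "HL"),
               depth(4, "H", "R", c(30, -20, -10), prefix = "HR"),
               strip(6, "T", "L", c(-60, -30, 0), prefix = "TL"),
               strip(4, "T", "R", c(60, -30, 0), prefix = "TR")),
    S02 = list(depth(4, "H", "L", c(-30, -20, -10)),
               strip(4, "T", "L", c(-60, -30, 0)),
               strip(4, "F", "L", c(-40, 40, 20)),
               strip(4, "IH", "B", c(0, 10, 50), dir = c(0, 1, 0))),
    S03 = list(depth(4, "H", "R", c(30, -20, -10)),
               strip(4, "T", "R", c(60, -30, 0)),
               strip(4, "F", "R", c(40, 40, 20)),
               strip(4, "IH", "B", c(0, 10, 50), dir = c(0, 1, 0))),
    S04 = list(strip(4, "FP", "B", c(0, 60, 10)),
               strip(4, "IH", "B", c(0, 10, 50), dir = c(0, 1, 0)),
               strip(4, "F", "L", c(-40, 40, 20)),
               depth(4, "D", "L", c(-25, 0, -5))),
    S05 = list(depth(4, "H", "L", c(-30, -20, -10), prefix = "HL"),
               depth(4, "H", "R", c(30, -20, -10), prefix = "HR"),
               strip(6, "T", "L", c(-60, -30, 0))),
    S06 = list(depth(4, "H", "L", c(-30, -20, -10)),
               strip(6, "T", "L", c(-60, -30, 0)),
               strip(4, "T", "R", c(60, -30, 0), prefix = "TR")),
    S07 = list(grid8("L", c(-70, -40, 10)),
               depth(4, "D", "L", c(-25, 0, -5))),
    S08 = list(depth(4, "H", "R", c(30, -20, -10)),
               strip(4, "FP", "R", c(20, 60, 10)),
               strip(4, "F", "R", c(40, 40, 20)),
               strip(4, "IH", "B", c(0, 10, 50), dir = c(0, 1, 0)),
               strip(4, "T", "R", c(60, -30, 0))),
    S09 = list(depth(4, "H", "L", c(-30, -20, -10), prefix = "HL"),
               depth(4, "H", "R", c(30, -20, -10), prefix = "HR"),
               strip(4, "T", "L", c(-60, -30, 0))),
    S10 = list(grid8("R", c(10, -40, 10)),
               depth(4, "D", "R", c(25, 0, -5))),
    S11 = list(depth(4, "H", "R", c(30, -20, -10)),
               strip(4, "FP", "R", c(20, 60, 10)),
               strip(4, "F", "R", c(40, 40, 20)),
               strip(4, "T", "R", c(60, -30, 0)))
  )
}

#' Generate a synthetic cohort
#'
#' One (layout, EC recording, EO recording) triple per subject. Layouts may
#' differ across subjects (heterogeneous implants); within a subject both
#' conditions share the layout. The master seed expands to per-subject,
#' per-condition child seeds by fixed arithmetic, so any subject/condition
#' is reproducible in isolation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param specs list of per-subject [layout_spec()] lists; defaults to the
#'   first `n_subjects` entries of [default_cohort_specs()] (recycled if
#'   more subjects are requested).
#' @param config template [synthetic_config()]; `n_channels` is replaced by
#'   each subject's contact count and `seed` by the child seed.
#' @param seed master seed (defaults to `config$seed`).
#' @return A list of subjects, each `list(layout, EC, EO)`.
#' @export
make_cohort <- function(n_subjects = 11,
                        specs = NULL,
                        config = synthetic_config(),
                        seed = config$seed) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (is.null(specs)) {
    all_specs <- default_cohort_specs()
    specs <- all_specs[((seq_len(n_subjects) - 1L) %% length(all_specs)) + 1L]
  }
  if (length(specs) != n_subjects)
    stop("need one spec list per subject")
  out <- vector("list", n_subjects)
  names(out) <- sprintf("S%02d", seq_len(n_subjects))
  for (s in seq_len(n_subjects)) {
    layout <- make_layout(specs[[s]])
    cfg <- config
    cfg$n_channels <- nrow(layout)
    cfg$coupling <- lapply(config$coupling, function(cc)
      expand_coupling(if (is.matrix(cc)) cc[1L, 2L] else cc, nrow(layout)))
    cfg$seed <- seed
    sid <- names(out)[s]
    out[[s]] <- list(
      layout = layout,
      EC = simulate_recording(cfg, "EC", layout$label, sid, s),
      EO = simulate_recording(cfg, "EO", layout$label, sid, s))
  }
  out
}
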