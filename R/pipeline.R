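#' Write a labelled square matrix as a tab-separated table
#'
#' Channel labels form the header row and first column; values are written
#' with 12 significant digits (so reruns are byte-identical). A JSON
#' sidecar `<path>.json` records the measure, band and any extra metadata.
#'
#' @param m labelled square matrix (connectivity, distance or wiring cost).
#' @param path output `.tsv` path.
#' @param meta named list of extra sidecar fields.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, meta = list()) {
  labs <- rownames(m)
  if (is.null(labs)) labs <- sprintf("CH%02d", seq_len(nrow(m)))
  txt <- apply(unclass(m), 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  lines <- c(paste(c("label", labs), collapse = "\t"),
             paste(labs, txt, sep = "\t"))
  writeLines(lines, path)
  side <- c(list(labels = labs,
                 measure = attr(m, "measure"),
                 band = attr(m, "band"),
                 n_windows = attr(m, "n_windows")),
            meta)
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path `.tsv` path.
#' @return Labelled numeric matrix; sidecar fields (if present) are
#'   attached as attributes.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(labs, labs)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    for (f in setdiff(names(side), "labels")) attr(m, f) <- side[[f]]
  }
  m
}

#' Write a synthetic cohort to disk
#'
#' One EDF file per subject and condition (`SXX_EC.edf`, `SXX_EO.edf`) and
#' one tab-separated layout per subject (`SXX_layout.tsv`).
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort)) {
    write_layout(cohort[[sid]]$layout, file.path(dir, paste0(sid, "_layout.tsv")))
    write_edf(cohort[[sid]]$EC, file.path(dir, paste0(sid, "_EC.edf")))
    write_edf(cohort[[sid]]$EO, file.path(dir, paste0(sid, "_EO.edf")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `SXX_layout.tsv` and `SXX_{EC,EO}.edf`.
#' @return A cohort list as produced by [make_cohort()].
#' @export
read_cohort <- function(dir) {
  lay_files <- sort(list.files(dir, "_layout\\.tsv$", full.names = TRUE))
  if (length(lay_files) == 0L) stop("no layout files found in ", dir)
  out <- list()
  for (lf in lay_files) {
    sid <- sub("_layout\\.tsv$", "", basename(lf))
    layout <- read_layout(lf)
    ec_path <- file.path(dir, paste0(sid, "_EC.edf"))
    eo_path <- file.path(dir, paste0(sid, "_EO.edf"))
    if (!file.exists(ec_path)) stop("missing EDF file: ", ec_path)
    if (!file.exists(eo_path)) stop("missing EDF file: ", eo_path)
    ec <- read_edf(ec_path, "EC")
    eo <- read_edf(eo_path, "EO")
    for (r in list(ec, eo)) {
      bad <- setdiff(r$labels, layout$label)
      if (length(bad))
        stop("EDF channels absent from layout for ", sid, ": ",
             paste(bad, collapse = ", "))
    }
    out[[sid]] <- list(layout = layout, EC = ec, EO = eo)
  }
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. With
#' `input_dir = NULL` a synthetic cohort is generated; otherwise layouts
#' and EDF recordings are read from `input_dir` (files as written by
#' [write_cohort()]).
#'
#' @param out_dir output directory for the result tree.
#' @param input_dir optional directory of recorded data.
#' @param n_subjects,fs,duration_s,coupling,alpha_power_scale,seed
#'   synthetic-cohort settings (see [synthetic_config()]).
#' @param specs optional per-subject layout specs (see [make_cohort()]).
#' @param band analysis band in Hz (alpha, 8-12, by default); the
#'   frequency axis is `seq(band[1], band[2])` in 1 Hz steps.
#' @param n_cycles Morlet wavelet cycles.
#' @param measures connectivity measures to compute.
#' @param curve_measures measures for which the filtration curve test is
#'   run (default power-based, the measure carried forward to network
#'   analysis).
#' @param window_s power-correlation window, seconds.
#' @param low_hz,high_hz,notch_hz filtering chain settings.
#' @param rule filtration rule.
#' @param filtrate_on `"wiring"` or `"connectivity"`.
#' @param grid_size curve-test threshold grid size.
#' @param n_perm_channel,n_perm_curve permutation counts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            n_subjects = 11,
                            specs = NULL,
                            fs = 500,
                            duration_s = 180,
                            coupling = list(EC = 0.8, EO = 0.2),
                            alpha_power_scale = list(EC = 2.0, EO = 1.0),
                            band = c(8, 12),
                            n_cycles = 7,
                            measures = c("spearman_power", "ispc", "pli"),
                            curve_measures = "spearman_power",
                            window_s = 5,
                            low_hz = 0.5, high_hz = 70, notch_hz = 60,
                            rule = "sublevel",
                            filtrate_on = "wiring",
                            grid_size = 100,
                            n_perm_channel = 999,
                            n_perm_curve = 199,
                            seed = 1L) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  measures <- match.arg(measures, several.ok = TRUE)
  stopifnot(all(curve_measures %in% measures))
  cfg <- list(out_dir = out_dir, input_dir = input_dir,
              n_subjects = n_subjects, specs = specs, fs = fs,
              duration_s = duration_s, coupling = coupling,
              alpha_power_scale = alpha_power_scale, band = band,
              n_cycles = n_cycles, measures = measures,
              curve_measures = curve_measures, window_s = window_s,
              low_hz = low_hz, high_hz = high_hz, notch_hz = notch_hz,
              rule = rule, filtrate_on = filtrate_on,
              grid_size = grid_size, n_perm_channel = n_perm_channel,
              n_perm_curve = n_perm_curve, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full two-condition analysis pipeline
#'
#' For each subject and condition: zero-phase filtering, Morlet
#' decomposition over the band frequencies, connectivity matrices for each
#' measure, wiring-cost matrices, fixed-threshold (mean + SD) network
#' metric vectors and their EC - EO difference, the full threshold
#' filtration and its difference curves, per-channel/per-region
#' permutation tests, and the filtration curve permutation test. Results
#' are written as tab-separated tables and JSON under `config$out_dir`; a
#' manifest records all parameters. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the cohort-level tables: `channel_tests`
#'   (per measure), `curve_tests`, `metric_differences`, and summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$input_dir)) {
    template <- synthetic_config(
      n_channels = 2, fs = config$fs, duration_s = config$duration_s,
      coupling = config$coupling,
      alpha_power_scale = config$alpha_power_scale, seed = config$seed)
    cohort <- make_cohort(config$n_subjects, config$specs, template,
                          seed = config$seed)
  } else {
    cohort <- read_cohort(config$input_dir)
  }

  freqs <- seq(config$band[1L], config$band[2L])
  channel_rows <- list()
  region_rows <- list()
  curve_rows <- list()
  diff_rows <- list()

  for (sid in names(cohort)) {
    sub <- cohort[[sid]]
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    write_layout(sub$layout, file.path(sdir, "layout.tsv"))
    D <- distance_matrix(sub$layout)
    write_matrix_tsv(D, file.path(sdir, "distance.tsv"))

    dec <- list()
    for (cond in c("EC", "EO")) {
      filt <- bandpass_notch(sub[[cond]], config$low_hz, config$high_hz,
                             config$notch_hz)
      dec[[cond]] <- wavelet_decompose(filt, freqs, config$n_cycles)
    }

    for (meas in config$measures) {
      Fm <- list(); Wm <- list(); met <- list(); filt_res <- list()
      wins <- list(); strength <- list()
      for (cond in c("EC", "EO")) {
        Fm[[cond]] <- connectivity_matrix(dec[[cond]], meas, config$band,
                                          config$window_s)
        Wm[[cond]] <- wiring_cost(D, Fm[[cond]])
        write_matrix_tsv(Fm[[cond]],
                         file.path(sdir, sprintf("connectivity_%s_%s.tsv", meas, cond)))
        write_matrix_tsv(Wm[[cond]],
                         file.path(sdir, sprintf("wiringcost_%s_%s.tsv", meas, cond)))
        net <- threshold_fixed(Fm[[cond]])
        met[[cond]] <- compute_metrics(net)
        filt_res[[cond]] <- filtrate(
          if (config$filtrate_on == "wiring") Wm[[cond]] else Fm[[cond]],
          D = NULL, rule = config$rule)
        wins[[cond]] <- connectivity_windows(dec[[cond]], meas, config$band,
                                             config$window_s)
        ns <- nrow(wins[[cond]][[1L]])
        strength[[cond]] <- t(vapply(wins[[cond]], function(m)
          rowSums(m) / (ns - 1L), numeric(ns)))
        colnames(strength[[cond]]) <- sub$layout$label
      }
      mdiff <- condition_difference(met$EC, met$EO)
      jsonlite::write_json(
        list(subject = sid, measure = meas,
             EC = as.list(met$EC), EO = as.list(met$EO),
             difference = as.list(mdiff)),
        file.path(sdir, sprintf("metrics_%s.json", meas)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      diff_rows[[paste(sid, meas)]] <-
        data.frame(subject = sid, measure = meas,
                   metric = names(mdiff), difference = unname(mdiff),
                   stringsAsFactors = FALSE)

      fd <- filtration_difference(filt_res$EC, filt_res$EO)
      write_filtration_tsv(filt_res, fd,
                           file.path(sdir, sprintf("filtration_%s.tsv", meas)))

      ct <- channel_condition_test(strength$EC, strength$EO,
                                   n_perm = config$n_perm_channel,
                                   seed = child_seed(config$seed, match(sid, names(cohort)), "EC"),
                                   layout = sub$layout)
      write.table(format_df(ct), file.path(sdir, sprintf("channel_test_%s.tsv", meas)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      channel_rows[[paste(sid, meas)]] <-
        cbind(subject = sid, measure = meas, as.data.frame(ct))
      rt <- attr(ct, "regions")
      region_rows[[paste(sid, meas)]] <-
        cbind(subject = sid, measure = meas, rt)

      if (meas %in% config$curve_measures) {
        cv <- curve_condition_test(wins$EC, wins$EO, D,
                                   on = config$filtrate_on,
                                   rule = config$rule,
                                   grid_size = config$grid_size,
                                   n_perm = config$n_perm_curve,
                                   seed = child_seed(config$seed, match(sid, names(cohort)), "EO"))
        write.table(format_df(cv), file.path(sdir, sprintf("curve_test_%s.tsv", meas)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        curve_rows[[paste(sid, meas)]] <-
          cbind(subject = sid, measure = meas, as.data.frame(cv))
      }
    }
    rm(dec)
  }

  channel_tests <- do.call(rbind, unname(channel_rows))
  region_tests <- do.call(rbind, unname(region_rows))
  curve_tests <- do.call(rbind, unname(curve_rows))
  metric_differences <- do.call(rbind, unname(diff_rows))

  for (meas in config$measures) {
    rt <- region_tests[region_tests$measure == meas, ]
    write.table(format_df(rt),
                file.path(out_dir, sprintf("cohort_region_tests_%s.tsv", meas)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(format_df(curve_tests), file.path(out_dir, "cohort_curve_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format_df(metric_differences),
              file.path(out_dir, "cohort_metric_differences.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "restwire",
    version = as.character(utils::packageVersion("restwire")),
    parameters = config[setdiff(names(config),
                                c("specs", "out_dir", "input_dir"))],
    subjects = names(cohort),
    files = sort(list.files(out_dir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(channel_tests = channel_tests,
                 region_tests = region_tests,
                 curve_tests = curve_tests,
                 metric_differences = metric_differences,
                 out_dir = out_dir))
}

# long-format filtration table: threshold, metric, value per condition,
# plus the EC - EO difference on the union grid
write_filtration_tsv <- function(filt_res, fd, path) {
  rows <- character(0)
  hdr <- "condition\tthreshold\tmetric\tvalue"
  for (cond in names(filt_res)) {
    fr <- filt_res[[cond]]
    for (mi in seq_len(ncol(fr$metrics))) {
      rows <- c(rows, paste(cond, fmt_num(fr$thresholds),
                            colnames(fr$metrics)[mi],
                            fmt_num(fr$metrics[, mi]), sep = "\t"))
    }
  }
  for (mi in seq_len(ncol(fd$difference))) {
    rows <- c(rows, paste("EC-EO", fmt_num(fd$thresholds),
                          colnames(fd$difference)[mi],
                          fmt_num(fd$difference[, mi]), sep = "\t"))
  }
  writeLines(c(hdr, rows), path)
}

# format numeric columns for deterministic text output
format_df <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  df
}
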