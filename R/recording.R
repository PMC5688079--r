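#' Construct a multichannel recording
#'
#' A `recording` is the basic container for one subject/condition block of
#' intracranial EEG: a channels x samples real matrix with its sampling
#' rate, channel labels, subject id and condition tag (`"EC"` eyes closed,
#' `"EO"` eyes open). Values are nominally in microvolts.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (positive).
#' @param labels character vector of unique channel labels, one per row.
#' @param subject subject identifier.
#' @param condition condition label, `"EC"` or `"EO"`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels = rownames(data),
                      subject = "S01", condition = c("EC", "EO")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("recording data must be a finite numeric matrix with no NaN")
  if (is.null(labels))
    labels <- sprintf("CH%02d", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("need one label per channel")
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels,
         subject = as.character(subject), condition = condition),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, condition %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec a [recording()].
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read an electrode coordinate table
#'
#' Layouts are tab-separated tables with columns `label`, `x_mm`, `y_mm`,
#' `z_mm`, `region`, `laterality`. Regions follow the implant categories
#' hippocampus (H), temporal (T), frontal (F), interhemispheral (IH),
#' frontal polar (FP), Grid and depth (D); laterality is L/R/B.
#'
#' @param path file path of the tab-separated layout.
#' @return A `data.frame` of class `electrode_layout`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("layout file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("label", "x_mm", "y_mm", "z_mm", "region", "laterality")
  if (!all(need %in% header))
    stop("layout header must contain: ", paste(need, collapse = ", "))
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    names(f) <- header[seq_along(f)]
    for (col in c("x_mm", "y_mm", "z_mm")) {
      v <- suppressWarnings(as.numeric(f[[col]]))
      if (is.na(v))
        stop(sprintf("non-numeric coordinate '%s' in column %s at line %d of %s",
                     f[[col]], col, i, path))
    }
    f
  })
  df <- data.frame(
    label      = vapply(rows, `[[`, "", "label"),
    x_mm       = as.numeric(vapply(rows, `[[`, "", "x_mm")),
    y_mm       = as.numeric(vapply(rows, `[[`, "", "y_mm")),
    z_mm       = as.numeric(vapply(rows, `[[`, "", "z_mm")),
    region     = vapply(rows, `[[`, "", "region"),
    laterality = vapply(rows, `[[`, "", "laterality"),
    stringsAsFactors = FALSE)
  as_electrode_layout(df)
}

#' Write an electrode coordinate table
#' @param layout an `electrode_layout` data.frame.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  df <- layout
  df$x_mm <- fmt_num(df$x_mm)
  df$y_mm <- fmt_num(df$y_mm)
  df$z_mm <- fmt_num(df$z_mm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_electrode_layout <- function(df) {
  if (anyDuplicated(df$label)) stop("electrode labels must be unique")
  if (any(!is.finite(df$x_mm)) || any(!is.finite(df$y_mm)) ||
      any(!is.finite(df$z_mm)))
    stop("electrode coordinates must be finite")
  class(df) <- c("electrode_layout", "data.frame")
  df
}

# fixed-width numeric formatting used by all text writers so that reruns
# are byte-identical
fmt_num <- function(x) sprintf("%.12g", x)
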