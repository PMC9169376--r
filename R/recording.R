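#' Labeled acceleration recording
#'
#' A `recording` is the canonical container for an accelerometer magnitude
#' trace with per-sample state labels, as produced by the logging program
#' during a lithotripsy session (or by the simulator). Labels are stored per
#' sample rather than per interval so that window purity can be checked
#' sample-by-sample during segmentation.
#'
#' @param samples Numeric vector of acceleration magnitudes (device units).
#' @param labels Integer vector of state codes in `{0, 1, 2}`, same length
#'   as `samples`. A single code is recycled.
#' @param sampling_rate_hz Sampling rate in Hz; the logging hardware records
#'   at 100 samples per second, the default.
#' @param meta Optional named list of provenance (source file, simulator
#'   seed or configuration).
#' @return An object of class `recording`: a list with elements `samples`,
#'   `labels`, `sampling_rate_hz` and `meta`.
#' @seealso [read_recording()], [write_recording()], [segment_recording()]
#' @examples
#' rec <- recording(rnorm(200), labels = 0, sampling_rate_hz = 100)
#' length(rec$samples)
#' @export
recording <- function(samples, labels, sampling_rate_hz = 100, meta = list()) {
  samples <- as.numeric(samples)
  if (length(labels) == 1L) labels <- rep(labels, length(samples))
  labels <- as.integer(labels)
  if (length(labels) != length(samples)) {
    stop("labels must have the same length as samples (",
         length(labels), " vs ", length(samples), ")")
  }
  check_label_codes(labels)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      is.na(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number")
  }
  structure(
    list(samples = samples, labels = labels,
         sampling_rate_hz = as.numeric(sampling_rate_hz), meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<recording> %d samples @ %g Hz (%.1f s)\n",
              n, x$sampling_rate_hz, n / x$sampling_rate_hz))
  if (n > 0L) {
    tab <- table(factor(x$labels, levels = 0:2, labels = names(state_labels())))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$samples)

# Canonical column names for the logging formats (case-insensitive on read).
.rec_columns <- c(time = "t_ms", magnitude = "magnitude", label = "label")

#' Read a labeled recording from disk
#'
#' Reads a logged trace in the CSV or XLSX logging layout: a header row with
#' columns `t_ms` (optional), `magnitude` and `label` (case-insensitive),
#' one row per sample. CSV is the canonical dialect; XLSX (first worksheet,
#' same columns) mirrors the spreadsheet export of the logging program and
#' requires the `readxl` package.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"xlsx"`; defaults to the file extension.
#' @param sampling_rate_hz Sampling rate to record; the file format carries
#'   no rate metadata, so the logging default of 100 Hz is assumed.
#' @return A [recording()]; `meta$source` holds the path.
#' @export
read_recording <- function(path, dialect = c("csv", "xlsx"),
                           sampling_rate_hz = 100) {
  if (missing(dialect)) {
    dialect <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (dialect == "csv") {
    if (file.size(path) == 0L) stop("format error: empty file: ", path)
    utils::read.csv(path, check.names = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the 'readxl' package")
    }
    as.data.frame(readxl::read_excel(path, sheet = 1L))
  }
  cols <- tolower(names(df))
  pick <- function(name, required = TRUE) {
    i <- match(name, cols)
    if (is.na(i)) {
      if (required) stop("format error: missing column '", name, "' in ", path)
      return(NULL)
    }
    v <- df[[i]]
    if (nrow(df) == 0L) return(numeric(0))  # header-only file
    if (!is.numeric(v)) {
      stop("format error: column '", name, "' is not numeric in ", path)
    }
    v
  }
  mag <- pick("magnitude")
  lab <- pick("label")
  if (any(lab != as.integer(lab), na.rm = TRUE)) {
    stop("format error: column 'label' contains non-integer values in ", path)
  }
  recording(mag, as.integer(lab), sampling_rate_hz = sampling_rate_hz,
            meta = list(source = path, dialect = dialect))
}

#' Write a labeled recording to disk
#'
#' Writes the CSV logging layout `t_ms,magnitude,label` (UTF-8, `.` decimal
#' separator), one row per sample, readable back by [read_recording()].
#' Magnitudes are written with 17 significant digits so the write/read
#' round trip is lossless to double precision. Only the CSV dialect is
#' supported for writing; XLSX is read-only.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param dialect Must be `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = "csv") {
  stopifnot(inherits(rec, "recording"))
  dialect <- match.arg(dialect, "csv")
  n <- length(rec$samples)
  t_ms <- if (n > 0L) (seq_len(n) - 1L) * 1000 / rec$sampling_rate_hz else numeric(0)
  df <- data.frame(t_ms = t_ms,
                   magnitude = sprintf("%.17g", rec$samples),
                   label = rec$labels)
  if (n == 0L) df <- df[0L, , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
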