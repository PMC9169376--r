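# Shared fixtures, built in code.

# Bare segment from a numeric vector (bypasses segmentation).
make_segment <- function(values, label = 0L, fs = 100) {
  structure(list(values = as.numeric(values), label = as.integer(label),
                 origin = list(recording = "<test>", start = 1L),
                 sampling_rate_hz = fs),
            class = "segment")
}

# One 60 s block per state with the default simulator, segmented; built once
# per test run and memoized (used by several files).
default_sim_segments <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- simulate_session(list(list("Idle", 60), list("Stone", 60),
                                   list("Tissue", 60)), seed = 123L)
      cache <<- segment_recording(rec)
    }
    cache
  }
})

# Mann-Whitney U-statistic AUC (ties counted 1/2): the exhaustive pairwise
# oracle for ROC area.
auc_u_statistic <- function(scores, truth, positive_class) {
  pos <- scores[truth == positive_class]
  neg <- scores[truth != positive_class]
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}

# Run the reference wavelet library (PyWavelets, via the python interpreter
# on PATH) on a matrix of signals; returns a matrix of cA||cD rows.
reference_dwt <- function(x_mat, wavelet, mode = "symmetric") {
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  utils::write.table(x_mat, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(
    "import numpy as np, pywt, sys\nX = np.loadtxt(%s, delimiter=',', ndmin=2)\nrows = [np.concatenate(pywt.dwt(x, %s, mode=%s)) for x in X]\nnp.savetxt(%s, np.vstack(rows), delimiter=',', fmt='%%.17e')\n",
    shQuote(infile), shQuote(wavelet), shQuote(mode), shQuote(outfile))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("reference DWT oracle failed: ", paste(res, collapse = "\n"))
  }
  as.matrix(utils::read.table(outfile, sep = ","))
}

# Write a minimal xlsx logging file via python/openpyxl (no xlsx writer is
# available in R); returns the path.
write_xlsx_fixture <- function(df, path) {
  infile <- tempfile(fileext = ".csv")
  utils::write.csv(df, infile, row.names = FALSE)
  script <- sprintf(
    "import csv, openpyxl\nwb = openpyxl.Workbook()\nws = wb.active\nwith open(%s) as f:\n    for i, row in enumerate(csv.reader(f)):\n        ws.append([c if i == 0 else float(c) for c in row])\nwb.save(%s)\n",
    shQuote(infile), shQuote(path))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(path)) {
    stop("xlsx fixture writer failed: ", paste(res, collapse = "\n"))
  }
  path
}
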