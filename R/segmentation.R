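#' Slice a recording into fixed-length, label-pure windows
#'
#' Cuts the trace into non-overlapping consecutive windows of exactly
#' `timestep` samples starting at the first sample (50 samples = 500 ms at
#' 100 Hz, the feedback cadence of the warning system). Windows spanning a
#' label change are discarded rather than majority-labeled, so neither class
#' spectra nor training labels are contaminated by transition windows; a
#' trailing remainder shorter than `timestep` is discarded too.
#'
#' @param rec A [recording()].
#' @param timestep Window length in samples (default 50, i.e. 500 ms at
#'   100 Hz); must be at least 2.
#' @param policy Window labeling policy; only `"pure_label"` is supported.
#' @return A list of `segment` objects, each a list with `values` (length
#'   `timestep`), `label` (integer state code), `origin` (recording source
#'   and 1-based start index) and `sampling_rate_hz`.
#' @examples
#' rec <- simulate_state_signal("Idle", 10, seed = 1)
#' length(segment_recording(rec))  # 1000 / 50
#' @export
segment_recording <- function(rec, timestep = 50L, policy = "pure_label") {
  stopifnot(inherits(rec, "recording"))
  policy <- match.arg(policy, "pure_label")
  timestep <- as.integer(timestep)
  if (is.na(timestep) || timestep < 2L) {
    stop("timestep must be an integer >= 2, got ", timestep)
  }
  n_win <- length(rec$samples) %/% timestep
  src <- if (!is.null(rec$meta$source)) rec$meta$source else "<recording>"
  out <- vector("list", n_win)
  kept <- 0L
  for (w in seq_len(n_win)) {
    i0 <- (w - 1L) * timestep + 1L
    idx <- i0:(i0 + timestep - 1L)
    labs <- rec$labels[idx]
    if (length(unique(labs)) != 1L) next  # mixed-label window: discard
    kept <- kept + 1L
    out[[kept]] <- structure(
      list(values = rec$samples[idx], label = labs[1L],
           origin = list(recording = src, start = i0),
           sampling_rate_hz = rec$sampling_rate_hz),
      class = "segment"
    )
  }
  out[seq_len(kept)]
}

#' One-sided FFT magnitude spectrum of a segment
#'
#' Raw discrete-Fourier magnitude of the window, no detrending and no
#' taper: for a length-`T` window sampled at `fs` Hz there are
#' `floor(T/2) + 1` bins at `0, fs/T, ..., fs/2` Hz (26 bins at
#' 0, 2, ..., 50 Hz for the default 50-sample window at 100 Hz).
#'
#' @param seg A `segment` from [segment_recording()], or a bare numeric
#'   vector (then `fs` supplies the rate).
#' @param fs Sampling rate used when `seg` is a bare vector.
#' @return A `spectrum_1s` object: list with `freqs_hz` and `magnitude`.
#' @export
fft_magnitude <- function(seg, fs = 100) {
  x <- if (inherits(seg, "segment")) seg$values else as.numeric(seg)
  if (inherits(seg, "segment")) fs <- seg$sampling_rate_hz
  T <- length(x)
  if (T < 1L) stop("segment is empty")
  nb <- T %/% 2L + 1L
  mag <- Mod(stats::fft(x))[seq_len(nb)]
  structure(list(freqs_hz = (0:(nb - 1L)) * fs / T, magnitude = mag),
            class = "spectrum_1s")
}

#' Class-averaged magnitude spectra
#'
#' Bin-wise arithmetic mean of [fft_magnitude()] across the segments of each
#' state, reproducing the spectral separability analysis: on separable data
#' the Stone average dominates the other two states across most of the
#' frequency range.
#'
#' @param segments List of `segment`s of identical length and sampling rate.
#' @return Named list mapping state name to `spectrum_1s`; states with no
#'   segments are absent. Empty input gives an empty list.
#' @examples
#' rec <- simulate_session(list(list("Idle", 5), list("Stone", 5)), seed = 1)
#' sp <- class_average_spectrum(segment_recording(rec))
#' names(sp)
#' @export
class_average_spectrum <- function(segments) {
  if (length(segments) == 0L) return(structure(list(), names = character(0)))
  lens <- vapply(segments, function(s) length(s$values), integer(1))
  fss <- vapply(segments, function(s) s$sampling_rate_hz, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(fss)) != 1L) {
    stop("segments must share one length and sampling rate")
  }
  labs <- vapply(segments, function(s) s$label, integer(1))
  out <- list()
  for (code in sort(unique(labs))) {
    mags <- vapply(segments[labs == code],
                   function(s) fft_magnitude(s)$magnitude,
                   numeric(lens[1L] %/% 2L + 1L))
    tmpl <- fft_magnitude(segments[[which(labs == code)[1L]]])
    out[[state_name(code)]] <- structure(
      list(freqs_hz = tmpl$freqs_hz, magnitude = rowMeans(mags)),
      class = "spectrum_1s"
    )
  }
  out
}
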