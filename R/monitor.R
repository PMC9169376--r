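#' Stream a recording through the trained classifier
#'
#' Emulates live operation: windows of `window` samples are classified in
#' arrival order at stride `hop`, each decision emitted as soon as its
#' window completes, with no lookahead. The default `hop = window` gives
#' one decision every 0.5 s at the standard 50-sample window and 100 Hz
#' rate -- the feedback cadence of the warning system. Per-decision compute
#' time is measured and reported (it is hardware-dependent and never
#' asserted against a target). No temporal smoothing is applied: windows
#' are classified independently, and any alerting policy over the emitted
#' states is left to the caller.
#'
#' @param model A `trained_forest` (see [train_forest()]).
#' @param wavelet Wavelet name; must match the wavelet the model was
#'   trained with when the model records one.
#' @param rec A [recording()] (labels, if any, are ignored).
#' @param window Window length in samples; must match the model's training
#'   timestep when recorded.
#' @param hop Stride in samples, `1 <= hop <= window`.
#' @param padding DWT padding mode (must match training).
#' @return A data frame with one row per complete window:
#'   `window_end_time_s`, `predicted` (integer state code), `state` (name),
#'   `p_Idle`, `p_Stone`, `p_Tissue` (summing to 1; classes unseen in
#'   training get 0) and `decision_latency_ms`. A recording shorter than
#'   `window` yields zero rows.
#' @examples
#' \donttest{
#' rec <- simulate_session(list(list("Idle", 30), list("Stone", 30),
#'                              list("Tissue", 30)), seed = 1)
#' ft <- build_feature_table(segment_recording(rec), "haar")
#' fit <- train_forest(ft, cfg = forest_config(n_trees = 50, seed = 1))
#' ev <- classify_stream(fit, "haar", simulate_state_signal("Stone", 3, seed = 9))
#' ev$state
#' }
#' @export
classify_stream <- function(model, wavelet, rec, window = 50L, hop = 50L,
                            padding = "symmetric") {
  stopifnot(inherits(model, "trained_forest"), inherits(rec, "recording"))
  window <- as.integer(window); hop <- as.integer(hop)
  if (hop < 1L || hop > window) stop("hop must satisfy 1 <= hop <= window")
  fm <- model$feature_meta
  if (!is.null(fm)) {
    if (!identical(fm$wavelet, wavelet)) {
      stop("wavelet mismatch: model was trained with '", fm$wavelet,
           "', stream requested '", wavelet, "'")
    }
    if (!is.na(fm$timestep) && fm$timestep != window) {
      stop("window mismatch: model was trained on ", fm$timestep,
           "-sample windows, stream uses ", window)
    }
    padding <- fm$padding
  }
  w <- load_wavelet(wavelet)
  fs <- rec$sampling_rate_hz
  n <- length(rec$samples)
  ends <- if (n >= window) seq.int(window, n, by = hop) else integer(0)
  out <- data.frame(window_end_time_s = numeric(0), predicted = integer(0),
                    state = character(0), p_Idle = numeric(0),
                    p_Stone = numeric(0), p_Tissue = numeric(0),
                    decision_latency_ms = numeric(0))
  if (length(ends) == 0L) return(out)

  rows <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    t0 <- proc.time()[["elapsed"]]
    x <- rec$samples[(ends[i] - window + 1L):ends[i]]
    co <- dwt_single_level(x, w, padding = padding)
    p <- predict_proba(model, matrix(c(co$approx, co$detail), nrow = 1L))
    pred <- model$classes[max.col(p, ties.method = "first")]
    latency <- (proc.time()[["elapsed"]] - t0) * 1000
    pfull <- c(Idle = 0, Stone = 0, Tissue = 0)
    pfull[state_name(model$classes)] <- p[1L, ]
    rows[[i]] <- data.frame(
      window_end_time_s = ends[i] / fs, predicted = pred,
      state = state_name(pred), p_Idle = pfull[["Idle"]],
      p_Stone = pfull[["Stone"]], p_Tissue = pfull[["Tissue"]],
      decision_latency_ms = latency
    )
  }
  do.call(rbind, rows)
}
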