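#' Load a wavelet filter bank
#'
#' Returns the decomposition/reconstruction filter taps of one of the five
#' supported families: `haar`, `db2`, `db4` (Daubechies extremal phase,
#' where the digit counts vanishing moments), `rbio2.4` (reverse
#' biorthogonal) and `dmey` (the 62-tap FIR approximation of the Meyer
#' wavelet). Taps are embedded constants of the standard published
#' constructions; no wavelet library is needed at run time.
#'
#' @param name Wavelet name.
#' @return A `wavelet_spec`: list with `name`, `orthogonal`, and numeric
#'   vectors `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`.
#' @examples
#' w <- load_wavelet("haar")
#' w$dec_lo
#' @export
load_wavelet <- function(name) {
  spec <- .wavelet_filters[[name]]
  if (is.null(spec)) {
    stop("unknown wavelet '", name, "'; supported: ",
         paste(names(.wavelet_filters), collapse = ", "))
  }
  structure(c(list(name = name), spec), class = "wavelet_spec")
}

#' @rdname load_wavelet
#' @return `supported_wavelets()` returns the names of the available
#'   families.
#' @export
supported_wavelets <- function() names(.wavelet_filters)

# Half-sample symmetric extension: index i (1-based, may lie outside 1..n)
# folds onto the signal as ... x2 x1 | x1 .. xn | xn x(n-1) ..., repeating
# with period 2n so arbitrarily deep extensions are defined.
.sym_fold <- function(i, n) {
  m <- (i - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Full linear convolution, vectorized over the (short) filter.
.conv_full <- function(x, h) {
  n <- length(x); L <- length(h)
  y <- numeric(n + L - 1L)
  for (j in seq_len(L)) y[j:(j + n - 1L)] <- y[j:(j + n - 1L)] + h[j] * x
  y
}

# One analysis channel. `symmetric`: extend by L-1 each side, convolve, keep
# the n+L-1 fully-overlapping outputs, downsample keeping every second value
# starting at the second -> floor((n+L-1)/2) coefficients. `none`: circular
# (periodized) convolution with the same downsampling phase -> exactly n/2
# coefficients, and the transform is an orthogonal map for orthogonal
# filter banks (energy is conserved).
.dwt_channel <- function(x, h, padding) {
  n <- length(x); L <- length(h)
  if (padding == "symmetric") {
    ext <- x[.sym_fold((1L - (L - 1L)):(n + L - 1L), n)]
    y <- .conv_full(ext, h)[L:(L + n + L - 2L)]   # valid part, length n+L-1
    y[seq(2L, n + L - 1L, by = 2L)]
  } else {  # periodized
    k <- seq_len(n %/% 2L)
    out <- numeric(length(k))
    for (j in seq_len(L)) {
      idx <- (2L * (k - 1L) + 2L - (j - 1L)) %% n + 1L
      out <- out + h[j] * x[idx]
    }
    out
  }
}

#' Single-level discrete wavelet transform
#'
#' Decomposes a signal into approximation (low-pass) and detail (high-pass)
#' coefficients through the two-channel filter bank of the named wavelet,
#' downsampling by two. With `padding = "none"` the convolution is
#' periodized (circular) and each output has exactly `length(x) / 2`
#' coefficients -- half the original data length; this requires an even
#' signal at least as long as the filter, which the 62-tap `dmey` filter
#' exceeds for 50-sample windows, hence the default `"symmetric"`
#' (half-sample symmetric extension), which works for every family and
#' yields `floor((length(x) + L - 1) / 2)` coefficients per channel, `L`
#' being the filter length. The symmetric-mode output matches the
#' conventional reference implementation coefficient-for-coefficient.
#'
#' @param x Numeric signal (e.g. a 50-sample window).
#' @param w A `wavelet_spec` from [load_wavelet()], or a wavelet name.
#' @param padding `"symmetric"` (default) or `"none"`.
#' @return A `dwt_coefficients` object: list with `approx`, `detail`,
#'   `wavelet`, `padding`, `orig_length`.
#' @examples
#' dwt_single_level(c(1, 1, 1, 1), "haar", padding = "none")$approx
#' @export
dwt_single_level <- function(x, w, padding = c("symmetric", "none")) {
  if (is.character(w)) w <- load_wavelet(w)
  padding <- match.arg(padding)
  x <- as.numeric(x)
  n <- length(x); L <- length(w$dec_lo)
  if (padding == "none") {
    if (n < L) {
      stop("padding 'none' needs length(x) >= filter length (", L,
           " taps for ", w$name, ", signal has ", n,
           " samples); use padding = 'symmetric'")
    }
    if (n %% 2L != 0L) stop("padding 'none' needs an even signal length")
  }
  if (n < 2L) stop("signal must have at least 2 samples")
  structure(
    list(approx = .dwt_channel(x, w$dec_lo, padding),
         detail = .dwt_channel(x, w$dec_hi, padding),
         wavelet = w$name, padding = padding, orig_length = n),
    class = "dwt_coefficients"
  )
}

#' Invert a single-level DWT
#'
#' Reconstructs the original signal from its approximation and detail
#' coefficients. The inverse is computed as the exact (least-squares)
#' inverse of the linear analysis operator for the recorded padding and
#' original length, so reconstruction is accurate to machine precision for
#' every supported family -- including `dmey`, whose 62-tap FIR
#' approximation of the Meyer wavelet is only near-orthogonal, leaving a
#' residual around `1e-3` if inverted through its synthesis filters.
#'
#' @param coeffs A `dwt_coefficients` object from [dwt_single_level()].
#' @param w Matching `wavelet_spec` or wavelet name.
#' @return Numeric vector of length `coeffs$orig_length`.
#' @examples
#' co <- dwt_single_level(c(1, 2, 3, 4), "haar", padding = "none")
#' idwt_single_level(co, "haar")
#' @export
idwt_single_level <- function(coeffs, w) {
  stopifnot(inherits(coeffs, "dwt_coefficients"))
  if (is.character(w)) w <- load_wavelet(w)
  if (!identical(w$name, coeffs$wavelet)) {
    stop("wavelet mismatch: coefficients were produced with '",
         coeffs$wavelet, "', not '", w$name, "'")
  }
  n <- coeffs$orig_length
  b <- c(coeffs$approx, coeffs$detail)
  # analysis operator applied to the canonical basis, column by column
  A <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    c(.dwt_channel(e, w$dec_lo, coeffs$padding),
      .dwt_channel(e, w$dec_hi, coeffs$padding))
  }, numeric(length(b)))
  as.numeric(qr.coef(qr(A), b))
}

#' Build the DWT feature table for a set of segments
#'
#' Transforms each segment with [dwt_single_level()] and concatenates the
#' approximation and detail coefficients into one feature row per segment
#' (order preserved), the representation fed to the random forest. All rows
#' have the same length, fixed by `(wavelet, timestep, padding)`.
#'
#' @param segments List of `segment`s of one common length.
#' @param wavelet Wavelet name (see [supported_wavelets()]).
#' @param padding Passed to [dwt_single_level()].
#' @return A `feature_table`: list with `features` (numeric matrix, one row
#'   per segment, columns `f0..f{d-1}`), `labels` (integer codes),
#'   `origins`, and the `wavelet` / `padding` / `timestep` used. Empty
#'   segment list gives a zero-row table.
#' @examples
#' rec <- simulate_state_signal("Stone", 5, seed = 1)
#' ft <- build_feature_table(segment_recording(rec), "haar", padding = "none")
#' dim(ft$features)
#' @export
build_feature_table <- function(segments, wavelet = "dmey",
                                padding = c("symmetric", "none")) {
  padding <- match.arg(padding)
  w <- load_wavelet(wavelet)
  if (length(segments) == 0L) {
    return(structure(list(features = matrix(numeric(0), nrow = 0L, ncol = 0L),
                          labels = integer(0), origins = list(),
                          wavelet = wavelet, padding = padding,
                          timestep = NA_integer_),
                     class = "feature_table"))
  }
  lens <- vapply(segments, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("segments must all have the same length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  rows <- lapply(segments, function(s) {
    co <- dwt_single_level(s$values, w, padding = padding)
    c(co$approx, co$detail)
  })
  features <- do.call(rbind, rows)
  colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  structure(
    list(features = features,
         labels = vapply(segments, function(s) s$label, integer(1)),
         origins = lapply(segments, function(s) s$origin),
         wavelet = wavelet, padding = padding, timestep = lens[1L]),
    class = "feature_table"
  )
}
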