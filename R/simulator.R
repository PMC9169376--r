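#' Per-state synthetic shockwave profile
#'
#' Parameterizes the synthetic signal generator for one laser state. The
#' signal model is baseline Gaussian sensor noise plus damped-cosine bursts
#' `A * exp(-t / tau) * cos(2 * pi * f * t)` arriving as a homogeneous
#' Poisson process -- a minimal stand-in for the pressure transient of a
#' vapor-bubble collapse at the laser contact point, transmitted through the
#' endoscope to the accelerometer.
#'
#' @param noise_sigma Std. dev. of the baseline Gaussian noise (device units).
#' @param burst_rate_hz Mean transient arrivals per second (Poisson rate);
#'   0 disables bursts (the idle state).
#' @param burst_amplitude Mean peak amplitude of a transient.
#' @param burst_freq_hz Dominant oscillation frequency of the burst kernel;
#'   must stay below the Nyquist frequency of the recording.
#' @param burst_decay_s Exponential decay time constant of the burst (s).
#' @param amplitude_jitter Relative std. dev. of per-burst amplitude.
#' @return A `state_profile` object (named list of the six parameters).
#' @seealso [default_sim_config()], [simulate_state_signal()]
#' @export
state_profile <- function(noise_sigma = 0.05, burst_rate_hz = 0,
                          burst_amplitude = 0, burst_freq_hz = 0,
                          burst_decay_s = 0.05, amplitude_jitter = 0) {
  p <- list(noise_sigma = noise_sigma, burst_rate_hz = burst_rate_hz,
            burst_amplitude = burst_amplitude, burst_freq_hz = burst_freq_hz,
            burst_decay_s = burst_decay_s, amplitude_jitter = amplitude_jitter)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                           is.na(v) || v < 0, logical(1))]
  if (length(bad) > 0L) {
    stop("state_profile parameters must be single nonnegative numbers: ",
         paste(bad, collapse = ", "))
  }
  structure(p, class = "state_profile")
}

#' Default simulation configuration
#'
#' The shipped profiles emulate the qualitative spectral separation of the
#' three states observed on real traces: `Stone` bursts are strong and
#' high-frequency (hard impacts, fast ring-down), `Tissue` bursts are weaker
#' and lower-frequency (soft-tissue damping), and `Idle` is pure sensor
#' noise. Stone and Tissue differ in both amplitude and dominant frequency
#' so that downstream separability does not rest on amplitude alone. The
#' burst rate of 30 per second reflects the pulse repetition rate of a
#' lithotripsy laser during activation, so active-state windows carry
#' sustained vibration rather than isolated transients. All burst
#' frequencies sit below the 50 Hz Nyquist limit of the 100 Hz sampling
#' rate.
#'
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param profiles Named list of [state_profile()]s, one per state name
#'   (`Idle`, `Stone`, `Tissue`); defaults described above.
#' @return A `sim_config` object: list with `profiles` and `sampling_rate_hz`.
#' @examples
#' cfg <- default_sim_config()
#' cfg$profiles$Stone$burst_freq_hz
#' @export
default_sim_config <- function(sampling_rate_hz = 100, profiles = NULL) {
  if (is.null(profiles)) {
    profiles <- list(
      Idle   = state_profile(noise_sigma = 0.05),
      Stone  = state_profile(noise_sigma = 0.05, burst_rate_hz = 30,
                             burst_amplitude = 1.0, burst_freq_hz = 35,
                             burst_decay_s = 0.05, amplitude_jitter = 0.1),
      Tissue = state_profile(noise_sigma = 0.05, burst_rate_hz = 30,
                             burst_amplitude = 0.2, burst_freq_hz = 12,
                             burst_decay_s = 0.08, amplitude_jitter = 0.1)
    )
  }
  missing_states <- setdiff(names(state_labels()), names(profiles))
  if (length(missing_states) > 0L) {
    stop("config error: profiles missing for state(s): ",
         paste(missing_states, collapse = ", "))
  }
  for (nm in names(state_labels())) {
    f <- profiles[[nm]]$burst_freq_hz
    if (f >= sampling_rate_hz / 2) {
      stop("config error: burst_freq_hz for ", nm,
           " must be below the Nyquist frequency ", sampling_rate_hz / 2, " Hz")
    }
  }
  structure(list(profiles = profiles, sampling_rate_hz = sampling_rate_hz),
            class = "sim_config")
}

# Deterministic per-block seed derivation: block i of a session depends only
# on (master seed, i), never on preceding blocks, so block content is
# order-invariant. Kept below 2^31 - 1.
.block_seed <- function(seed, block) {
  as.integer((as.numeric(seed) + (block - 1) * 1000003) %% 2147483647)
}

#' Simulate a single-state shockwave recording
#'
#' Generates `round(duration_s * fs)` samples of one state: Gaussian noise
#' plus damped-cosine bursts `A * exp(-t/tau) * cos(2*pi*f*t)` at
#' continuous-time Poisson arrival times, rendered at sample resolution;
#' overlapping bursts sum linearly. The logging hardware records the
#' *magnitude* of the acceleration, so the returned trace is the absolute
#' value of that sum (nonnegative, like the real logs). Output is
#' bit-reproducible given `(cfg, seed)`, and scaling both `noise_sigma` and
#' `burst_amplitude` by a common factor scales the trace sample-wise.
#'
#' @param state State name or integer code.
#' @param duration_s Duration in seconds; must yield at least one sample.
#' @param cfg A [default_sim_config()]-style configuration.
#' @param seed Integer seed.
#' @return A [recording()] with every label equal to `state`; `meta` records
#'   the seed and state.
#' @examples
#' rec <- simulate_state_signal("Stone", 10, seed = 1)
#' length(rec$samples)
#' @export
simulate_state_signal <- function(state, duration_s, cfg = default_sim_config(),
                                  seed = 1L) {
  if (is.numeric(state)) state <- state_name(state)
  state <- match.arg(state, names(state_labels()))
  prof <- cfg$profiles[[state]]
  if (is.null(prof)) stop("config error: no profile for state ", state)
  fs <- cfg$sampling_rate_hz
  n <- round(duration_s * fs)
  if (n < 1L) stop("duration_s too short: yields no samples at ", fs, " Hz")

  set.seed(seed)
  x <- stats::rnorm(n, 0, prof$noise_sigma)
  n_bursts <- 0L
  if (prof$burst_rate_hz > 0 && prof$burst_amplitude > 0) {
    n_bursts <- stats::rpois(1L, prof$burst_rate_hz * duration_s)
    if (n_bursts > 0L) {
      arrivals <- stats::runif(n_bursts, 0, duration_s)
      amps <- prof$burst_amplitude *
        pmax(0, 1 + prof$amplitude_jitter * stats::rnorm(n_bursts))
      # render each burst until its envelope has decayed to 0.1% of peak
      t_max <- prof$burst_decay_s * log(1000)
      tgrid <- (seq_len(n) - 1L) / fs
      for (b in seq_len(n_bursts)) {
        i0 <- ceiling(arrivals[b] * fs) + 1L
        i1 <- min(n, floor((arrivals[b] + t_max) * fs) + 1L)
        if (i0 > n || i1 < i0) next
        dt <- tgrid[i0:i1] - arrivals[b]
        x[i0:i1] <- x[i0:i1] +
          amps[b] * exp(-dt / prof$burst_decay_s) *
          cos(2 * pi * prof$burst_freq_hz * dt)
      }
    }
  }
  recording(abs(x), state_code(state), sampling_rate_hz = fs,
            meta = list(simulator = list(state = state, seed = seed,
                                         duration_s = duration_s,
                                         n_bursts = n_bursts)))
}

#' Simulate a multi-state session
#'
#' Concatenates per-state blocks into one labeled recording, emulating a
#' procedure trace in which the laser alternates between idle periods, stone
#' fragmentation and tissue contact. Each block draws from its own seed
#' substream derived from the master seed and block position, so a block's
#' content does not depend on the blocks before it.
#'
#' @param schedule List of `list(state, duration_s)` pairs (or a 2-column
#'   data frame with columns `state`, `duration_s`).
#' @param cfg A [default_sim_config()]-style configuration.
#' @param seed Master integer seed.
#' @return A [recording()] whose labels follow the schedule block by block.
#' @examples
#' rec <- simulate_session(list(list("Idle", 1), list("Stone", 1)), seed = 1)
#' table(rec$labels)
#' @export
simulate_session <- function(schedule, cfg = default_sim_config(), seed = 1L) {
  if (is.data.frame(schedule)) {
    schedule <- lapply(seq_len(nrow(schedule)), function(i)
      list(schedule$state[i], schedule$duration_s[i]))
  }
  if (length(schedule) == 0L) stop("schedule must be nonempty")
  blocks <- lapply(seq_along(schedule), function(i) {
    entry <- schedule[[i]]
    dur <- as.numeric(entry[[2L]])
    if (is.na(dur) || dur <= 0) {
      stop("schedule entry ", i, ": duration must be positive, got ", dur)
    }
    simulate_state_signal(entry[[1L]], dur, cfg, seed = .block_seed(seed, i))
  })
  recording(
    unlist(lapply(blocks, `[[`, "samples")),
    unlist(lapply(blocks, `[[`, "labels")),
    sampling_rate_hz = cfg$sampling_rate_hz,
    meta = list(simulator = list(seed = seed, n_blocks = length(blocks)))
  )
}
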