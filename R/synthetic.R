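# Seeded generators: multichannel signals built from known band-limited
# modes, and toy seizure timelines, so every pipeline stage is testable
# without clinical recordings.

#' Specification of one synthetic band-limited mode
#'
#' An amplitude-modulated cosine with optional slow frequency jitter — the
#' simplest signal satisfying the narrow-band assumption behind variational
#' mode extraction.
#'
#' @param center_hz Center frequency in Hz (must stay below Nyquist).
#' @param amplitude Per-channel amplitude(s); recycled across channels.
#' @param am_depth,am_rate_hz Amplitude-modulation depth in \[0, 1\] and
#'   rate (Hz); depth 0 disables modulation.
#' @param freq_jitter_sd Standard deviation (Hz, per sample step) of a slow
#'   random-walk deviation of the instantaneous frequency; 0 disables.
#' @param phase Per-channel initial phase(s) in radians; recycled.
#' @return Object of class `synthetic_mode`.
#' @export
synthetic_mode <- function(center_hz, amplitude = 1, am_depth = 0,
                           am_rate_hz = 0, freq_jitter_sd = 0, phase = 0) {
  if (center_hz <= 0) stop("center_hz must be > 0")
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (am_depth < 0 || am_depth > 1) stop("am_depth must be in [0, 1]")
  structure(list(center_hz = center_hz, amplitude = amplitude,
                 am_depth = am_depth, am_rate_hz = am_rate_hz,
                 freq_jitter_sd = freq_jitter_sd, phase = phase),
            class = "synthetic_mode")
}

#' Generate a multichannel recording with known modes
#'
#' Sums the requested modes channel by channel, stores each mode's exact
#' waveform as ground truth, and adds white Gaussian noise (standing in for
#' broadband background activity). Deterministic for a fixed seed.
#'
#' @param modes List of [synthetic_mode()] specs (non-empty).
#' @param n_channels Number of channels C.
#' @param duration_s Duration in seconds.
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   mode center frequency.
#' @param noise_sigma Noise standard deviation (same units as amplitudes).
#' @param seed Integer seed.
#' @return Object of class `synthetic_recording`: `signal`
#'   (a [multichannel_signal()]), `ground_truth` (list of
#'   `list(center_hz, modes)` with C x T matrices), `noise` (C x T),
#'   `noise_sigma`, `seed`. By construction
#'   `signal = sum(ground truth) + noise` exactly.
#' @export
generate_recording <- function(modes, n_channels, duration_s, sample_rate,
                               noise_sigma = 0, seed = 1L) {
  if (!length(modes)) stop("need at least one mode spec")
  stopifnot(all(vapply(modes, inherits, logical(1), "synthetic_mode")))
  hi <- max(vapply(modes, `[[`, numeric(1), "center_hz"))
  if (sample_rate <= 2 * hi)
    stop("mode center frequency at or above Nyquist: raise sample_rate")
  C <- as.integer(n_channels)
  T <- round(duration_s * sample_rate)
  tt <- (seq_len(T) - 1) / sample_rate
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  truth <- vector("list", length(modes))
  total <- matrix(0, C, T)
  for (i in seq_along(modes)) {
    sp <- modes[[i]]
    amp <- rep_len(sp$amplitude, C)
    ph <- rep_len(sp$phase, C)
    dev <- if (sp$freq_jitter_sd > 0)
      2 * pi * cumsum(cumsum(stats::rnorm(T, 0, sp$freq_jitter_sd))) / sample_rate^2
    else 0
    env <- 1 + sp$am_depth * sin(2 * pi * sp$am_rate_hz * tt)
    U <- matrix(0, C, T)
    for (k in seq_len(C))
      U[k, ] <- amp[k] * env * cos(2 * pi * sp$center_hz * tt + ph[k] + dev)
    truth[[i]] <- list(center_hz = sp$center_hz, modes = U)
    total <- total + U
  }
  noise <- matrix(if (noise_sigma > 0) stats::rnorm(C * T, 0, noise_sigma) else 0,
                  C, T)
  structure(
    list(signal = multichannel_signal(total + noise, sample_rate),
         ground_truth = truth, noise = noise,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "synthetic_recording"
  )
}

#' Generate a toy seizure timeline
#'
#' Labels samples every `step_seconds` as preictal inside the horizon
#' before each onset — between `preictal_horizon_minutes` and
#' `preictal_gap_minutes` before onset, emulating the convention of taking
#' the stretch from 66 down to 5 minutes pre-onset as preictal — and
#' interictal elsewhere, then flips labels independently at
#' `label_noise_rate` (seeded).
#'
#' @param duration_hours Recording span in hours.
#' @param onset_times Seizure onset times in seconds, inside the span and
#'   far enough apart that preictal windows do not overlap.
#' @param label_noise_rate Probability of flipping each label.
#' @param preictal_horizon_minutes,preictal_gap_minutes Preictal window
#'   boundaries before onset (defaults 66 and 5 minutes).
#' @param step_seconds Label step (default 2 s).
#' @param seed Integer seed.
#' @return A [seizure_timeline()].
#' @export
generate_timeline <- function(duration_hours, onset_times,
                              label_noise_rate = 0,
                              preictal_horizon_minutes = 66,
                              preictal_gap_minutes = 5,
                              step_seconds = 2, seed = 1L) {
  span <- c(0, duration_hours * 3600)
  onset_times <- sort(as.numeric(onset_times))
  if (length(onset_times) && (any(onset_times < span[1]) || any(onset_times > span[2])))
    stop("onsets must lie inside the recording span")
  if (label_noise_rate < 0 || label_noise_rate > 1)
    stop("label_noise_rate must be in [0, 1]")
  if (preictal_gap_minutes >= preictal_horizon_minutes)
    stop("preictal gap must be shorter than the horizon")
  lo <- onset_times - preictal_horizon_minutes * 60
  hi <- onset_times - preictal_gap_minutes * 60
  if (length(onset_times) > 1L && any(lo[-1L] < hi[-length(hi)]))
    stop("onsets too close: preictal windows overlap")
  times <- seq(step_seconds, span[2], by = step_seconds)
  labels <- rep(0L, length(times))
  for (i in seq_along(onset_times))
    labels[times >= lo[i] & times < hi[i]] <- 1L
  if (label_noise_rate > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    flip <- stats::runif(length(labels)) < label_noise_rate
    labels[flip] <- 1L - labels[flip]
  }
  seizure_timeline(times, labels, onsets = onset_times, span = span)
}
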