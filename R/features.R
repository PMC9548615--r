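# Time-frequency features: long overlapping samples, per-second STFT power
# spectra, 2-Hz band averaging, channel concatenation.

#' STFT feature configuration
#'
#' Defaults follow the canonical protocol: 30-s samples sliding every 2 s
#' (28-s overlap), 1-s analysis windows with 75% overlap, one-sided power
#' spectra truncated to \[0, 140) Hz and averaged within consecutive 2-Hz
#' bands. With those settings a 30-s sample yields 117 time steps of 70
#' band powers per channel.
#'
#' @param sample_seconds,sample_overlap_seconds Length and overlap of the
#'   long samples fed to the classifier.
#' @param window_seconds,window_overlap_fraction STFT analysis window
#'   length and fractional overlap.
#' @param f_max_hz Upper truncation frequency (exclusive); must not exceed
#'   the Nyquist frequency of the data.
#' @param band_width_hz Width of the averaging bands.
#' @param estimator Spectral estimator per window: `"periodogram"`
#'   (Hamming-windowed, default) or `"welch"` (averaged half-length
#'   segments, 50% overlap).
#' @return Object of class `stft_config`.
#' @export
stft_config <- function(sample_seconds = 30, sample_overlap_seconds = 28,
                        window_seconds = 1, window_overlap_fraction = 0.75,
                        f_max_hz = 140, band_width_hz = 2,
                        estimator = c("periodogram", "welch")) {
  if (sample_overlap_seconds >= sample_seconds)
    stop("sample overlap must be shorter than the sample")
  if (window_overlap_fraction < 0 || window_overlap_fraction >= 1)
    stop("window_overlap_fraction must be in [0, 1)")
  if (f_max_hz <= 0 || band_width_hz <= 0) stop("frequencies must be > 0")
  structure(
    list(sample_seconds = sample_seconds,
         sample_overlap_seconds = sample_overlap_seconds,
         window_seconds = window_seconds,
         window_overlap_fraction = window_overlap_fraction,
         f_max_hz = f_max_hz, band_width_hz = band_width_hz,
         estimator = match.arg(estimator)),
    class = "stft_config"
  )
}

#' Slide long overlapping samples over a recording
#'
#' @param signal A [multichannel_signal()] at least one sample long.
#' @param cfg An [stft_config()].
#' @return List of [multichannel_signal()] samples starting every
#'   `sample_seconds - sample_overlap_seconds` seconds; the count is
#'   `floor((T_sec - sample_seconds)/step) + 1`.
#' @export
window_samples <- function(signal, cfg = stft_config()) {
  stopifnot(inherits(signal, "multichannel_signal"), inherits(cfg, "stft_config"))
  fs <- signal$sample_rate
  len <- round(fs * cfg$sample_seconds)
  step <- round(fs * (cfg$sample_seconds - cfg$sample_overlap_seconds))
  T <- n_samples(signal)
  if (T < len) stop("signal shorter than one sample window")
  n <- (T - len) %/% step + 1L
  lapply(seq_len(n), function(i) {
    start <- (i - 1L) * step + 1L
    multichannel_signal(signal$data[, start:(start + len - 1L), drop = FALSE],
                        fs, signal$channel_names)
  })
}

# one-sided PSD of a single windowed segment (density scaling, power/Hz)
.segment_psd <- function(x, fs, win) {
  xw <- x * win
  X <- stats::fft(xw)
  n <- length(x)
  K <- n %/% 2L + 1L
  p <- abs(X[seq_len(K)])^2 / (fs * sum(win^2))
  # double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, K); dbl[1] <- 1
  if (n %% 2L == 0L) dbl[K] <- 1
  list(psd = p * dbl, freq = (seq_len(K) - 1) * fs / n)
}

#' STFT band-power feature tensor of one sample
#'
#' For every channel and every analysis window, computes a one-sided power
#' spectrum, truncates it below `f_max_hz`, and averages the bins whose
#' center falls in each consecutive `band_width_hz` band. Channel band
#' vectors are stacked into one column per time step, giving a
#' `(N_c * N_p) x N` matrix chronologically ordered over windows.
#'
#' @param sample A [multichannel_signal()] of exactly `sample_seconds`.
#' @param cfg An [stft_config()]; `f_max_hz` must be at most Nyquist.
#' @return Object of class `feature_tensor`: `X` (the matrix), `n_channels`,
#'   `n_bands`, `n_steps`, `band_edges_hz`, `sample_rate`.
#' @export
stft_band_power <- function(sample, cfg = stft_config()) {
  stopifnot(inherits(sample, "multichannel_signal"), inherits(cfg, "stft_config"))
  fs <- sample$sample_rate
  if (cfg$f_max_hz > fs / 2)
    stop("f_max_hz exceeds the Nyquist frequency of the sample")
  wlen <- round(fs * cfg$window_seconds)
  hop <- round(wlen * (1 - cfg$window_overlap_fraction))
  if (hop < 1L) stop("window overlap too large: empty hop")
  T <- n_samples(sample)
  n_steps <- (T - wlen) %/% hop + 1L
  C <- n_channels(sample)
  n_bands <- as.integer(cfg$f_max_hz / cfg$band_width_hz)
  win <- signal::hamming(wlen)

  seg_bands <- function(x) {
    if (cfg$estimator == "periodogram") {
      ps <- .segment_psd(x, fs, win)
    } else {
      slen <- wlen %/% 2L
      shop <- max(1L, slen %/% 2L)
      wv <- signal::hamming(slen)
      starts <- seq(1L, wlen - slen + 1L, by = shop)
      acc <- NULL
      for (s in starts) {
        p <- .segment_psd(x[s:(s + slen - 1L)], fs, wv)
        acc <- if (is.null(acc)) p$psd else acc + p$psd
      }
      ps <- list(psd = acc / length(starts),
                 freq = (seq_along(acc) - 1) * fs / slen)
    }
    keep <- ps$freq < cfg$f_max_hz
    bidx <- ps$freq[keep] %/% cfg$band_width_hz + 1L
    as.numeric(tapply(ps$psd[keep], factor(bidx, levels = seq_len(n_bands)), mean))
  }

  X <- matrix(0, C * n_bands, n_steps)
  for (j in seq_len(n_steps)) {
    s0 <- (j - 1L) * hop
    for (k in seq_len(C)) {
      X[((k - 1L) * n_bands + 1L):(k * n_bands), j] <-
        seg_bands(sample$data[k, (s0 + 1L):(s0 + wlen)])
    }
  }
  structure(
    list(X = X, n_channels = C, n_bands = n_bands, n_steps = n_steps,
         band_edges_hz = seq(0, cfg$f_max_hz, by = cfg$band_width_hz),
         sample_rate = fs),
    class = "feature_tensor"
  )
}

#' Pair feature tensors with class labels
#'
#' @param tensors List of `feature_tensor` objects with identical shapes.
#' @param labels Vector of class labels (e.g. `"preictal"`/`"interictal"`),
#'   one per tensor.
#' @param shuffle_seed Optional integer; if given, the dataset order is a
#'   deterministic seeded permutation.
#' @return Object of class `feature_dataset`: `tensors`, `labels` (factor),
#'   `n`.
#' @export
assemble_dataset <- function(tensors, labels, shuffle_seed = NULL) {
  if (length(tensors) != length(labels))
    stop("tensors and labels must have equal length")
  if (length(tensors)) {
    stopifnot(all(vapply(tensors, inherits, logical(1), "feature_tensor")))
    dims <- vapply(tensors, function(t) dim(t$X), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all feature tensors must share one shape")
  }
  ord <- seq_along(tensors)
  if (!is.null(shuffle_seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(shuffle_seed))
    ord <- sample(ord)
  }
  structure(
    list(tensors = tensors[ord], labels = factor(unname(labels)[ord]),
         n = length(tensors)),
    class = "feature_dataset"
  )
}
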