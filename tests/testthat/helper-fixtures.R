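# Shared fixture builders.

# multichannel sum of cosines with per-channel phase offsets
tone_signal <- function(freqs_hz, amps, C, duration_s, fs, noise_sigma = 0,
                        seed = NULL) {
  T <- round(duration_s * fs)
  tt <- (0:(T - 1)) / fs
  data <- matrix(0, C, T)
  for (k in seq_len(C)) {
    for (i in seq_along(freqs_hz))
      data[k, ] <- data[k, ] + amps[i] * cos(2 * pi * freqs_hz[i] * tt + 0.4 * k + 0.2 * i)
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    data <- data + matrix(rnorm(C * T, 0, noise_sigma), C, T)
  }
  multichannel_signal(data, fs)
}

# fraction of a channel's spectral energy inside [lo, hi) Hz
band_energy_fraction <- function(x, fs, lo, hi) {
  X <- abs(stats::fft(x))^2
  K <- length(x) %/% 2L + 1L
  f <- (0:(K - 1)) * fs / length(x)
  p <- X[seq_len(K)]
  sum(p[f >= lo & f < hi]) / sum(p)
}

# decomposition-shaped object with prescribed center frequencies, for
# band-removal logic tests that do not need a real decomposition
fake_decomposition <- function(centers_hz, fs = 400, C = 2L, T = 64L,
                               seed = 7L) {
  set.seed(seed)
  mode_sets <- lapply(seq_along(centers_hz), function(i) {
    structure(list(modes = matrix(rnorm(C * T), C, T),
                   center_frequency_hz = centers_hz[i],
                   center_frequency_norm = centers_hz[i] / fs,
                   scale_index = i, mean_energy = 1,
                   uhat = NULL, diagnostics = list()),
              class = "mode_set")
  })
  total <- Reduce(`+`, lapply(mode_sets, `[[`, "modes"))
  noise <- matrix(rnorm(C * T, 0, 0.01), C, T)
  sig <- multichannel_signal(total + noise, fs)
  structure(list(mode_sets = mode_sets, residual = noise,
                 n_scales = length(mode_sets), signal = sig,
                 diagnostics = list()),
            class = "svmd_decomposition")
}

# minimal feature_tensor wrapper around a plain matrix
as_tensor <- function(M, n_channels = 1L) {
  structure(list(X = M, n_channels = n_channels,
                 n_bands = nrow(M) %/% n_channels, n_steps = ncol(M),
                 band_edges_hz = NULL, sample_rate = NA_real_),
            class = "feature_tensor")
}

# the ten published per-subject sensitivities and FPRs (inputs for
# aggregation checks)
subject_performance <- function() {
  data.frame(
    subject = c(paste0("Dog_", 1:8), "Patient_1", "Patient_2"),
    sensitivity = c(0.65, 0.87, 0.92, 0.94, 0.90, 0.90, 0.86, 0.88, 1, 0.67),
    fpr = c(0.25, 0.06, 0.23, 0.07, 0.16, 0.15, 0.18, 0.09, 0.36, 0.25)
  )
}
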