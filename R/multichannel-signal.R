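#' Multichannel signal container
#'
#' Wraps a real-valued channels-by-samples matrix together with its sampling
#' rate. This is the common currency of the package: decomposition,
#' denoising and feature extraction all consume and produce
#' `multichannel_signal` objects.
#'
#' @param data Numeric matrix, channels x samples. A numeric vector is
#'   treated as a single channel.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector of channel labels.
#' @return An object of class `multichannel_signal` with elements `data`
#'   (C x T matrix), `sample_rate` and `channel_names`.
#' @examples
#' sig <- multichannel_signal(matrix(rnorm(32), 2, 16), sample_rate = 8)
#' n_channels(sig)
#' @export
multichannel_signal <- function(data, sample_rate, channel_names = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (!all(is.finite(data)))
    stop("rejected input: signal contains non-finite samples")
  if (nrow(data) < 1L) stop("signal needs at least one channel")
  if (ncol(data) < 8L) stop("signal needs at least 8 samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number (Hz)")
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  } else if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length must match the number of channels")
  }
  structure(
    list(data = unname(data), sample_rate = as.numeric(sample_rate),
         channel_names = as.character(channel_names)),
    class = "multichannel_signal"
  )
}

#' @rdname multichannel_signal
#' @param x A `multichannel_signal`.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "multichannel_signal"))
  nrow(x$data)
}

#' @rdname multichannel_signal
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "multichannel_signal"))
  ncol(x$data)
}

#' @rdname multichannel_signal
#' @export
duration_seconds <- function(x) {
  n_samples(x) / x$sample_rate
}

#' @export
print.multichannel_signal <- function(x, ...) {
  cat(sprintf("<multichannel_signal> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$sample_rate, duration_seconds(x)))
  invisible(x)
}
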