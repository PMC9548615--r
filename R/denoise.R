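# Preprocessing: clip the recording, decompose each clip, drop modes whose
# center frequency falls in a subject-specific removal band, reconstruct
# from the retained modes and re-concatenate in chronological order.

#' Center-frequency removal band
#'
#' A set of non-overlapping half-open frequency intervals `[low, high)` in
#' Hz. Modes whose pooled center frequency falls inside any interval are
#' discarded during denoising. Subject-specific bands such as "below 60 Hz"
#' map to `c(0, 60)`; strict-lower bands like "between 8 and 15 Hz"
#' (exclusive) map to `c(8, 15)` — a mode landing exactly on the lower edge
#' is a measure-zero event and is resolved toward removal.
#'
#' @param ... Numeric length-2 vectors `c(low, high)` in Hz, or a single
#'   list of such vectors, or an n x 2 matrix. May be empty (no removal).
#' @return Object of class `removal_band`.
#' @examples
#' removal_band(c(8, 15))
#' removal_band(c(0, 20), c(60, 90))
#' @export
removal_band <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.numeric(args[[1]]))
    args <- args[[1]]
  if (length(args) == 1L && is.matrix(args[[1]]))
    args <- split(args[[1]], row(args[[1]]))
  iv <- if (length(args)) do.call(rbind, lapply(args, function(a) {
    a <- as.numeric(a)
    if (length(a) != 2L || !all(is.finite(a))) stop("each interval must be c(low, high)")
    if (a[1] >= a[2]) stop("interval must have low < high")
    a
  })) else matrix(numeric(0), 0, 2)
  if (nrow(iv) > 1L) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1L, 1] < iv[-nrow(iv), 2])) stop("removal intervals must not overlap")
  }
  colnames(iv) <- c("low_hz", "high_hz")
  structure(list(intervals = iv), class = "removal_band")
}

#' @rdname removal_band
#' @param band A `removal_band`.
#' @param freq_hz Numeric vector of frequencies to test.
#' @return `in_removal_band()` returns a logical vector: inside any interval.
#' @export
in_removal_band <- function(band, freq_hz) {
  stopifnot(inherits(band, "removal_band"))
  iv <- band$intervals
  vapply(freq_hz, function(f)
    any(iv[, 1] <= f & f < iv[, 2]), logical(1))
}

#' Split a recording into consecutive non-overlapping clips
#'
#' @param signal A [multichannel_signal()].
#' @param clip_seconds Clip duration (default 2 s). A trailing remainder
#'   shorter than one clip is dropped.
#' @return List of [multichannel_signal()] clips in chronological order.
#' @export
segment_clips <- function(signal, clip_seconds = 2) {
  stopifnot(inherits(signal, "multichannel_signal"))
  if (clip_seconds <= 0) stop("clip_seconds must be > 0")
  len <- round(signal$sample_rate * clip_seconds)
  T <- n_samples(signal)
  n <- T %/% len
  if (n < 1L) stop("signal shorter than one clip")
  lapply(seq_len(n), function(i) {
    cols <- ((i - 1L) * len + 1L):(i * len)
    multichannel_signal(signal$data[, cols, drop = FALSE], signal$sample_rate,
                        signal$channel_names)
  })
}

#' Drop modes inside a removal band
#'
#' Removes whole mode sets (all channels share one center frequency) whose
#' center frequency lies in any removal interval. The residual of the
#' decomposition is also excluded from any subsequent reconstruction of the
#' denoised signal: the denoised output is the sum of retained modes only.
#' The returned object's residual is redefined as input minus the retained
#' modes, preserving the completeness identity. Idempotent.
#'
#' @param result An `svmd_decomposition`.
#' @param band A [removal_band()].
#' @return An `svmd_decomposition` holding only the retained mode sets.
#' @export
remove_modes <- function(result, band) {
  stopifnot(inherits(result, "svmd_decomposition"), inherits(band, "removal_band"))
  cf <- vapply(result$mode_sets, `[[`, numeric(1), "center_frequency_hz")
  keep <- !in_removal_band(band, cf)
  kept <- result$mode_sets[which(keep)]
  for (i in seq_along(kept)) kept[[i]]$scale_index <- i
  residual <- if (length(kept))
    result$signal$data - Reduce(`+`, lapply(kept, `[[`, "modes"))
  else result$signal$data
  structure(
    list(mode_sets = kept, residual = residual, n_scales = length(kept),
         signal = result$signal,
         diagnostics = c(result$diagnostics,
                         list(list(removed_centers_hz = cf[!keep])))),
    class = "svmd_decomposition"
  )
}

#' Denoise a recording by per-clip mode removal
#'
#' Segments the recording into non-overlapping clips, decomposes each clip,
#' drops mode sets whose center frequency falls in the removal band, sums
#' the retained modes (the residual is discarded as unassigned noise) and
#' concatenates the reconstructed clips in chronological order.
#'
#' @param signal A [multichannel_signal()].
#' @param band A [removal_band()].
#' @param config An [svmd_config()].
#' @param clip_seconds Clip duration in seconds (default 2).
#' @return A [multichannel_signal()] of length `n_clips * clip_samples`.
#' @export
denoise_recording <- function(signal, band, config = svmd_config(),
                              clip_seconds = 2) {
  clips <- segment_clips(signal, clip_seconds)
  out <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    dec <- tryCatch(
      mvsvmd(clips[[i]], config),
      svmd_convergence_error = function(e) {
        stop(sprintf("clip %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
    kept <- remove_modes(dec, band)
    out[[i]] <- reconstruct(kept, include_residual = FALSE)$data
  }
  multichannel_signal(do.call(cbind, out), signal$sample_rate,
                      signal$channel_names)
}
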