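# Successive extraction loop: one scale at a time, alpha swept coarse to
# fine, until the newest mode is indistinguishable from noise.

.pooled_peak_frequency <- function(state) {
  pow <- rowSums(abs(state$residual_fhat)^2)
  state$freqs[which.max(pow)]
}

#' Extract one common mode (one scale)
#'
#' Runs the inner ADMM loop — mode update, center-frequency update and
#' (optionally) dual ascent — until every channel's mode spectrum changes by
#' less than `epsilon1` in squared relative norm, then grows the bandwidth
#' penalty as `alpha_min + exp(m)` and repeats from the converged state,
#' stopping once the next alpha would exceed `alpha_max`. The center
#' frequency is initialized at the largest peak of the channel-pooled
#' residual power spectrum; multipliers are reset at each alpha step.
#'
#' @param state A `spectral_state` whose `residual_fhat` holds the spectra
#'   of the current working residual and whose `prior_uhat`/`prior_omegas`
#'   record the already-extracted scales.
#' @param config An [svmd_config()].
#' @return An object of class `mode_set`: `modes` (C x T time-domain
#'   matrix), `center_frequency_norm` (cycles/sample), `center_frequency_hz`,
#'   `mean_energy` (`sum_k ||u_lk||^2 / T`), `uhat` (spectra, for internal
#'   reuse) and `diagnostics` (iterations per alpha step, final alpha).
#' @export
extract_mode_at_scale <- function(state, config) {
  stopifnot(inherits(state, "spectral_state"), inherits(config, "svmd_config"))
  C <- state$n_channels
  state$omega <- .pooled_peak_frequency(state)
  state$omega_prev <- NA_real_
  state$uhat[] <- 0 + 0i
  state$lambda[] <- 0 + 0i
  state$alpha <- config$alpha_min

  iters_per_sweep <- integer(0)
  m <- 0L
  repeat {
    n <- 0L
    repeat {
      n <- n + 1L
      if (n > config$max_inner_iters) {
        stop(structure(
          class = c("svmd_convergence_error", "error", "condition"),
          list(message = sprintf(
                 "mode extraction did not converge within %d inner iterations (alpha = %g, omega = %g)",
                 config$max_inner_iters, state$alpha, state$omega),
               call = sys.call(-1),
               diagnostics = list(alpha = state$alpha, omega = state$omega,
                                  sweep = m + 1L, iterations = iters_per_sweep))))
      }
      u_old <- state$uhat
      state <- update_modes(state)
      state <- update_center_frequency(state)
      if (config$tau > 0) state <- update_multipliers(state, config$tau)
      rel <- vapply(seq_len(C), function(k) {
        dn <- sum(abs(u_old[, k])^2)
        nn <- sum(abs(state$uhat[, k] - u_old[, k])^2)
        if (dn == 0) { if (nn == 0) 0 else Inf } else nn / dn
      }, numeric(1))
      if (all(rel < config$epsilon1)) break
    }
    iters_per_sweep <- c(iters_per_sweep, n)
    m <- m + 1L
    alpha_next <- config$alpha_min + exp(m)
    if (alpha_next > config$alpha_max) break
    state$alpha <- alpha_next
    state$lambda[] <- 0 + 0i   # carry uhat and omega, reset the multipliers
  }

  modes <- .spectra_to_time(state$uhat, state)
  structure(
    list(modes = modes,
         center_frequency_norm = state$omega,
         center_frequency_hz = state$omega * state$sample_rate,
         scale_index = NA_integer_,
         mean_energy = sum(modes^2) / ncol(modes),
         uhat = state$uhat,
         diagnostics = list(alpha_final = state$alpha,
                            n_sweeps = m,
                            iterations = iters_per_sweep,
                            cost = cost_terms(state))),
    class = "mode_set"
  )
}

#' Multivariate successive variational mode decomposition
#'
#' Successively extracts common band-limited modes shared across all
#' channels. Each extracted mode is subtracted from the working residual;
#' extraction terminates when the newest mode's pooled mean energy falls
#' below `epsilon2` (that mode is regarded as noise and left inside the
#' residual), when the residual itself drops below `epsilon2`, or at
#' `max_modes`. Retained modes are sorted by center frequency ascending and
#' the residual is defined by subtraction, so the completeness identity
#' `input = sum of modes + residual` holds to machine precision.
#'
#' @param signal A [multichannel_signal()].
#' @param config An [svmd_config()]; defaults follow the canonical
#'   canine-iEEG settings.
#' @return An object of class `svmd_decomposition`: `mode_sets` (list of
#'   `mode_set`, center frequencies non-decreasing), `residual` (C x T),
#'   `n_scales`, `signal`, and `diagnostics` per extracted scale.
#' @examples
#' t <- seq(0, 2, length.out = 800)
#' x <- rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t))
#' dec <- mvsvmd(multichannel_signal(x, 400), svmd_config(max_modes = 3))
#' dec$n_scales
#' @export
mvsvmd <- function(signal, config = svmd_config()) {
  stopifnot(inherits(signal, "multichannel_signal"), inherits(config, "svmd_config"))
  T <- n_samples(signal)
  base_state <- analytic_spectrum(signal, mirror = config$mirror)
  residual <- signal$data
  mode_sets <- list()
  diagnostics <- list()

  for (l in seq_len(config$max_modes)) {
    if (sum(residual^2) / T < config$epsilon2) break
    st <- base_state
    st$prior_uhat <- lapply(mode_sets, `[[`, "uhat")
    st$prior_omegas <- vapply(mode_sets, `[[`, numeric(1), "center_frequency_norm")
    res_state <- analytic_spectrum(
      multichannel_signal(residual, signal$sample_rate), mirror = config$mirror)
    st$residual_fhat <- res_state$fhat
    ms <- extract_mode_at_scale(st, config)
    diagnostics[[length(diagnostics) + 1L]] <- c(
      list(scale = l, center_frequency_hz = ms$center_frequency_hz,
           mean_energy = ms$mean_energy), ms$diagnostics)
    if (ms$mean_energy < config$epsilon2) break  # noise-level mode: discard
    mode_sets[[length(mode_sets) + 1L]] <- ms
    residual <- residual - ms$modes
  }

  if (length(mode_sets)) {
    ord <- order(vapply(mode_sets, `[[`, numeric(1), "center_frequency_norm"))
    mode_sets <- mode_sets[ord]
    for (i in seq_along(mode_sets)) mode_sets[[i]]$scale_index <- i
    total <- Reduce(`+`, lapply(mode_sets, `[[`, "modes"))
    residual <- signal$data - total
  } else {
    residual <- signal$data
  }

  structure(
    list(mode_sets = mode_sets,
         residual = residual,
         n_scales = length(mode_sets),
         signal = signal,
         diagnostics = diagnostics),
    class = "svmd_decomposition"
  )
}

#' @export
print.svmd_decomposition <- function(x, ...) {
  cat(sprintf("<svmd_decomposition> %d scale(s), %d channel(s) x %d samples @ %g Hz\n",
              x$n_scales, nrow(x$residual), ncol(x$residual), x$signal$sample_rate))
  if (x$n_scales) {
    cf <- vapply(x$mode_sets, `[[`, numeric(1), "center_frequency_hz")
    en <- vapply(x$mode_sets, `[[`, numeric(1), "mean_energy")
    print(data.frame(scale = seq_along(cf), center_hz = round(cf, 3),
                     mean_energy = signif(en, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Partial reconstruction from selected scales
#'
#' Sums the selected mode sets sample-wise, optionally adding the residual.
#' Selecting all scales plus the residual reproduces the input (exactly, up
#' to the floating-point association of the sum that defines the residual).
#'
#' @param result An `svmd_decomposition`.
#' @param scales Integer vector of scale indices (1-based, ascending center
#'   frequency order); defaults to all scales.
#' @param include_residual Add the residual to the sum.
#' @return A [multichannel_signal()].
#' @export
reconstruct <- function(result, scales = seq_len(result$n_scales),
                        include_residual = FALSE) {
  stopifnot(inherits(result, "svmd_decomposition"))
  scales <- as.integer(scales)
  if (length(scales) && (any(scales < 1L) || any(scales > result$n_scales)))
    stop("invalid scale index: must be within 1..n_scales")
  out <- matrix(0, nrow(result$residual), ncol(result$residual))
  for (s in scales) out <- out + result$mode_sets[[s]]$modes
  if (include_residual) out <- out + result$residual
  multichannel_signal(out, result$signal$sample_rate,
                      result$signal$channel_names)
}

#' Mode-count and center-frequency distributions over many decompositions
#'
#' Summarizes a batch of decompositions the way mode-population diagnostics
#' are usually displayed: a histogram of the number of extracted scales, and
#' per ordinal scale (1st, 2nd, ... after frequency sorting) the range and
#' quartiles of center frequencies across the batch.
#'
#' @param results List of `svmd_decomposition` objects (at least one).
#' @return List with `count_histogram` (named table) and `scale_frequency`
#'   (data frame: scale, n, min, q25, median, q75, max in Hz).
#' @export
scale_statistics <- function(results) {
  if (!length(results)) stop("need at least one decomposition result")
  stopifnot(all(vapply(results, inherits, logical(1), "svmd_decomposition")))
  counts <- vapply(results, `[[`, numeric(1), "n_scales")
  hist <- table(counts)
  max_s <- max(counts)
  if (max_s == 0) {
    return(list(count_histogram = hist,
                scale_frequency = data.frame(scale = integer(0), n = integer(0),
                                             min = numeric(0), q25 = numeric(0),
                                             median = numeric(0), q75 = numeric(0),
                                             max = numeric(0))))
  }
  rows <- lapply(seq_len(max_s), function(s) {
    cf <- unlist(lapply(results, function(r)
      if (r$n_scales >= s) r$mode_sets[[s]]$center_frequency_hz else NULL))
    q <- stats::quantile(cf, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(scale = s, n = length(cf), min = min(cf),
               q25 = q[1], median = q[2], q75 = q[3], max = max(cf))
  })
  list(count_histogram = hist,
       scale_frequency = do.call(rbind, rows))
}
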