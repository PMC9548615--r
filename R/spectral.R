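# Spectral-domain state and ADMM update steps for multivariate SVMD.
# All frequencies are normalized (cycles/sample) on the one-sided grid
# omega >= 0; real signals are recovered by conjugate symmetry.

.mirror_extend <- function(x) {
  # reflect at both boundaries; total length is always 2*T
  T <- length(x)
  half <- T %/% 2L
  c(rev(x[seq_len(half)]), x, rev(x[(half + 1L):T]))
}

#' One-sided analytic spectrum of a multichannel signal
#'
#' Transforms every channel to the spectral domain (optionally after mirror
#' extension at both boundaries) and sets up the state on which the ADMM
#' update steps operate: the fixed signal spectra, the current mode spectra
#' (initialized to zero), Lagrange multipliers, and bookkeeping for prior
#' scales. Only non-negative frequencies are kept; [spectrum_to_signal()]
#' inverts by conjugate symmetry and trims the mirror padding.
#'
#' @param signal A [multichannel_signal()].
#' @param mirror Reflect the signal at both ends before transforming.
#' @return An object of class `spectral_state`. Fields of interest:
#'   `fhat` (K x C complex one-sided signal spectra), `uhat` (current mode
#'   spectra), `lambda` (multipliers), `freqs` (normalized frequency grid),
#'   `omega` (current center frequency), `prior_uhat` / `prior_omegas`
#'   (already-extracted scales) and `alpha` (current penalty).
#' @export
analytic_spectrum <- function(signal, mirror = TRUE) {
  stopifnot(inherits(signal, "multichannel_signal"))
  C <- n_channels(signal); T <- n_samples(signal)
  if (mirror) {
    ext <- t(apply(signal$data, 1L, .mirror_extend))
    trim_start <- (T %/% 2L) + 1L
  } else {
    ext <- signal$data
    trim_start <- 1L
  }
  Text <- ncol(ext)
  full <- stats::mvfft(t(ext))              # Text x C complex
  K <- (Text %/% 2L) + 1L
  state <- list(
    fhat = full[seq_len(K), , drop = FALSE],
    uhat = matrix(0 + 0i, K, C),
    lambda = matrix(0 + 0i, K, C),
    prior_uhat = list(),
    prior_omegas = numeric(0),
    residual_fhat = full[seq_len(K), , drop = FALSE],
    omega = NA_real_,
    omega_prev = NA_real_,
    alpha = NA_real_,
    freqs = (seq_len(K) - 1) / Text,
    n_ext = Text, n_orig = T, n_channels = C,
    trim_start = trim_start,
    sample_rate = signal$sample_rate,
    mirror = isTRUE(mirror)
  )
  class(state) <- "spectral_state"
  state
}

# one-sided K x C spectra -> C x T_orig real time-domain matrix
.spectra_to_time <- function(S, state) {
  K <- nrow(S); Text <- state$n_ext
  neg_idx <- if (Text %% 2L == 0L) seq(K - 1L, 2L) else seq(K, 2L)
  full <- rbind(S, Conj(S[neg_idx, , drop = FALSE]))
  tm <- Re(stats::mvfft(full, inverse = TRUE)) / Text
  rows <- state$trim_start:(state$trim_start + state$n_orig - 1L)
  t(tm[rows, , drop = FALSE])
}

#' Invert a spectral state back to the time domain
#'
#' Applies conjugate symmetry to the one-sided spectra, inverse-transforms,
#' and trims any mirror padding. Inverting an unmodified state returns the
#' original signal.
#'
#' @param state A `spectral_state`.
#' @param which `"signal"` inverts the fixed signal spectra `fhat`,
#'   `"mode"` the current mode spectra `uhat`.
#' @return A [multichannel_signal()].
#' @export
spectrum_to_signal <- function(state, which = c("signal", "mode")) {
  stopifnot(inherits(state, "spectral_state"))
  which <- match.arg(which)
  S <- if (which == "signal") state$fhat else state$uhat
  multichannel_signal(.spectra_to_time(S, state), state$sample_rate)
}

# prior-penalty vector sum_i 1/(alpha^2 (w - w_i)^4), plus exact-hit mask
.prior_penalty <- function(freqs, prior_omegas, alpha) {
  pen <- numeric(length(freqs))
  hit <- logical(length(freqs))
  for (wi in prior_omegas) {
    d <- freqs - wi
    z <- d == 0
    hit <- hit | z
    d[z] <- 1  # placeholder; masked bins are zeroed by the caller
    pen <- pen + 1 / (alpha^2 * d^4)
  }
  list(pen = pen, hit = hit)
}

#' One ADMM mode-update step
#'
#' Updates every channel's current mode spectrum independently by the
#' Wiener-type filter of the mode subproblem:
#' \deqn{\hat u_{lk}^{n+1}(\omega) = \frac{\hat f_k(\omega) +
#'   \alpha^2(\omega-\omega_l)^4 \hat u_{lk}^{n}(\omega) + \hat\lambda_k/2}
#'   {[1+\alpha^2(\omega-\omega_l)^4]
#'    [1 + 2\alpha(\omega-\omega_l)^2 +
#'     \sum_{i<l} \alpha^{-2}(\omega-\omega_i)^{-4}]}}
#' At bins where \eqn{\omega} coincides exactly with a prior center
#' frequency the penalty diverges and the updated value is 0 (the
#' continuous limit).
#'
#' @param state A `spectral_state` with `alpha` and `omega` set.
#' @return The state with `uhat` replaced by the updated mode spectra.
#' @export
update_modes <- function(state) {
  stopifnot(inherits(state, "spectral_state"))
  if (!is.finite(state$alpha) || state$alpha <= 0) stop("alpha must be set and > 0")
  if (!is.finite(state$omega)) stop("omega must be set")
  w <- state$freqs
  d <- w - state$omega
  A <- state$alpha^2 * d^4
  pp <- .prior_penalty(w, state$prior_omegas, state$alpha)
  denom <- (1 + A) * (1 + 2 * state$alpha * d^2 + pp$pen)
  unew <- (state$fhat + A * state$uhat + state$lambda / 2) / denom
  if (any(pp$hit)) unew[pp$hit, ] <- 0 + 0i
  state$uhat <- unew
  state
}

#' Pooled spectral centroid of the current mode
#'
#' The power-weighted mean frequency of the current mode spectra, pooled
#' over channels, evaluated by the trapezoid rule on the one-sided grid:
#' \deqn{\omega_l = \frac{\sum_k \int_0^\infty \omega\,|\hat u_{lk}|^2
#'   d\omega}{\sum_k \int_0^\infty |\hat u_{lk}|^2 d\omega}}
#'
#' @param state A `spectral_state`.
#' @return Normalized center frequency (cycles/sample), guaranteed to lie
#'   within the frequency support of the nonzero spectrum.
#' @export
spectral_centroid <- function(state) {
  stopifnot(inherits(state, "spectral_state"))
  pow <- rowSums(abs(state$uhat)^2)
  K <- length(pow)
  wt <- c(0.5, rep(1, K - 2L), 0.5)
  E <- sum(wt * pow)
  if (E <= 0) stop("degenerate mode: zero spectral energy, no centroid")
  sum(wt * state$freqs * pow) / E
}

#' @rdname spectral_centroid
#' @return `update_center_frequency()` returns the state with `omega`
#'   replaced by the centroid (the previous value is kept in `omega_prev`).
#' @export
update_center_frequency <- function(state) {
  wl <- spectral_centroid(state)
  state$omega_prev <- state$omega
  state$omega <- wl
  state
}

# spectrum of the unprocessed part f_u, as printed in the dual-ascent step:
# numerator uses omega_prev (the pre-update center), denominator the updated one
.fu_hat <- function(state) {
  w <- state$freqs
  wp <- if (is.finite(state$omega_prev)) state$omega_prev else state$omega
  prior_sum <- if (length(state$prior_uhat))
    Reduce(`+`, state$prior_uhat) else matrix(0 + 0i, nrow(state$fhat), state$n_channels)
  num_gain <- state$alpha^2 * (w - wp)^4
  den <- 1 + state$alpha^2 * (w - state$omega)^4
  (num_gain * (state$fhat - state$uhat - prior_sum + state$lambda / 2)) / den
}

#' Dual-ascent multiplier update
#'
#' Moves each channel's Lagrange multiplier along the reconstruction
#' constraint violation, `lambda <- lambda + tau * (fhat - (uhat + fu_hat +
#' sum of prior modes))`, where `fu_hat` is the spectrum of the unprocessed
#' part implied by its own subproblem. With `tau = 0` the multipliers stay
#' at zero.
#'
#' @param state A `spectral_state`.
#' @param tau Dual-ascent step size (>= 0).
#' @return The state with updated `lambda`.
#' @export
update_multipliers <- function(state, tau) {
  stopifnot(inherits(state, "spectral_state"))
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(state)
  prior_sum <- if (length(state$prior_uhat))
    Reduce(`+`, state$prior_uhat) else matrix(0 + 0i, nrow(state$fhat), state$n_channels)
  violation <- state$fhat - (state$uhat + .fu_hat(state) + prior_sum)
  state$lambda <- state$lambda + tau * violation
  state
}

#' Variational cost terms (diagnostics)
#'
#' Evaluates the three cost terms of the scale-l variational problem on the
#' one-sided grid: `L1`, the pooled bandwidth of the current mode around its
#' center frequency; `L2`, the energy of everything that is not the current
#' mode after passing through the scale-l filter (spectral overlap with the
#' rest of the signal); and `L3`, the energy of the current mode seen
#' through the filters of previously extracted scales (overlap with prior
#' modes). Bins where a filter's center frequency is hit exactly are
#' skipped (the filter response is singular there; grid hits are
#' measure-zero).
#'
#' @param state A `spectral_state` with `alpha` and `omega` set.
#' @return Named numeric vector `c(L1 =, L2 =, L3 =)`, all non-negative.
#' @export
cost_terms <- function(state) {
  stopifnot(inherits(state, "spectral_state"))
  w <- state$freqs
  upow <- abs(state$uhat)^2
  L1 <- sum((w - state$omega)^2 * upow)
  keep <- w != state$omega
  beta_l <- 1 / (state$alpha * (w[keep] - state$omega)^2)
  L2 <- sum(beta_l^2 * rowSums(abs(state$fhat - state$uhat)[keep, , drop = FALSE]^2))
  L3 <- 0
  for (wi in state$prior_omegas) {
    ki <- w != wi
    beta_i <- 1 / (state$alpha * (w[ki] - wi)^2)
    L3 <- L3 + sum(beta_i^2 * rowSums(upow[ki, , drop = FALSE]))
  }
  c(L1 = L1, L2 = L2, L3 = L3)
}
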