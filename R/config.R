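#' Decomposition configuration
#'
#' Parameters controlling multivariate successive variational mode
#' decomposition. The penalty factor alpha sets the bandwidth of extracted
#' modes (larger alpha, narrower modes); within each scale alpha is swept
#' from `alpha_min` upward as `alpha_min + exp(m)` until it would exceed
#' `alpha_max`, a coarse-to-fine search for the strongest mode in the
#' residual. `epsilon1` is the squared relative-change tolerance of the
#' inner ADMM loop, `epsilon2` the pooled mean-energy threshold below which
#' a freshly extracted mode is regarded as noise and extraction stops.
#'
#' The canonical alpha ranges are \[200, 800\] for 400 Hz canine iEEG and
#' \[200, 2000\] for human iEEG resampled to 500 Hz.
#'
#' @param alpha_min,alpha_max Bandwidth penalty sweep range (dimensionless,
#'   applied on normalized frequency in cycles/sample).
#' @param epsilon1 Inner-loop convergence tolerance on the squared relative
#'   change of each channel's mode spectrum.
#' @param epsilon2 Noise-energy threshold: extraction stops when the newest
#'   mode's pooled mean energy `sum_k ||u_lk||^2 / T` falls below it.
#' @param tau Dual-ascent step for the Lagrange multipliers; 0 (default)
#'   disables the multipliers, the standard noise-robust choice.
#' @param max_modes Safety cap on the number of extracted scales.
#' @param max_inner_iters Safety cap on inner ADMM iterations per alpha step.
#' @param mirror Mirror-extend the signal at both ends before the transform
#'   (recommended; suppresses boundary splatter).
#' @return An object of class `svmd_config`.
#' @export
svmd_config <- function(alpha_min = 200, alpha_max = 800,
                        epsilon1 = 1e-6, epsilon2 = 1e-3,
                        tau = 0, max_modes = 15L, max_inner_iters = 300L,
                        mirror = TRUE) {
  if (!(alpha_min > 0 && alpha_min <= alpha_max))
    stop("need 0 < alpha_min <= alpha_max")
  if (epsilon1 <= 0 || epsilon2 <= 0) stop("epsilon1 and epsilon2 must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  if (max_modes < 1) stop("max_modes must be >= 1")
  if (max_inner_iters < 1) stop("max_inner_iters must be >= 1")
  structure(
    list(alpha_min = alpha_min, alpha_max = alpha_max,
         epsilon1 = epsilon1, epsilon2 = epsilon2, tau = tau,
         max_modes = as.integer(max_modes),
         max_inner_iters = as.integer(max_inner_iters),
         mirror = isTRUE(mirror)),
    class = "svmd_config"
  )
}
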