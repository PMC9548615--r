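# Independent oracles, coded directly from the printed formulas with
# explicit per-bin loops, kept separate from the package's vectorized
# implementation paths.

# one mode-update step, bin by bin
oracle_mode_update <- function(fhat, uhat, lambda, freqs, omega, prior_omegas,
                               alpha) {
  K <- nrow(fhat); C <- ncol(fhat)
  out <- matrix(0 + 0i, K, C)
  for (b in seq_len(K)) {
    w <- freqs[b]
    if (length(prior_omegas) && any(w == prior_omegas)) next  # divergent penalty
    pen <- 0
    for (wi in prior_omegas) pen <- pen + 1 / (alpha^2 * (w - wi)^4)
    A <- alpha^2 * (w - omega)^4
    den <- (1 + A) * (1 + 2 * alpha * (w - omega)^2 + pen)
    for (k in seq_len(C))
      out[b, k] <- (fhat[b, k] + A * uhat[b, k] + lambda[b, k] / 2) / den
  }
  out
}

# pooled trapezoid-rule centroid via pracma::trapz
oracle_centroid <- function(uhat, freqs) {
  pow <- rowSums(abs(uhat)^2)
  pracma::trapz(freqs, freqs * pow) / pracma::trapz(freqs, pow)
}

# dual-ascent step, bin by bin
oracle_dual_step <- function(fhat, uhat, lambda, freqs, omega, omega_prev,
                             prior_sum, alpha, tau) {
  K <- nrow(fhat); C <- ncol(fhat)
  out <- lambda
  for (b in seq_len(K)) {
    w <- freqs[b]
    for (k in seq_len(C)) {
      fu <- alpha^2 * (w - omega_prev)^4 *
        (fhat[b, k] - uhat[b, k] - prior_sum[b, k] + lambda[b, k] / 2) /
        (1 + alpha^2 * (w - omega)^4)
      out[b, k] <- lambda[b, k] +
        tau * (fhat[b, k] - (uhat[b, k] + fu + prior_sum[b, k]))
    }
  }
  out
}

# cost terms by direct summation
oracle_cost_terms <- function(fhat, uhat, freqs, omega, prior_omegas, alpha) {
  K <- nrow(fhat); C <- ncol(fhat)
  L1 <- 0; L2 <- 0; L3 <- 0
  for (b in seq_len(K)) {
    w <- freqs[b]
    for (k in seq_len(C)) {
      L1 <- L1 + (w - omega)^2 * abs(uhat[b, k])^2
      if (w != omega)
        L2 <- L2 + abs(fhat[b, k] - uhat[b, k])^2 / (alpha * (w - omega)^2)^2
      for (wi in prior_omegas)
        if (w != wi)
          L3 <- L3 + abs(uhat[b, k])^2 / (alpha * (w - wi)^2)^2
    }
  }
  c(L1 = L1, L2 = L2, L3 = L3)
}

# full univariate successive decomposition, coded independently (plain fft,
# per-bin loops) following the printed algorithm
svmd_uni_oracle <- function(x, fs, cfg) {
  T <- length(x); half <- T %/% 2L
  mirror <- function(v) c(rev(v[seq_len(half)]), v, rev(v[(half + 1L):T]))
  ext <- mirror(x)
  Text <- length(ext)
  K <- Text %/% 2L + 1L
  freqs <- (0:(K - 1)) / Text
  fhat <- stats::fft(ext)[seq_len(K)]
  to_time <- function(S) {
    neg <- if (Text %% 2L == 0L) seq(K - 1L, 2L) else seq(K, 2L)
    full <- c(S, Conj(S[neg]))
    Re(stats::fft(full, inverse = TRUE))[(half + 1L):(half + T)] / Text
  }
  residual <- x
  modes <- list(); omegas <- numeric(0)
  for (l in seq_len(cfg$max_modes)) {
    if (sum(residual^2) / T < cfg$epsilon2) break
    rpow <- abs(stats::fft(mirror(residual))[seq_len(K)])^2
    omega <- freqs[which.max(rpow)]
    uhat <- rep(0 + 0i, K); lambda <- rep(0 + 0i, K)
    alpha <- cfg$alpha_min; m <- 0L
    repeat {
      repeat {
        u_old <- uhat
        pen <- numeric(K); hit <- logical(K)
        for (wi in omegas) {
          d <- freqs - wi; z <- d == 0; hit <- hit | z; d[z] <- 1
          pen <- pen + 1 / (alpha^2 * d^4)
        }
        d <- freqs - omega; A <- alpha^2 * d^4
        uhat <- (fhat + A * uhat + lambda / 2) /
          ((1 + A) * (1 + 2 * alpha * d^2 + pen))
        uhat[hit] <- 0 + 0i
        pow <- abs(uhat)^2
        wt <- c(0.5, rep(1, K - 2L), 0.5)
        omega <- sum(wt * freqs * pow) / sum(wt * pow)
        dn <- sum(abs(u_old)^2); nn <- sum(abs(uhat - u_old)^2)
        rel <- if (dn == 0) (if (nn == 0) 0 else Inf) else nn / dn
        if (rel < cfg$epsilon1) break
      }
      m <- m + 1L
      alpha_next <- cfg$alpha_min + exp(m)
      if (alpha_next > cfg$alpha_max) break
      alpha <- alpha_next
      lambda[] <- 0 + 0i
    }
    u <- to_time(uhat)
    if (sum(u^2) / T < cfg$epsilon2) break
    modes[[length(modes) + 1L]] <- u
    omegas <- c(omegas, omega)
    residual <- residual - u
  }
  ord <- order(omegas)
  modes <- modes[ord]
  list(modes = modes, omegas = omegas[ord],
       residual = if (length(modes)) x - Reduce(`+`, modes) else x)
}

# sliding-window alarm logic by exhaustive recount
oracle_alarms <- function(times, labels, span_start, window_s, frac, refractory_s) {
  alarms <- numeric(0); last <- -Inf
  for (j in seq_along(times)) {
    tj <- times[j]
    if (tj < span_start + window_s) next
    if (tj < last + refractory_s) next
    inside <- which(times > tj - window_s & times <= tj)
    if (sum(labels[inside]) / length(inside) > frac) {
      alarms <- c(alarms, tj); last <- tj
    }
  }
  alarms
}

# upper-tail binomial probability by enumeration over all 2^M outcomes
oracle_binom_tail <- function(M, m, P) {
  total <- 0
  for (pattern in 0:(2^M - 1)) {
    bits <- as.integer(intToBits(pattern))[seq_len(M)]
    s <- sum(bits)
    if (s >= m) total <- total + P^s * (1 - P)^(M - s)
  }
  total
}

# spec-shaped random spectral state for update-step oracles
rand_state <- function(K = 65L, C = 2L, n_priors = 0L, seed = 1L,
                       priors_on_grid = FALSE) {
  set.seed(seed)
  Text <- 2L * (K - 1L)
  freqs <- (0:(K - 1)) / Text
  rc <- function() matrix(complex(real = rnorm(K * C), imaginary = rnorm(K * C)), K, C)
  prior_omegas <- if (n_priors) {
    if (priors_on_grid) sample(freqs[-1], n_priors) else runif(n_priors, 0.05, 0.45)
  } else numeric(0)
  st <- list(
    fhat = rc(), uhat = rc(), lambda = rc(),
    prior_uhat = lapply(seq_len(n_priors), function(i) rc()),
    prior_omegas = prior_omegas,
    residual_fhat = rc(),
    omega = sample(freqs[2:(K - 1L)], 1L),
    omega_prev = sample(freqs[2:(K - 1L)], 1L),
    alpha = runif(1, 100, 1000),
    freqs = freqs, n_ext = Text, n_orig = K - 1L, n_channels = C,
    trim_start = 1L, sample_rate = 400, mirror = FALSE
  )
  class(st) <- "spectral_state"
  st
}
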