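test_that("analytic spectrum localizes energy and round-trips losslessly", {
  # DC signal: all energy in the omega = 0 bin
  dc <- multichannel_signal(matrix(1, 1, 64), 64)
  st <- analytic_spectrum(dc)
  pow <- abs(st$fhat[, 1])^2
  expect_equal(which.max(pow), 1L)
  expect_lt(sum(pow[-1]) / sum(pow), 1e-20)

  # pure 10 Hz cosine at fs = 400: single dominant bin at 10 Hz
  tone <- tone_signal(10, 1, 1, 1, 400)
  st <- analytic_spectrum(tone)
  expect_equal(st$freqs[which.max(abs(st$fhat[, 1]))] * 400, 10, tolerance = 1e-12)

  # random round trip, with and without mirror extension
  set.seed(11)
  sig <- multichannel_signal(matrix(rnorm(3 * 101), 3, 101), 100)
  for (mirror in c(TRUE, FALSE)) {
    back <- spectrum_to_signal(analytic_spectrum(sig, mirror = mirror))
    expect_lt(max(abs(back$data - sig$data)), 1e-10)
  }

  expect_error(multichannel_signal(matrix(c(1, NA, 1:6), 1, 8), 10),
               "non-finite")
})

test_that("mode update has unit gain at the center, zeros at prior centers, and matches the direct formula", {
  # l = 1, lambda = 0: at omega = omega_l the update returns fhat exactly
  st <- rand_state(K = 33L, C = 2L, seed = 5)
  st$lambda[] <- 0 + 0i
  b <- which(st$freqs == st$omega)
  up <- update_modes(st)
  expect_identical(up$uhat[b, ], st$fhat[b, ])

  # with a prior center on the grid, the updated value there is 0
  st2 <- rand_state(K = 33L, C = 2L, n_priors = 1L, seed = 6, priors_on_grid = TRUE)
  b2 <- which(st2$freqs == st2$prior_omegas[1])
  up2 <- update_modes(st2)
  expect_true(all(up2$uhat[b2, ] == 0 + 0i))

  # random states: bin-by-bin direct evaluation to 1e-12
  for (seed in 1:5) {
    st <- rand_state(K = 49L, C = 3L, n_priors = 2L, seed = seed)
    got <- update_modes(st)$uhat
    want <- oracle_mode_update(st$fhat, st$uhat, st$lambda, st$freqs,
                               st$omega, st$prior_omegas, st$alpha)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("spectral centroid is the pooled power-weighted mean frequency", {
  st <- rand_state(K = 65L, C = 2L, seed = 2)
  st$uhat[] <- 0 + 0i
  b1 <- which.min(abs(st$freqs - 0.1))

  # all energy in one bin
  st$uhat[b1, 1] <- 3 + 0i
  expect_equal(spectral_centroid(st), st$freqs[b1], tolerance = 1e-14)

  # equal energy in bins at 0.1 and 0.2 (split across channels)
  b2 <- which.min(abs(st$freqs - 0.2))
  st$uhat[b2, 2] <- 0 - 3i
  expect_equal(spectral_centroid(st), (st$freqs[b1] + st$freqs[b2]) / 2,
               tolerance = 1e-14)

  # Gaussian bump: equals the trapezoid-rule quotient on the same bins
  st$uhat <- matrix(complex(modulus = exp(-((st$freqs - 0.22) / 0.04)^2),
                            argument = seq(0, 3, length.out = 65)), 65, 2)
  expect_equal(spectral_centroid(st), oracle_centroid(st$uhat, st$freqs),
               tolerance = 1e-10)

  # bounds and monotonicity under an upward shift of all spectral mass
  supp <- range(st$freqs[rowSums(abs(st$uhat)^2) > 0])
  cen <- spectral_centroid(st)
  expect_gte(cen, supp[1]); expect_lte(cen, supp[2])
  st_up <- st
  st_up$uhat <- rbind(matrix(0 + 0i, 3, 2), st$uhat[1:62, ])
  expect_gt(spectral_centroid(st_up), cen)

  st$uhat[] <- 0 + 0i
  expect_error(spectral_centroid(st), "degenerate")
})

test_that("dual ascent is inert at tau = 0 and at exact reconstruction, and matches the direct formula", {
  st <- rand_state(K = 33L, C = 2L, n_priors = 1L, seed = 9)
  expect_identical(update_multipliers(st, 0)$lambda, st$lambda)

  # exact reconstruction: fhat = uhat + prior modes, lambda = 0 -> no move
  st0 <- st
  st0$lambda[] <- 0 + 0i
  st0$fhat <- st0$uhat + st0$prior_uhat[[1]]
  expect_equal(update_multipliers(st0, 0.1)$lambda, st0$lambda)

  for (seed in 1:5) {
    st <- rand_state(K = 41L, C = 2L, n_priors = 2L, seed = seed)
    got <- update_multipliers(st, 0.1)$lambda
    want <- oracle_dual_step(st$fhat, st$uhat, st$lambda, st$freqs, st$omega,
                             st$omega_prev, Reduce(`+`, st$prior_uhat),
                             st$alpha, 0.1)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("cost terms are non-negative and match direct summation", {
  st <- rand_state(K = 33L, C = 2L, n_priors = 2L, seed = 4)
  # zero current mode: L1 = L3 = 0
  st0 <- st; st0$uhat[] <- 0 + 0i
  ct0 <- cost_terms(st0)
  expect_equal(unname(ct0[c("L1", "L3")]), c(0, 0))
  # no priors: L3 = 0
  st1 <- st; st1$prior_omegas <- numeric(0); st1$prior_uhat <- list()
  expect_equal(unname(cost_terms(st1)["L3"]), 0)

  ct <- cost_terms(st)
  expect_true(all(ct >= 0))
  want <- oracle_cost_terms(st$fhat, st$uhat, st$freqs, st$omega,
                            st$prior_omegas, st$alpha)
  expect_equal(ct, want, tolerance = 1e-10)
})

test_that("single-scale extraction recovers a pure tone and starts at the dominant peak", {
  cfg <- svmd_config()
  # C = 2 pure 25 Hz cosine: center within 1 Hz, mode correlation > 0.99
  sig <- tone_signal(25, 1, 2, 2, 400)
  st <- analytic_spectrum(sig)
  ms <- extract_mode_at_scale(st, cfg)
  expect_lt(abs(ms$center_frequency_hz - 25), 1)
  for (k in 1:2) expect_gt(cor(ms$modes[k, ], sig$data[k, ]), 0.99)

  # 10 Hz + 60 Hz with the 60 Hz tone stronger: first extraction centers there
  sig2 <- tone_signal(c(10, 60), c(0.5, 1), 2, 2, 400)
  st2 <- analytic_spectrum(sig2)
  peak_hz <- st2$freqs[which.max(rowSums(abs(st2$residual_fhat)^2))] * 400
  expect_lt(abs(peak_hz - 60), 1)  # peak-initialization oracle
  ms2 <- extract_mode_at_scale(st2, cfg)
  expect_lt(abs(ms2$center_frequency_hz - 60), 1)

  # exhausting the iteration budget raises a convergence error with context
  expect_error(extract_mode_at_scale(st2, svmd_config(max_inner_iters = 1L)),
               class = "svmd_convergence_error")
})

test_that("successive decomposition retains exactly the true tones and is complete", {
  # 3 channels, 10 + 40 Hz tones plus sigma = 0.05 noise, 2 s at 400 Hz
  sig <- tone_signal(c(10, 40), c(1, 1), 3, 2, 400, noise_sigma = 0.05, seed = 42)
  dec <- mvsvmd(sig, svmd_config())
  expect_equal(dec$n_scales, 2L)
  cf <- vapply(dec$mode_sets, `[[`, numeric(1), "center_frequency_hz")
  expect_lt(abs(cf[1] - 10), 1)
  expect_lt(abs(cf[2] - 40), 1)
  expect_true(!is.unsorted(cf))

  # completeness: input - (sum of modes + residual) is exactly zero
  total <- Reduce(`+`, lapply(dec$mode_sets, `[[`, "modes"))
  expect_true(all(sig$data - total - dec$residual == 0))

  # zero signal: no modes, zero residual
  z <- mvsvmd(multichannel_signal(matrix(0, 2, 64), 32), svmd_config())
  expect_equal(z$n_scales, 0L)
  expect_true(all(z$residual == 0))
})

test_that("the multivariate path reduces to an independently coded univariate run at C = 1", {
  cfg <- svmd_config()
  sig <- tone_signal(c(12, 45), c(1, 0.8), 1, 2, 400, noise_sigma = 0.02, seed = 8)
  dec <- mvsvmd(sig, cfg)
  ora <- svmd_uni_oracle(sig$data[1, ], 400, cfg)
  expect_equal(dec$n_scales, length(ora$modes))
  for (i in seq_len(dec$n_scales)) {
    expect_lt(abs(dec$mode_sets[[i]]$center_frequency_norm - ora$omegas[i]), 1e-10)
    expect_lt(max(abs(dec$mode_sets[[i]]$modes[1, ] - ora$modes[[i]])), 1e-10)
  }
  expect_lt(max(abs(dec$residual[1, ] - ora$residual)), 1e-10)
})

test_that("the converged mode spectrum is a fixed point of the update", {
  cfg <- svmd_config()
  sig <- tone_signal(25, 1, 2, 2, 400)
  st <- analytic_spectrum(sig)
  ms <- extract_mode_at_scale(st, cfg)
  st$uhat <- ms$uhat
  st$omega <- ms$center_frequency_norm
  st$alpha <- ms$diagnostics$alpha_final
  re <- update_modes(st)
  for (k in 1:2) {
    rel <- sum(abs(re$uhat[, k] - st$uhat[, k])^2) / sum(abs(st$uhat[, k])^2)
    expect_lt(rel, cfg$epsilon1)
  }
})

test_that("center frequencies and waveforms are recovered across channel counts at 20 dB SNR", {
  for (C in c(2L, 4L)) {
    sig <- tone_signal(c(10, 40), c(1, 1), C, 2, 400, noise_sigma = 0.1,
                       seed = 100 + C)
    truth <- tone_signal(c(10, 40), c(1, 1), C, 2, 400)
    dec <- mvsvmd(sig, svmd_config())
    cf <- vapply(dec$mode_sets, `[[`, numeric(1), "center_frequency_hz")
    expect_true(!is.unsorted(cf))
    for (f0 in c(10, 40)) {
      i <- which.min(abs(cf - f0))
      expect_lt(abs(cf[i] - f0), 1)
      tt <- (0:799) / 400
      for (k in seq_len(C)) {
        ref <- cos(2 * pi * f0 * tt + 0.4 * k + 0.2 * which(c(10, 40) == f0))
        expect_gt(cor(dec$mode_sets[[i]]$modes[k, ], ref), 0.95)
      }
    }
  }
})

test_that("partial reconstruction selects scales and preserves completeness", {
  sig <- tone_signal(c(10, 40), c(1, 1), 2, 2, 400, noise_sigma = 0.03, seed = 3)
  dec <- mvsvmd(sig, svmd_config())
  expect_equal(dec$n_scales, 2L)

  full <- reconstruct(dec, include_residual = TRUE)
  expect_lt(max(abs(full$data - sig$data)), 1e-12)

  none <- reconstruct(dec, scales = integer(0))
  expect_true(all(none$data == 0))

  low <- reconstruct(dec, scales = 1L)
  for (k in 1:2)
    expect_gt(band_energy_fraction(low$data[k, ], 400, 0, 20), 0.9)

  expect_error(reconstruct(dec, scales = 5L), "invalid scale index")
})

test_that("scale statistics aggregate mode counts and per-scale frequency ranges", {
  one <- fake_decomposition(c(10, 40, 90))
  stats10 <- scale_statistics(rep(list(one), 10))
  expect_equal(as.integer(stats10$count_histogram["3"]), 10L)

  batch <- list(fake_decomposition(c(10, 40)), fake_decomposition(c(11, 42)),
                fake_decomposition(c(9, 38, 80)))
  st <- scale_statistics(batch)
  expect_equal(as.integer(st$count_histogram[c("2", "3")]), c(2L, 1L))
  # hand-computed per-scale ranges
  expect_equal(st$scale_frequency$min, c(9, 38, 80))
  expect_equal(st$scale_frequency$max, c(11, 42, 80))
  expect_equal(st$scale_frequency$n, c(3L, 3L, 1L))
})
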