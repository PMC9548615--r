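# mvsvmd

Multivariate successive variational mode decomposition (SVMD) for
multi-channel biomedical time series, with the complete scaffold of a
patient-specific seizure-prediction pipeline built around it.

## The problem

Intracranial EEG is recorded from many electrodes at once, and the
oscillatory components that matter — and the artifacts that do not — live in
narrow frequency bands that differ by subject. Classic empirical mode
decomposition is adaptive but fragile; standard variational mode
decomposition (VMD) is robust but requires fixing the number of modes in
advance and treats each channel separately. Successive VMD extracts one
narrow-band mode at a time until only noise is left, and this package
extends it across channels: at each scale `l` it finds a *common* center
frequency `ω_l` and one band-limited mode per channel,

    f_k(t) = Σ_{i=1..L} u_ik(t) + residual,   k = 1..C,

by minimizing, over `u_lk` and `ω_l`, the pooled bandwidth of the current
modes around `ω_l` plus penalties against spectral overlap with everything
already extracted and everything not yet explained, subject to exact
reconstruction. The problem is solved in the spectral domain by ADMM: a
Wiener-type filter update for each channel's mode spectrum, a pooled
power-weighted centroid update for `ω_l`, and (optionally) dual ascent on
the reconstruction constraint, with the bandwidth penalty `α` swept from
coarse to fine. Extraction stops when the newest mode's pooled mean energy
falls below a noise threshold.

Around the decomposition, the package implements the full prediction chain:
per-clip decomposition and removal of subject-specific irrelevant frequency
bands (denoising), STFT band-power feature tensors (30-s samples, 1-s
windows with 75% overlap, 2-Hz bands up to 140 Hz), a Hadamard
data-embedding scheme with a pluggable classifier contract and
majority-vote ensembling, sliding-window alarm logic scored with SPH/SOP
conventions, and significance testing against the analytic random
predictor `P = 1 − exp(−FPR·SOP)`, `p = Σ_{i≥m} C(M,i) P^i (1−P)^{M−i}`.

A seeded synthetic-data generator produces multichannel recordings with
known band-limited modes and toy seizure timelines, so every stage is
testable without clinical data.

## Worked example

```r
library(mvsvmd)

modes <- list(synthetic_mode(10, amplitude = 1, am_depth = 0.3, am_rate_hz = 0.5),
              synthetic_mode(40, amplitude = 0.8))
rec <- generate_recording(modes, n_channels = 3, duration_s = 2,
                          sample_rate = 400, noise_sigma = 0.05, seed = 1)

dec <- mvsvmd(rec$signal, svmd_config(alpha_min = 200, alpha_max = 800))
dec
#> <svmd_decomposition> 2 scale(s), 3 channel(s) x 800 samples @ 400 Hz
#>  scale center_hz mean_energy
#>      1    10.001      1.5680
#>      2    40.002      0.8124
```

Both planted tones are recovered as common modes (centers within
thousandths of a hertz of 10 and 40 Hz); the broadband noise stays in the
residual because its pooled mean energy falls below the `epsilon2 = 1e-3`
noise threshold. Removing the alpha-band mode denoises the recording:

```r
den <- denoise_recording(rec$signal, removal_band(c(5, 15)), svmd_config())
# spectral energy in 5-15 Hz, channel 1: before 209.904, after 0.00011
```

and the evaluation side reproduces published significance numbers — for a
subject with both of 2 seizures predicted at a false prediction rate of
0.36/h and a 20-min seizure occurrence period:

```r
random_predictor_pvalue(0.36, sop_hours = 20/60, n_seizures = 2, n_predicted = 2)
#> [1] 0.01278772
#> attr(,"significant")
#> [1] TRUE
```

A command-line surface over the same functions ships in
`inst/cli/mvsvmd.R` (subcommands `simulate`, `decompose`, `denoise`,
`features`, `evaluate`, driven by a YAML config).

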