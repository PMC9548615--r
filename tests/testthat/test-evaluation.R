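test_that("alarms fire on saturated windows and respect the refractory period", {
  cfg <- alarm_config()
  times <- seq(30, 3600, by = 30)

  all_pre <- seizure_timeline(times, rep(1, length(times)), span = c(0, 3600))
  a <- raise_alarms(all_pre, cfg)
  expect_equal(a[1], 600)                 # first full window
  expect_true(all(diff(a) >= cfg$refractory_minutes * 60))

  all_int <- seizure_timeline(times, rep(0, length(times)), span = c(0, 3600))
  expect_length(raise_alarms(all_int, cfg), 0L)

  empty <- seizure_timeline(numeric(0), integer(0), onsets = 100,
                            span = c(0, 3600))
  expect_error(raise_alarms(empty, cfg), "empty label stream")
})

test_that("alarm times match the brute-force sliding-count oracle on random streams", {
  cfg <- alarm_config()
  for (seed in 1:100) {
    set.seed(seed)
    times <- seq(60, by = 60, length.out = 40)
    labels <- rbinom(40, 1, runif(1, 0.3, 0.8))
    tl <- seizure_timeline(times, labels, span = c(0, 2400))
    expect_identical(raise_alarms(tl, cfg),
                     oracle_alarms(times, labels, 0, 600, 0.6,
                                   cfg$refractory_minutes * 60))
  }
})

test_that("SPH/SOP scoring counts a prediction only inside the occurrence period", {
  cfg <- alarm_config()  # SPH 30 min, SOP 20 min
  tl <- seizure_timeline(seq(30, 7200, 30), rep(0, 240), onsets = 7000,
                         span = c(0, 7200))

  hit <- score_predictions(7000 - 40 * 60, tl, cfg)  # 40 min lead: inside SOP
  expect_equal(hit$n_predicted, 1L)
  expect_equal(hit$sensitivity, 1)

  miss <- score_predictions(7000 - 10 * 60, tl, cfg)  # 10 min lead: inside SPH
  expect_equal(miss$n_predicted, 0L)
  expect_equal(miss$n_false_alarms, 1L)
  expect_gt(miss$fpr, 0)

  # seeded random alarm/onset layouts vs a direct interval-membership check
  for (seed in 1:50) {
    set.seed(seed)
    onsets <- sort(runif(3, 5000, 80000))
    if (min(diff(onsets)) < 3600) next
    alarms <- sort(runif(6, 0, 80000))
    tl <- seizure_timeline(seq(30, 86400, 30), rep(0, 2880), onsets = onsets,
                           span = c(0, 86400))
    rep_ <- score_predictions(alarms, tl, cfg)
    m_ref <- sum(vapply(onsets, function(o)
      any(o >= alarms + 1800 & o <= alarms + 1800 + 1200), logical(1)))
    false_ref <- sum(vapply(alarms, function(a)
      !any(onsets >= a + 1800 & onsets <= a + 3000), logical(1)))
    expect_equal(rep_$n_predicted, m_ref)
    expect_equal(rep_$n_false_alarms, false_ref)
  }
})

test_that("the chance alarm probability follows the exponential law", {
  expect_equal(random_predictor_probability(0, 1/3), 0)
  expect_equal(random_predictor_probability(0.36, 1/3), 1 - exp(-0.12),
               tolerance = 1e-15)
  expect_gt(random_predictor_probability(1e4, 1/3), 1 - 1e-12)
})

test_that("the significance level matches exhaustive enumeration and is monotone", {
  # enumeration over all 2^M outcome patterns, M up to 12
  for (M in c(2L, 5L, 12L)) {
    P <- random_predictor_probability(0.3, 1/3)
    for (m in 0:M) {
      expect_equal(as.numeric(random_predictor_pvalue(0.3, 1/3, M, m)),
                   oracle_binom_tail(M, m, P), tolerance = 1e-12)
    }
  }
  expect_equal(as.numeric(random_predictor_pvalue(0.5, 1/3, 4, 0)), 1)

  # p nonincreasing in m; P nondecreasing in FPR and SOP
  ps <- vapply(0:5, function(m)
    as.numeric(random_predictor_pvalue(0.4, 1/3, 5, m)), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(!is.unsorted(vapply(seq(0, 2, 0.2), random_predictor_probability,
                                  numeric(1), sop_hours = 1/3)))
  expect_true(!is.unsorted(vapply(seq(0.1, 2, 0.2), function(s)
    random_predictor_probability(0.4, s), numeric(1))))
})

test_that("per-subject aggregation is the unweighted mean", {
  perf <- subject_performance()
  reports <- lapply(seq_len(nrow(perf)), function(i)
    list(sensitivity = perf$sensitivity[i], fpr = perf$fpr[i]))
  agg <- aggregate_performance(reports)
  expect_equal(round(agg$mean_sensitivity, 2), 0.86)
  expect_equal(round(agg$mean_fpr, 2), 0.18)

  single <- aggregate_performance(reports[1])
  expect_equal(single$mean_sensitivity, perf$sensitivity[1])
  expect_equal(single$mean_fpr, perf$fpr[1])
})

test_that("leave-one-seizure-out splits are balanced, seeded and cover all folds", {
  splits <- build_trial_splits(4, letters[1:10], n_trials = 10, seed = 5)
  expect_length(splits, 10L)
  for (s in splits) {
    expect_length(s$train_preictal, 3L)
    expect_length(s$train_interictal, 3L)
    expect_length(s$validation_interictal, 7L)
    expect_false(s$held_out_seizure %in% s$train_preictal)
    expect_length(intersect(s$train_interictal, s$validation_interictal), 0L)
  }
  expect_identical(build_trial_splits(4, letters[1:10], 10, seed = 5), splits)
  held <- vapply(splits, `[[`, numeric(1), "held_out_seizure")
  expect_setequal(held, 1:4)  # every seizure held out at least once

  expect_error(build_trial_splits(1, letters[1:10]), "at least 2")
  expect_error(build_trial_splits(5, letters[1:2]), "pool too small")
})
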