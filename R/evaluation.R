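# Alarm generation, SPH/SOP scoring, random-predictor significance and
# performance aggregation.

#' Seizure timeline
#'
#' Per-sample classifier labels with timestamps, seizure onset times and the
#' recording span, all in seconds from recording start (0-based, half-open
#' interval conventions throughout).
#'
#' @param sample_times Strictly increasing numeric vector of label
#'   timestamps (s).
#' @param labels Binary vector (1 = preictal, 0 = interictal), one per
#'   timestamp.
#' @param onsets Numeric vector of seizure onset times (s), inside the span.
#' @param span Length-2 numeric `c(start, end)` of the recording (s);
#'   defaults to `c(0, max(sample_times, onsets))`.
#' @return Object of class `seizure_timeline`.
#' @export
seizure_timeline <- function(sample_times, labels, onsets = numeric(0),
                             span = NULL) {
  if (length(sample_times) != length(labels))
    stop("sample_times and labels must have equal length")
  if (length(sample_times) && any(diff(sample_times) <= 0))
    stop("timestamps must be strictly increasing")
  labels <- as.integer(as.logical(labels))
  if (any(is.na(labels))) stop("labels must be binary")
  if (is.null(span))
    span <- c(0, max(c(sample_times, onsets, 0)))
  if (length(span) != 2L || span[1] >= span[2]) stop("invalid span")
  if (length(onsets) && (any(onsets < span[1]) || any(onsets > span[2])))
    stop("onsets must lie within the recording span")
  structure(list(sample_times = as.numeric(sample_times), labels = labels,
                 onsets = sort(as.numeric(onsets)), span = as.numeric(span)),
            class = "seizure_timeline")
}

#' Alarm configuration
#'
#' Sliding prediction window, alarm threshold, and the SPH/SOP scoring
#' intervals. An alarm is raised when strictly more than
#' `positive_fraction` of the samples in the trailing `window_minutes` are
#' labeled preictal; for a correct prediction the seizure must not occur
#' during the SPH (intervention horizon) and must occur within the SOP
#' following it. After an alarm no new alarm is raised for
#' `refractory_minutes` (defaults to the SOP).
#'
#' @param window_minutes Length of the sliding prediction window.
#' @param positive_fraction Strict preictal-fraction threshold in (0, 1).
#' @param sph_minutes Seizure prediction horizon.
#' @param sop_minutes Seizure occurrence period.
#' @param refractory_minutes Alarm dead time; `NULL` means `sop_minutes`.
#' @return Object of class `alarm_config`.
#' @export
alarm_config <- function(window_minutes = 10, positive_fraction = 0.6,
                         sph_minutes = 30, sop_minutes = 20,
                         refractory_minutes = NULL) {
  if (is.null(refractory_minutes)) refractory_minutes <- sop_minutes
  if (any(c(window_minutes, sph_minutes, sop_minutes, refractory_minutes) <= 0))
    stop("all durations must be > 0")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be in (0, 1)")
  structure(list(window_minutes = window_minutes,
                 positive_fraction = positive_fraction,
                 sph_minutes = sph_minutes, sop_minutes = sop_minutes,
                 refractory_minutes = refractory_minutes),
            class = "alarm_config")
}

#' Raise alarms from a labeled timeline
#'
#' Slides the prediction window one sample step at a time; at each sample
#' time `t` whose trailing window `(t - window, t]` is fully inside the
#' recording, an alarm fires when the fraction of preictal-labeled samples
#' in the window strictly exceeds the threshold, after which alarms are
#' suppressed for the refractory period.
#'
#' @param timeline A [seizure_timeline()] with at least one sample.
#' @param cfg An [alarm_config()].
#' @return Numeric vector of alarm times (s), possibly empty.
#' @export
raise_alarms <- function(timeline, cfg = alarm_config()) {
  stopifnot(inherits(timeline, "seizure_timeline"), inherits(cfg, "alarm_config"))
  t <- timeline$sample_times
  if (!length(t)) stop("empty label stream: no samples to evaluate")
  win <- cfg$window_minutes * 60
  refr <- cfg$refractory_minutes * 60
  alarms <- numeric(0)
  last <- -Inf
  for (j in seq_along(t)) {
    if (t[j] < timeline$span[1] + win) next
    if (t[j] < last + refr) next
    idx <- t > t[j] - win & t <= t[j]
    if (mean(timeline$labels[idx]) > cfg$positive_fraction) {
      alarms <- c(alarms, t[j])
      last <- t[j]
    }
  }
  alarms
}

#' Score alarms against seizure onsets
#'
#' A seizure is counted as predicted iff some alarm at time `t` satisfies
#' `onset` in `[t + SPH, t + SPH + SOP]`; alarms matching no onset are
#' false alarms. Sensitivity is `m/M`; the false prediction rate is false
#' alarms per hour of evaluated interictal recording, where the SPH+SOP
#' stretch before each onset is excluded from the denominator.
#'
#' @param alarms Numeric vector of alarm times (s).
#' @param timeline A [seizure_timeline()].
#' @param cfg An [alarm_config()].
#' @return Object of class `performance_report`: `sensitivity`, `fpr`
#'   (per hour), `n_seizures`, `n_predicted`, `n_false_alarms`,
#'   `interictal_hours`, `p_value` (NA; see [random_predictor_pvalue()]).
#' @export
score_predictions <- function(alarms, timeline, cfg = alarm_config()) {
  stopifnot(inherits(timeline, "seizure_timeline"), inherits(cfg, "alarm_config"))
  sph <- cfg$sph_minutes * 60
  sop <- cfg$sop_minutes * 60
  onsets <- timeline$onsets
  M <- length(onsets)
  predicted <- vapply(onsets, function(o)
    any(alarms >= o - sph - sop & alarms <= o - sph), logical(1))
  true_alarm <- vapply(alarms, function(a)
    any(onsets >= a + sph & onsets <= a + sph + sop), logical(1))
  n_false <- sum(!true_alarm)
  # evaluated interictal time: span minus the pre-onset SPH+SOP stretches
  span <- timeline$span
  excluded <- 0
  for (o in onsets) {
    lo <- max(span[1], o - sph - sop)
    hi <- min(span[2], o)
    excluded <- excluded + max(0, hi - lo)
  }
  hours <- (span[2] - span[1] - excluded) / 3600
  if (hours <= 0) stop("zero evaluated interictal hours")
  structure(list(sensitivity = if (M) sum(predicted) / M else NA_real_,
                 fpr = n_false / hours,
                 n_seizures = M, n_predicted = sum(predicted),
                 n_false_alarms = n_false, interictal_hours = hours,
                 p_value = NA_real_),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> sensitivity %s (m=%d of M=%d), FPR %.3f/h, p=%s\n",
              format(x$sensitivity, digits = 3), x$n_predicted, x$n_seizures,
              x$fpr, format(x$p_value, digits = 3)))
  invisible(x)
}

#' Chance probability of an alarm in one occurrence period
#'
#' The random-predictor approximation `P = 1 - exp(-FPR * SOP)` for the
#' probability that an unspecific alarm process with the given false
#' prediction rate raises at least one alarm during one SOP.
#'
#' @param fpr False prediction rate per hour (>= 0).
#' @param sop_hours Seizure occurrence period in hours (> 0).
#' @return Probability in \[0, 1).
#' @export
random_predictor_probability <- function(fpr, sop_hours) {
  if (fpr < 0) stop("fpr must be >= 0")
  if (sop_hours <= 0) stop("sop_hours must be > 0")
  1 - exp(-fpr * sop_hours)
}

#' Random-predictor significance of a prediction result
#'
#' Upper-tail binomial probability of predicting at least `m` of `M`
#' independent seizures by chance, with per-seizure success probability
#' from [random_predictor_probability()]. Values below 0.05 indicate
#' performance significantly better than chance.
#'
#' @param fpr False prediction rate per hour.
#' @param sop_hours Seizure occurrence period in hours.
#' @param n_seizures Total number of seizures `M`.
#' @param n_predicted Number of correctly predicted seizures `m`
#'   (`0 <= m <= M`).
#' @return p-value in \[0, 1\], with attribute `significant` (vs 0.05).
#' @examples
#' random_predictor_pvalue(0.36, 1/3, 2, 2)
#' @export
random_predictor_pvalue <- function(fpr, sop_hours, n_seizures, n_predicted) {
  M <- as.integer(n_seizures); m <- as.integer(n_predicted)
  if (m < 0 || m > M) stop("need 0 <= n_predicted <= n_seizures")
  P <- random_predictor_probability(fpr, sop_hours)
  p <- if (m == 0) 1 else stats::pbinom(m - 1L, M, P, lower.tail = FALSE)
  structure(p, significant = p < 0.05)
}

#' Average per-subject performance reports
#'
#' Unweighted arithmetic means of sensitivity and FPR across subjects.
#'
#' @param reports List of `performance_report` objects (or any lists with
#'   `sensitivity` and `fpr` fields).
#' @return List with `mean_sensitivity`, `mean_fpr`, `n_subjects`.
#' @export
aggregate_performance <- function(reports) {
  if (!length(reports)) stop("need at least one report")
  sens <- vapply(reports, function(r) as.numeric(r$sensitivity), numeric(1))
  fpr <- vapply(reports, function(r) as.numeric(r$fpr), numeric(1))
  list(mean_sensitivity = mean(sens), mean_fpr = mean(fpr),
       n_subjects = length(reports))
}

#' Leave-one-seizure-out balanced trial splits
#'
#' Builds `n_trials` train/validation splits: each trial holds out one
#' seizure (cycling through the M folds), trains on the remaining `M - 1`
#' preictal sequences plus an equal number of interictal sequences sampled
#' without replacement from the pool, and validates on the held-out seizure
#' and all remaining interictal sequences.
#'
#' @param n_seizures Number of seizures `M` (>= 2).
#' @param interictal_pool Vector of interictal sequence identifiers
#'   (length >= `M - 1`).
#' @param n_trials Number of trials (default 10).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List of `n_trials` lists with elements `held_out_seizure`,
#'   `train_preictal`, `train_interictal`, `validation_interictal`.
#' @export
build_trial_splits <- function(n_seizures, interictal_pool, n_trials = 10L,
                               seed = 1L) {
  M <- as.integer(n_seizures)
  if (M < 2L) stop("need at least 2 seizures for leave-one-out splits")
  if (length(interictal_pool) < M - 1L)
    stop("interictal pool too small: need at least M - 1 sequences")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  lapply(seq_len(n_trials), function(trial) {
    held <- ((trial - 1L) %% M) + 1L
    train_int <- sample(interictal_pool, M - 1L, replace = FALSE)
    list(held_out_seizure = held,
         train_preictal = setdiff(seq_len(M), held),
         train_interictal = train_int,
         validation_interictal = setdiff(interictal_pool, train_int))
  })
}
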