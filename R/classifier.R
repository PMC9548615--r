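# Classifier-facing representation: seeded Hadamard data embedding plus
# position embedding, a pluggable fit/predict contract with a deterministic
# regularized linear-discriminant baseline, and majority-vote ensembling.

#' Seeded embedding parameters
#'
#' Fixed (seeded) weight and position-embedding matrices matching the shape
#' of a feature tensor. The data embedding is the Hadamard product of the
#' tensor with `W`; the input representation adds a position embedding with
#' one column per time step. Entries are drawn from a normal distribution.
#'
#' @param n_features Number of tensor rows (`n_channels * n_bands`).
#' @param n_steps Number of tensor columns (time steps).
#' @param mean,sd Normal-distribution parameters for initialization
#'   (defaults 0 and 0.02).
#' @param seed Integer seed making the spec reproducible.
#' @return Object of class `embedding_spec` with matrices `W` and `E_p`.
#' @export
embedding_spec <- function(n_features, n_steps, mean = 0, sd = 0.02, seed = 1L) {
  stopifnot(n_features >= 1, n_steps >= 1, sd >= 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(n_features * n_steps, mean, sd), n_features, n_steps)
  E_p <- matrix(stats::rnorm(n_features * n_steps, mean, sd), n_features, n_steps)
  structure(list(W = W, E_p = E_p, n_features = as.integer(n_features),
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "embedding_spec")
}

#' Embed a feature tensor
#'
#' `E = X (Hadamard) W + E_p`, elementwise; deterministic for a fixed spec.
#'
#' @param X A `feature_tensor` or a plain numeric matrix.
#' @param spec An [embedding_spec()] of matching shape.
#' @return Numeric matrix `E` of the same shape.
#' @export
data_embedding <- function(X, spec) {
  stopifnot(inherits(spec, "embedding_spec"))
  M <- if (inherits(X, "feature_tensor")) X$X else X
  if (!is.matrix(M)) stop("X must be a feature tensor or matrix")
  if (nrow(M) != nrow(spec$W) || ncol(M) != ncol(spec$W))
    stop("shape mismatch between tensor and embedding spec")
  M * spec$W + spec$E_p
}

#' Deterministic linear baseline classifier
#'
#' A regularized linear discriminant on flattened (optionally embedded)
#' feature tensors, solved in the dual so the per-sample dimension stays at
#' the number of training sequences. It fulfils the classifier contract —
#' `fit_classifier()` then `predict()` returning a preictal probability in
#' \[0, 1\] — that a stronger sequence model (e.g. a fine-tuned transformer)
#' would implement in a full deployment; the baseline keeps the pipeline
#' end-to-end testable and fully reproducible.
#'
#' @param lambda Ridge penalty (> 0).
#' @param spec Optional [embedding_spec()] applied to every tensor before
#'   flattening.
#' @return Unfitted classifier object of class `linear_baseline`.
#' @export
linear_baseline <- function(lambda = 1, spec = NULL) {
  stopifnot(lambda > 0)
  structure(list(lambda = lambda, spec = spec, fitted = FALSE),
            class = c("linear_baseline", "seizure_classifier"))
}

.flatten_tensor <- function(tensor, spec) {
  M <- if (is.null(spec)) {
    if (inherits(tensor, "feature_tensor")) tensor$X else tensor
  } else data_embedding(tensor, spec)
  as.numeric(M)
}

#' Fit a classifier on a labeled dataset
#'
#' @param object A classifier implementing the contract.
#' @param dataset A `feature_dataset` from [assemble_dataset()] with exactly
#'   two classes; the alphabetically later level (e.g. `"preictal"` vs
#'   `"interictal"`) is taken as the positive class unless a level named
#'   `"preictal"` exists.
#' @param ... Passed to methods.
#' @return The fitted classifier.
#' @export
fit_classifier <- function(object, dataset, ...) UseMethod("fit_classifier")

#' @export
fit_classifier.linear_baseline <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "feature_dataset"))
  if (nlevels(dataset$labels) != 2L) stop("baseline needs exactly two classes")
  lev <- levels(dataset$labels)
  positive <- if ("preictal" %in% lev) "preictal" else lev[2]
  Z <- t(vapply(dataset$tensors, .flatten_tensor, spec = object$spec,
                numeric(length(.flatten_tensor(dataset$tensors[[1]], object$spec)))))
  y <- ifelse(dataset$labels == positive, 1, -1)
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2L, mu)
  n <- nrow(Zc)
  # dual ridge: w = Zc' (Zc Zc' + lambda I)^{-1} y
  a <- solve(Zc %*% t(Zc) + object$lambda * diag(n), y - mean(y))
  object$w <- drop(t(Zc) %*% a)
  object$mu <- mu
  object$b <- mean(y)
  object$positive <- positive
  object$levels <- lev
  object$fitted <- TRUE
  object
}

#' @export
predict.linear_baseline <- function(object, newdata, ...) {
  if (!isTRUE(object$fitted)) stop("classifier has not been fitted yet")
  tensors <- if (inherits(newdata, "feature_dataset")) newdata$tensors
             else if (inherits(newdata, "feature_tensor") || is.matrix(newdata)) list(newdata)
             else newdata
  scores <- vapply(tensors, function(t)
    sum((.flatten_tensor(t, object$spec) - object$mu) * object$w) + object$b,
    numeric(1))
  stats::plogis(scores)
}

#' Majority-vote trial ensemble
#'
#' Configuration for aggregating the binary decisions of independently
#' trained trials: with the defaults, a sequence is declared preictal only
#' when strictly more than 6 of the 10 trials vote preictal.
#'
#' @param n_trials Number of trials/models (default 10).
#' @param vote_threshold Strict threshold: positive iff votes > threshold
#'   (default 6).
#' @param seeds Optional integer vector of per-trial seeds (length
#'   `n_trials`).
#' @return Object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(n_trials = 10L, vote_threshold = 6L, seeds = NULL) {
  if (!(vote_threshold > 0 && vote_threshold < n_trials))
    stop("need 0 < vote_threshold < n_trials")
  if (!is.null(seeds) && length(seeds) != n_trials)
    stop("seeds must have one entry per trial")
  structure(list(n_trials = as.integer(n_trials),
                 vote_threshold = as.integer(vote_threshold),
                 seeds = seeds),
            class = "trial_ensemble")
}

#' Aggregate per-trial votes into one label
#'
#' @param votes Binary vector (0/1 or logical), one vote per trial.
#' @param ensemble A [trial_ensemble()].
#' @return `1L` (preictal) iff the positive votes strictly exceed the
#'   threshold, else `0L`.
#' @export
ensemble_vote <- function(votes, ensemble = trial_ensemble()) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  if (length(votes) != ensemble$n_trials)
    stop("vote vector length must equal n_trials")
  v <- as.integer(as.logical(votes))
  if (any(is.na(v))) stop("votes must be binary")
  as.integer(sum(v) > ensemble$vote_threshold)
}
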