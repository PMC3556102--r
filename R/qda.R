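#' Quadratic discriminant model
#'
#' Container for a two-class QDA rule: per-class means, covariance matrices,
#' their Cholesky factors and log-determinants, and class priors. Built
#' directly (e.g. to plug in true population parameters) or by [train_qda()].
#'
#' @param means 2 x p matrix of class means (row 1 = class 1).
#' @param covariances List of two p x p symmetric positive definite matrices.
#' @param priors Two probabilities summing to 1 (default equal).
#' @return A `qda_model`.
#' @export
qda_model <- function(means, covariances, priors = c(0.5, 0.5)) {
  means <- as.matrix(means)
  if (nrow(means) != 2L) stop_argument("`means` must have two rows")
  if (abs(sum(priors) - 1) > 1e-12 || any(priors <= 0))
    stop_argument("`priors` must be positive and sum to 1")
  chols <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R) || any(!is.finite(diag(R))) || any(diag(R) <= 0))
      stop_degenerate("class covariance is not positive definite")
    R
  })
  structure(list(means = means, covariances = covariances,
                 chol = chols,
                 log_determinants = vapply(chols, function(R)
                   2 * sum(log(diag(R))), numeric(1)),
                 priors = priors),
            class = "qda_model")
}

#' Train QDA on a labeled sample
#'
#' Class means are per-class sample means; covariances are per-class sample
#' covariances, by default with the unbiased 1/(m-1) divisor. A singular or
#' non-positive-definite class covariance raises a degenerate-training
#' condition (class `cvbias_degenerate_error`) distinct from argument errors,
#' so resampling callers can respond by redrawing; no ridge regularization is
#' applied.
#'
#' @param sample A `labeled_sample` (or anything with `features`/`labels`).
#' @param priors Class priors, fixed at (0.5, 0.5) throughout the study.
#' @param unbiased Use the 1/(m-1) covariance divisor (default) or 1/m.
#' @return A [qda_model()].
#' @export
train_qda <- function(sample, priors = c(0.5, 0.5), unbiased = TRUE) {
  X <- as.matrix(sample$features)
  y <- sample$labels
  if (!all(c(1L, 2L) %in% y))
    stop_argument("both classes must be present to train QDA")
  fit_class <- function(cls) {
    Xc <- X[y == cls, , drop = FALSE]
    m <- nrow(Xc)
    if (m < 2L) stop_degenerate("fewer than two observations in a class")
    mu <- colMeans(Xc)
    ctr <- sweep(Xc, 2, mu)
    S <- crossprod(ctr) / (if (unbiased) m - 1 else m)
    list(mean = mu, sigma = S)
  }
  f1 <- fit_class(1L); f2 <- fit_class(2L)
  qda_model(means = rbind(f1$mean, f2$mean),
            covariances = list(f1$sigma, f2$sigma),
            priors = priors)
}

#' Classify points with a QDA model
#'
#' Assigns each point to the class maximizing the quadratic discriminant
#' \eqn{\delta_c(x) = -\tfrac12 \log|\Sigma_c| - \tfrac12 (x-\mu_c)'
#' \Sigma_c^{-1} (x-\mu_c) + \log \pi_c}. Exact ties go to class 1
#' (deterministic; a measure-zero event for continuous features).
#'
#' @param model A [qda_model()].
#' @param points m x p matrix (or length-p vector for a single point).
#' @return Integer vector of predicted labels in \{1, 2\}.
#' @export
predict_qda <- function(model, points) {
  stopifnot(inherits(model, "qda_model"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != ncol(model$means))
    stop_argument("`points` dimension does not match the model")
  score <- function(c) {
    ctr <- sweep(points, 2, model$means[c, ])
    z <- ctr %*% backsolve(model$chol[[c]], diag(ncol(points)))
    -0.5 * model$log_determinants[c] - 0.5 * rowSums(z * z) +
      log(model$priors[c])
  }
  ifelse(score(1L) >= score(2L), 1L, 2L)
}

#' Misclassification rate
#'
#' Proportion of points whose predicted label differs from the true label:
#' an error count divided by a point count.
#'
#' @param model A [qda_model()].
#' @param points m x p matrix.
#' @param labels True labels, aligned with `points`.
#' @return Proportion in \[0, 1\].
#' @export
misclassification_rate <- function(model, points, labels) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (nrow(points) == 0L || length(labels) == 0L)
    stop_argument("empty input")
  if (nrow(points) != length(labels))
    stop_argument("`points` and `labels` lengths disagree")
  sum(predict_qda(model, points) != labels) / length(labels)
}

#' Distinct observations per class
#'
#' Counts unique feature rows within each class (exact row equality), the
#' quantity constrained in bootstrap resamples to keep QDA trainable.
#'
#' @param sample A `labeled_sample`.
#' @return Integer vector `c(class1, class2)`.
#' @export
count_distinct_per_class <- function(sample) {
  X <- as.matrix(sample$features)
  y <- sample$labels
  vapply(1:2, function(cls) {
    nrow(unique(X[y == cls, , drop = FALSE]))
  }, integer(1))
}
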