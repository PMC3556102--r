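#' Two-class Gaussian population configuration
#'
#' Defines the data-generating process for the simulation study: class 1 is
#' \eqn{N(0, \Sigma_1)} and class 2 is \eqn{N(\mu_2, \Sigma_2)} with
#' \eqn{\mu_2 = (\Delta/\sqrt{p}) \cdot 1_p}, so the Euclidean distance
#' between the class means equals \eqn{\Delta} for every dimension \eqn{p}.
#' The `equal` covariance case has \eqn{\Sigma_1 = \Sigma_2 = I_p}; the
#' `unequal` case has \eqn{\Sigma_2 = 2 I_p}.
#'
#' @param p Feature dimension (integer, >= 1).
#' @param delta Separation \eqn{\Delta} between class means (>= 0; 0 gives
#'   two indistinguishable classes, useful for degenerate checks).
#' @param covariance_case `"equal"` or `"unequal"`.
#' @param per_class_size Number of super-population members per class
#'   (default 5000, i.e. a 10,000-point super-population).
#' @return A `population_config` object.
#' @export
population_config <- function(p, delta, covariance_case = c("equal", "unequal"),
                              per_class_size = 5000L) {
  covariance_case <- match.arg(covariance_case)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop_argument("`p` must be a positive integer")
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop_argument("`delta` must be a nonnegative number")
  if (!is.numeric(per_class_size) || per_class_size < 1)
    stop_argument("`per_class_size` must be >= 1")
  structure(list(p = as.integer(p), delta = as.numeric(delta),
                 covariance_case = covariance_case,
                 per_class_size = as.integer(per_class_size)),
            class = "population_config")
}

#' Class mean and covariance implied by a configuration
#'
#' @param config A [population_config()].
#' @param class_id 1 or 2.
#' @return List with `mean` (length-p vector) and `sigma` (p x p matrix).
#' @export
class_parameters <- function(config, class_id) {
  p <- config$p
  if (class_id == 1L) {
    list(mean = rep(0, p), sigma = diag(p))
  } else {
    scale <- if (config$covariance_case == "unequal") 2 else 1
    list(mean = rep(config$delta / sqrt(p), p), sigma = scale * diag(p))
  }
}

#' Draw the super-population
#'
#' Draws `per_class_size` points from each class; the resulting finite
#' population stands in for the infinite population: study samples are drawn
#' from it and the true conditional error of a trained classifier is measured
#' on its unsampled remainder.
#'
#' @param config A [population_config()].
#' @param seed Integer seed; the same (config, seed) pair reproduces the
#'   super-population bit-for-bit.
#' @return A `super_population`: list with `features` (2M x p matrix),
#'   `labels` (1/2), `config`, `seed`.
#' @export
draw_super_population <- function(config, seed) {
  stopifnot(inherits(config, "population_config"))
  M <- config$per_class_size
  p <- config$p
  set.seed(seed)
  par1 <- class_parameters(config, 1L)
  par2 <- class_parameters(config, 2L)
  # independent coordinates: scale/shift of standard normals per class
  x1 <- matrix(rnorm(M * p), M, p)
  x2 <- matrix(rnorm(M * p), M, p)
  x1 <- sweep(x1 * sqrt(par1$sigma[1, 1]), 2, par1$mean, `+`)
  x2 <- sweep(x2 * sqrt(par2$sigma[1, 1]), 2, par2$mean, `+`)
  structure(list(features = rbind(x1, x2),
                 labels = rep(1:2, each = M),
                 config = config, seed = as.integer(seed)),
            class = "super_population")
}

#' Stratified without-replacement sample from a super-population
#'
#' Draws n/2 rows from each class without replacement and records the source
#' row indices, so the 10000 - n holdout used for the true conditional error
#' is recoverable.
#'
#' @param sp A [draw_super_population()] result.
#' @param n Even sample size with n/2 <= per-class size.
#' @param seed Optional integer seed.
#' @return A `labeled_sample`: list with `features` (n x p), `labels`,
#'   `source_indices`, `n`.
#' @export
draw_stratified_sample <- function(sp, n, seed = NULL) {
  stopifnot(inherits(sp, "super_population"))
  M <- sp$config$per_class_size
  if (n %% 2 != 0) stop_argument("`n` must be even (n/2 per class)")
  if (n / 2 > M) stop_argument("`n`/2 exceeds the per-class population size")
  with_seed(seed, {
    i1 <- sample.int(M, n / 2)
    i2 <- M + sample.int(M, n / 2)
  })
  idx <- c(i1, i2)
  structure(list(features = sp$features[idx, , drop = FALSE],
                 labels = sp$labels[idx],
                 source_indices = idx, n = as.integer(n)),
            class = "labeled_sample")
}

#' Construct a labeled sample from raw matrices
#'
#' @param features Numeric matrix (n x p).
#' @param labels Integer vector of class indicators in \{1, 2\}.
#' @param source_indices Optional indices into an originating population.
#' @return A `labeled_sample`.
#' @export
labeled_sample <- function(features, labels, source_indices = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop_argument("`features` and `labels` lengths disagree")
  if (!all(labels %in% c(1L, 2L)))
    stop_argument("`labels` must be coded 1/2")
  structure(list(features = features, labels = as.integer(labels),
                 source_indices = source_indices,
                 n = nrow(features)),
            class = "labeled_sample")
}

#' Bayes error of the optimal rule for a configuration
#'
#' For equal covariances the optimal-rule error has the closed form
#' \eqn{\Phi(-\Delta/2)} (it depends only on the Mahalanobis distance
#' \eqn{\Delta}). For the unequal case no closed form is used; a seeded
#' Monte Carlo estimate over at least 10^6 points evaluates the optimal
#' quadratic rule built from the true parameters.
#'
#' @param config A [population_config()].
#' @param mc_points Points per class for the unequal-covariance Monte Carlo
#'   estimate (total >= 10^6 by default).
#' @param seed Seed for the Monte Carlo branch.
#' @return Error probability in \[0, 0.5\].
#' @export
bayes_error <- function(config, mc_points = 5e5, seed = 20251L) {
  stopifnot(inherits(config, "population_config"))
  if (config$covariance_case == "equal")
    return(pnorm(-config$delta / 2))
  par1 <- class_parameters(config, 1L)
  par2 <- class_parameters(config, 2L)
  model <- qda_model(means = rbind(par1$mean, par2$mean),
                     covariances = list(par1$sigma, par2$sigma),
                     priors = c(0.5, 0.5))
  set.seed(seed)
  p <- config$p
  x1 <- matrix(rnorm(mc_points * p), ncol = p)
  x2 <- sweep(matrix(rnorm(mc_points * p), ncol = p) * sqrt(2), 2,
              par2$mean, `+`)
  err1 <- mean(predict_qda(model, x1) != 1L)
  err2 <- mean(predict_qda(model, x2) != 2L)
  (err1 + err2) / 2
}
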