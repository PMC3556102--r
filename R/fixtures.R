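# Hand-sized fixtures and straight-line oracles used by the test surface.
# The oracles deliberately share no helpers with the main implementation:
# they refit QDA by direct density evaluation so scheme code can be checked
# against naive enumeration.

#' Separable two-cluster fixture sample
#'
#' Two 1-SD Gaussian clusters `gap` standard deviations apart; with a large
#' gap every CV scheme must estimate error 0.
#'
#' @param p Dimension.
#' @param n Even sample size (n/2 per class).
#' @param gap Separation in SD units.
#' @param seed Seed for reproducibility.
#' @return A `labeled_sample`.
#' @export
make_separable_sample <- function(p, n, gap, seed = 1L) {
  if (n %% 2 != 0) stop_argument("`n` must be even")
  if (gap < 0) stop_argument("`gap` must be nonnegative")
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
             matrix(rnorm(n / 2 * p) + gap, n / 2, p))
  labeled_sample(X, rep(1:2, each = n / 2))
}

# Straight-line QDA prediction by direct Gaussian log-density evaluation.
oracle_qda_predict <- function(X_train, y_train, X_test, priors = c(0.5, 0.5),
                               unbiased = TRUE) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  stats_for <- function(cls) {
    Z <- X_train[y_train == cls, , drop = FALSE]
    mu <- colMeans(Z)
    cen <- sweep(Z, 2, mu)
    S <- t(cen) %*% cen / (if (unbiased) nrow(Z) - 1 else nrow(Z))
    list(mu = mu, S = S)
  }
  s1 <- stats_for(1L); s2 <- stats_for(2L)
  logdens <- function(x, st) {
    d <- x - st$mu
    -0.5 * determinant(st$S, logarithm = TRUE)$modulus[1] -
      0.5 * as.numeric(t(d) %*% solve(st$S) %*% d)
  }
  out <- integer(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    g1 <- logdens(X_test[i, ], s1) + log(priors[1])
    g2 <- logdens(X_test[i, ], s2) + log(priors[2])
    out[i] <- if (g1 >= g2) 1L else 2L
  }
  out
}

#' Brute-force cross-validation oracle
#'
#' Computes a CV estimate from an explicit plan by naive enumeration: for
#' every fold, refit QDA on the complement via direct moment/density
#' computation and count test misclassifications. Supply `indices` to
#' replay a recorded bootstrap resample (the plan then partitions the
#' resampled rows).
#'
#' @param sample A `labeled_sample`.
#' @param fold_assign Fold id per row (of the resample when `indices`
#'   given).
#' @param indices Optional recorded with-replacement row indices.
#' @param priors,unbiased QDA settings.
#' @return Misclassified fraction.
#' @export
brute_force_cv <- function(sample, fold_assign, indices = NULL,
                           priors = c(0.5, 0.5), unbiased = TRUE) {
  X <- as.matrix(sample$features)
  y <- sample$labels
  if (!is.null(indices)) {
    X <- X[indices, , drop = FALSE]
    y <- y[indices]
  }
  n <- nrow(X)
  if (length(fold_assign) != n) stop_argument("fold plan length mismatch")
  wrong <- 0L
  for (j in unique(fold_assign)) {
    test <- which(fold_assign == j)
    pred <- oracle_qda_predict(X[-test, , drop = FALSE], y[-test],
                               X[test, , drop = FALSE], priors, unbiased)
    wrong <- wrong + sum(pred != y[test])
  }
  wrong / n
}

#' Write a labeled sample as delimited text
#'
#' CSV snapshot with a `class` column followed by the p feature columns.
#'
#' @param sample A `labeled_sample`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  df <- data.frame(class = sample$labels, as.data.frame(sample$features))
  names(df)[-1] <- paste0("x", seq_len(ncol(sample$features)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled sample written by [write_sample_csv()]
#'
#' @param path CSV path with a `class` column and numeric feature columns.
#' @return A `labeled_sample`.
#' @export
read_sample_csv <- function(path) {
  df <- utils::read.csv(path)
  labeled_sample(as.matrix(df[, -1, drop = FALSE]), df$class)
}
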