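#' Per-run MSE decomposition
#'
#' For one simulation run with R repetition estimates \eqn{\hat e_{ri}} of a
#' true conditional error \eqn{e_i}:
#' \deqn{MSE_i = \frac1R \sum_r (\hat e_{ri} - e_i)^2, \quad
#'       VAR_i = \frac1R \sum_r (\hat e_{ri} - \bar e_{Ri})^2, \quad
#'       BIAS_i = \bar e_{Ri} - e_i,}
#' with the algebraic identity \eqn{MSE_i = VAR_i + BIAS_i^2}. Both moments
#' use the 1/R divisor, so VAR is exactly 0 when R = 1.
#'
#' @param estimates Numeric vector of R repetition estimates in \[0, 1\].
#' @param e_i True conditional error of the run.
#' @return List with `mse`, `var`, `bias`, `mean_estimate`.
#' @export
per_run_decomposition <- function(estimates, e_i) {
  if (length(estimates) == 0L) stop_argument("`estimates` must be nonempty")
  if (e_i < 0 || e_i > 1) stop_argument("`e_i` must be in [0, 1]")
  R <- length(estimates)
  m <- mean(estimates)
  list(mse = sum((estimates - e_i)^2) / R,
       var = sum((estimates - m)^2) / R,
       bias = m - e_i,
       mean_estimate = m)
}

#' Per-run record
#'
#' Bundles one simulation run's truth, estimates, and decomposition.
#'
#' @param i Run index.
#' @param e_i True conditional error.
#' @param estimates Repetition estimates.
#' @return A `run_record`.
#' @export
run_record <- function(i, e_i, estimates) {
  d <- per_run_decomposition(estimates, e_i)
  structure(list(i = i, e_i = e_i, estimates = estimates,
                 mean_estimate = d$mean_estimate,
                 mse = d$mse, var = d$var, bias = d$bias),
            class = "run_record")
}

records_field <- function(records, field)
  unname(vapply(records, `[[`, numeric(1), field))

#' Aggregate run records into one summary row
#'
#' Over N runs the averages use the 1/N divisor:
#' \eqn{\overline{MSE} = \frac1N \sum_i MSE_i},
#' \eqn{\overline{VAR} = \frac1N \sum_i VAR_i},
#' \eqn{\overline{BIAS} = \frac1N \sum_i BIAS_i}, and the mean squared bias
#' \eqn{MSB = \frac1N \sum_i BIAS_i^2}, giving
#' \eqn{\overline{MSE} = \overline{VAR} + MSB}. The dispersion columns
#' SD(MSE), SD(VAR), SD(BIAS) are sample standard deviations over runs
#' (1/(N-1) divisor), so \eqn{MSB = \frac{N-1}{N} SD(BIAS)^2 +
#' \overline{BIAS}^2}. `e_bar` is the mean of the N true conditional errors
#' and `e_bar_N` the mean of the N run-mean estimates.
#'
#' @param records List of [run_record()]s with a common repetition count R.
#' @param method,n,delta,p,cov_case,B Labels for the output row.
#' @return One-row `data.frame` with columns `method, n, delta, p, cov_case,
#'   e_bar, e_bar_N, mse_bar, sd_mse, var_bar, sd_var, msb, bias_bar,
#'   sd_bias, N_sims, B`.
#' @export
aggregate_records <- function(records, method = NA_character_, n = NA_integer_,
                              delta = NA_real_, p = NA_integer_,
                              cov_case = NA_character_, B = NA_integer_) {
  N <- length(records)
  if (N < 2L) stop_argument("need at least two run records")
  Rs <- vapply(records, function(r) length(r$estimates), integer(1))
  if (length(unique(Rs)) != 1L)
    stop_argument("records have inconsistent repetition counts R")
  e <- records_field(records, "e_i")
  ebarRi <- records_field(records, "mean_estimate")
  mse <- records_field(records, "mse")
  vr <- records_field(records, "var")
  bias <- records_field(records, "bias")
  data.frame(method = method, n = n, delta = delta, p = p,
             cov_case = cov_case,
             e_bar = mean(e), e_bar_N = mean(ebarRi),
             mse_bar = mean(mse), sd_mse = sd(mse),
             var_bar = mean(vr), sd_var = sd(vr),
             msb = mean(bias^2),
             bias_bar = mean(bias), sd_bias = sd(bias),
             N_sims = N, B = B,
             stringsAsFactors = FALSE)
}

#' Split the mean squared bias into spread and mean components
#'
#' \eqn{MSB = \frac1N \sum_i (BIAS_i - \overline{BIAS})^2 +
#' \overline{BIAS}^2}: the first term is the (1/N-divisor) spread of the
#' per-run biases, the second the squared average bias.
#'
#' @param records List of [run_record()]s.
#' @return Named vector `c(sd_component, mean_component)`; the two sum to
#'   the MSB.
#' @export
msb_decomposition <- function(records) {
  if (length(records) < 2L) stop_argument("need at least two run records")
  bias <- records_field(records, "bias")
  N <- length(bias)
  c(sd_component = sum((bias - mean(bias))^2) / N,
    mean_component = mean(bias)^2)
}

#' Relative bias of an aggregate row
#'
#' \eqn{\overline{BIAS}/\bar e}, equivalently \eqn{(\bar e_N - \bar e)/\bar
#' e}; the sign is preserved.
#'
#' @param row One-row aggregate as returned by [aggregate_records()].
#' @return Signed relative bias.
#' @export
relative_bias <- function(row) {
  if (row$e_bar <= 0) stop_argument("`e_bar` must be positive")
  row$bias_bar / row$e_bar
}

#' Bias-to-spread ratio with acceptability threshold
#'
#' \eqn{|\overline{BIAS}| / SD(BIAS)}, compared against a rule-of-thumb
#' threshold (0.25 by default) for acceptable relative bias.
#'
#' @param row One-row aggregate as returned by [aggregate_records()].
#' @param threshold Acceptability cutoff (default 0.25).
#' @return List with `ratio` and logical `exceeds`.
#' @export
bias_sd_ratio <- function(row, threshold = 0.25) {
  if (!is.finite(row$sd_bias) || row$sd_bias <= 0)
    stop_argument("`sd_bias` must be positive")
  ratio <- abs(row$bias_bar) / row$sd_bias
  list(ratio = ratio, exceeds = ratio > threshold)
}

#' Per-partition conditional-error differences
#'
#' The customary protocol treats the true conditional error as one fixed
#' quantity per run; this diagnostic instead defines a separate true
#' conditional error for each fold-trained model. For every fold j of every
#' repetition r it computes \eqn{e_{ijr}}, the holdout misclassification of
#' the model trained on the sample minus fold j, measured on the
#' super-population remainder, and \eqn{\hat e_{ijr}}, that model's error on
#' its own test fold; it returns all differences
#' \eqn{\hat e_{ijr} - e_{ijr}}. Their spread isolates estimation error from
#' the fold-to-fold drift of the estimand.
#'
#' @param sample A `labeled_sample` drawn from `sp` with `source_indices`.
#' @param sp The originating `super_population`.
#' @param k Folds per repetition.
#' @param R Repetitions.
#' @param seed Optional seed for the partitions.
#' @param priors,unbiased Passed to the QDA fit.
#' @return Numeric vector of R x k differences.
#' @export
per_partition_conditional_errors <- function(sample, sp, k, R, seed = NULL,
                                             priors = c(0.5, 0.5),
                                             unbiased = TRUE) {
  if (is.null(sample$source_indices))
    stop_argument("`sample` must record source_indices")
  hold <- setdiff(seq_len(nrow(sp$features)), sample$source_indices)
  Xh <- sp$features[hold, , drop = FALSE]
  yh <- sp$labels[hold]
  rep_folds <- repeated_kfold(sample, k, R, seed, priors, unbiased,
                              record = TRUE)$folds
  X <- as.matrix(sample$features)
  y <- sample$labels
  diffs <- numeric(0)
  for (r in seq_len(R)) {
    fold_of <- rep_folds[r, ]
    for (j in sort(unique(fold_of))) {
      test <- which(fold_of == j)
      model <- train_qda(labeled_sample(X[-test, , drop = FALSE], y[-test]),
                         priors, unbiased)
      e_hat <- misclassification_rate(model, X[test, , drop = FALSE], y[test])
      e_true <- misclassification_rate(model, Xh, yh)
      diffs <- c(diffs, e_hat - e_true)
    }
  }
  diffs
}
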