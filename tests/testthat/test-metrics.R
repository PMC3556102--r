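test_that("per-run decomposition matches hand arithmetic and its identity", {
  d <- per_run_decomposition(0.2, 0.3)
  expect_equal(d$mse, 0.01)
  expect_equal(d$var, 0)  # single repetition: no within-run variance
  expect_equal(d$bias, -0.1)
  d2 <- per_run_decomposition(c(0.1, 0.3), 0.2)
  expect_equal(d2$mse, 0.01)
  expect_equal(d2$var, 0.01)
  expect_equal(d2$bias, 0)
  set.seed(31)
  for (i in 1:200) {
    est <- runif(sample(1:10, 1))
    e <- runif(1)
    d <- per_run_decomposition(est, e)
    expect_lt(abs(d$mse - (d$var + d$bias^2)), 1e-12)
  }
  expect_error(per_run_decomposition(numeric(0), 0.1),
               class = "cvbias_argument_error")
})

test_that("aggregation over a hand-worked three-run fixture matches spreadsheet arithmetic", {
  # run 1: est (0.1, 0.3), e = 0.2;  run 2: (0.2, 0.4), e = 0.1;
  # run 3: (0.0, 0.2), e = 0.3
  recs <- list(run_record(1, 0.2, c(0.1, 0.3)),
               run_record(2, 0.1, c(0.2, 0.4)),
               run_record(3, 0.3, c(0.0, 0.2)))
  row <- aggregate_records(recs, method = "toy")
  # straight-line recomputation, kept independent of the implementation:
  # biases 0, .2, -.2; per-run var .01 each;
  # mses .01, .05, .05
  expect_equal(row$e_bar, (0.2 + 0.1 + 0.3) / 3)
  expect_equal(row$e_bar_N, (0.2 + 0.3 + 0.1) / 3)
  expect_equal(row$mse_bar, (0.01 + 0.05 + 0.05) / 3)
  expect_equal(row$sd_mse, sd(c(0.01, 0.05, 0.05)))
  expect_equal(row$var_bar, 0.01)
  expect_equal(row$sd_var, 0)
  expect_equal(row$msb, (0 + 0.04 + 0.04) / 3)
  expect_equal(row$bias_bar, 0)
  expect_equal(row$sd_bias, sd(c(0, 0.2, -0.2)))
  expect_lt(abs(row$mse_bar - (row$var_bar + row$msb)), 1e-12)
  dec <- msb_decomposition(recs)
  expect_equal(unname(dec["sd_component"]), 0.08 / 3)
  expect_equal(unname(dec["mean_component"]), 0)
})

test_that("all-perfect estimates collapse every statistic except the shared mean error", {
  recs <- lapply(1:4, function(i) run_record(i, 0.25, rep(0.25, 3)))
  row <- aggregate_records(recs)
  expect_equal(row$e_bar, row$e_bar_N)
  expect_equal(c(row$mse_bar, row$sd_mse, row$var_bar, row$sd_var, row$msb,
                 row$bias_bar, row$sd_bias), rep(0, 7))
})

test_that("aggregate identities hold on random records and survive reordering", {
  set.seed(32)
  recs <- lapply(1:50, function(i) run_record(i, runif(1), runif(5)))
  row <- aggregate_records(recs)
  expect_lt(abs(row$mse_bar - (row$var_bar + row$msb)), 1e-10)
  # MSB splits into (N-1)/N x SD(BIAS)^2 + mean-bias^2
  N <- 50
  expect_lt(abs(row$msb - ((N - 1) / N * row$sd_bias^2 + row$bias_bar^2)),
            1e-12)
  dec <- msb_decomposition(recs)
  expect_true(all(dec >= 0))
  expect_equal(sum(dec), row$msb)
  shuffled <- aggregate_records(recs[sample(N)])
  expect_equal(shuffled[-1], row[-1])
  # inconsistent repetition counts are rejected
  bad <- c(recs, list(run_record(51, 0.5, runif(3))))
  expect_error(aggregate_records(bad), class = "cvbias_argument_error")
})

test_that("relative bias and the bias-to-spread ratio behave as signed and absolute ratios", {
  row <- data.frame(bias_bar = -0.11250, e_bar = 0.38308, sd_bias = 0.04693)
  expect_equal(relative_bias(row), -0.11250 / 0.38308)
  r <- bias_sd_ratio(row)
  expect_equal(r$ratio, 0.11250 / 0.04693)
  expect_true(r$exceeds)
  row2 <- transform(row, bias_bar = 0)
  expect_equal(relative_bias(row2), 0)
  expect_false(bias_sd_ratio(row2)$exceeds)
  row3 <- transform(row, bias_bar = 2 * bias_bar, e_bar = 2 * e_bar)
  expect_equal(relative_bias(row3), relative_bias(row))
  expect_equal(bias_sd_ratio(transform(row, bias_bar = -bias_bar))$ratio,
               r$ratio)
  expect_error(relative_bias(transform(row, e_bar = 0)),
               class = "cvbias_argument_error")
  expect_error(bias_sd_ratio(transform(row, sd_bias = 0)),
               class = "cvbias_argument_error")
})

test_that("per-partition conditional errors are structurally sound", {
  sp <- small_super_population(p = 1, delta = 30, M = 300, seed = 13)
  smp <- draw_stratified_sample(sp, 12, seed = 14)
  # widely separated classes: fold estimates and fold truths are all zero
  d <- per_partition_conditional_errors(smp, sp, k = 6, R = 2, seed = 15)
  expect_length(d, 12L)
  expect_true(all(d == 0))
  # k = n: one difference per left-out point; fold errors are 0 or 1
  sp2 <- small_super_population(p = 1, delta = 1, M = 300, seed = 16)
  smp2 <- draw_stratified_sample(sp2, 10, seed = 17)
  d2 <- per_partition_conditional_errors(smp2, sp2, k = 10, R = 1, seed = 18)
  expect_length(d2, 10L)
  # each difference is a 0/1 single-point estimate minus a holdout proportion
  expect_true(all(d2 > -1 & d2 < 1))
  expect_error(per_partition_conditional_errors(
    labeled_sample(smp2$features, smp2$labels), sp2, k = 5, R = 1),
    class = "cvbias_argument_error")
})
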