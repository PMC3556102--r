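test_that("training recovers hand-computed class moments", {
  m <- train_qda(toy_1d_sample())
  expect_equal(unname(m$means[, 1]), c(0.5, 5.5))
  expect_equal(m$covariances[[1]][1, 1], 5 / 3)
  expect_equal(m$covariances[[2]][1, 1], 5 / 3)
  mb <- train_qda(toy_1d_sample(), unbiased = FALSE)
  expect_equal(mb$covariances[[1]][1, 1], 5 / 4)
})

test_that("prediction matches a direct Gaussian log-density oracle and MASS on random instances", {
  for (seed in 1:3) {
    smp <- random_sample(p = 5, n = 40, delta = 1, seed = seed)
    set.seed(seed + 100)
    pts <- matrix(rnorm(100 * 5), 100, 5)
    model <- train_qda(smp)
    got <- predict_qda(model, pts)
    want <- cvbias:::oracle_qda_predict(smp$features, smp$labels, pts)
    expect_identical(got, want)
    fit <- MASS::qda(smp$features, grouping = factor(smp$labels),
                     prior = c(0.5, 0.5))
    expect_identical(got, as.integer(predict(fit, pts)$class))
  }
})

test_that("exact discriminant ties go to class 1", {
  # identical point sets per class: scores are equal everywhere
  X <- matrix(c(0, 1, 2, 3, 0, 1, 2, 3), ncol = 1)
  m <- train_qda(labeled_sample(X, rep(1:2, each = 4)))
  expect_true(all(predict_qda(m, matrix(seq(-2, 5, 0.5))) == 1L))
})

test_that("a point at a class mean of a well-separated model takes that class", {
  smp <- random_sample(p = 2, n = 30, delta = 6, seed = 2)
  m <- train_qda(smp)
  expect_equal(predict_qda(m, m$means[1, , drop = FALSE]), 1L)
  expect_equal(predict_qda(m, m$means[2, , drop = FALSE]), 2L)
})

test_that("predictions are invariant to a common positive rescaling of the features", {
  smp <- random_sample(p = 3, n = 30, delta = 1, seed = 5)
  set.seed(6); pts <- matrix(rnorm(60 * 3), 60, 3)
  base <- predict_qda(train_qda(smp), pts)
  scaled <- labeled_sample(smp$features * 7.3, smp$labels)
  expect_identical(predict_qda(train_qda(scaled), pts * 7.3), base)
})

test_that("trained QDA is consistent with the optimal-rule error at large n", {
  cfg <- population_config(1, 1, "equal")
  set.seed(8)
  n <- 5000
  X <- matrix(c(rnorm(n / 2), rnorm(n / 2) + 1), ncol = 1)
  smp <- labeled_sample(X, rep(1:2, each = n / 2))
  model <- train_qda(smp)
  Xt <- matrix(c(rnorm(5e4), rnorm(5e4) + 1), ncol = 1)
  err <- misclassification_rate(model, Xt, rep(1:2, each = 5e4))
  expect_lt(abs(err - bayes_error(cfg)), 0.01)
})

test_that("misclassification rate is an exact error fraction", {
  smp <- random_sample(p = 1, n = 20, delta = 50, seed = 3)
  m <- train_qda(smp)
  expect_equal(misclassification_rate(m, smp$features, smp$labels), 0)
  expect_equal(misclassification_rate(m, smp$features, 3L - smp$labels), 1)
  pred <- predict_qda(m, smp$features)
  lab <- smp$labels
  lab[1:3] <- 3L - pred[1:3]  # force exactly 3 errors among 20
  expect_equal(misclassification_rate(m, smp$features, lab), 3 / 20)
  expect_error(misclassification_rate(m, smp$features[0, , drop = FALSE],
                                      integer(0)),
               class = "cvbias_argument_error")
})

test_that("degenerate training raises a typed condition distinct from argument errors", {
  zero_var <- labeled_sample(matrix(c(1, 1, 1, 1, 2, 3, 4, 5), ncol = 1),
                             rep(1:2, each = 4))
  expect_error(train_qda(zero_var), class = "cvbias_degenerate_error")
  one_class <- labeled_sample(matrix(rnorm(6), ncol = 1), rep(1L, 6))
  expect_error(train_qda(one_class), class = "cvbias_argument_error")
})

test_that("distinct observations per class are counted by exact row equality", {
  X <- matrix(c(0, 0, 1, 2, 5, 6, 7, 8), ncol = 1)
  s <- labeled_sample(X, rep(1:2, each = 4))
  expect_equal(count_distinct_per_class(s), c(3L, 4L))
  smp <- random_sample(p = 2, n = 30, seed = 4)
  expect_equal(count_distinct_per_class(smp), c(15L, 15L))
})
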