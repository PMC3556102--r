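test_that("scheme plans reproduce the equalized-retraining design", {
  B <- 50L
  n <- 50L
  plans <- lapply(table_schemes(1, B), scheme_plan, n = n)
  expect_equal(vapply(plans, `[[`, integer(1), "R"),
               c(kCVn = 1L, BCVn = 50L, kCVn2 = 100L, BCVn2 = 100L,
                 kCV10 = 250L, BCV10 = 250L))
  # retrainings: n for LOOCV, B x n otherwise
  expect_equal(scheme_retraining_count(scheme_spec("kCVn"), 50), 50L)
  expect_equal(scheme_retraining_count(scheme_spec("BCV10", B = 50), 100), 5000L)
  expect_equal(scheme_retraining_count(scheme_spec("kCVn2", B = 50), 20), 1000L)
  # p-dependent bootstrap safeguards
  s1 <- table_schemes(1)$BCVn; s5 <- table_schemes(5)$BCVn
  expect_false(s1$stratified_bootstrap); expect_equal(s1$min_distinct_per_class, 4L)
  expect_true(s5$stratified_bootstrap); expect_equal(s5$min_distinct_per_class, 8L)
})

test_that("LOOCV is deterministic and equals brute-force enumeration", {
  smp <- random_sample(p = 1, n = 8, delta = 1, seed = 21)
  got <- loocv(smp)
  expect_length(got$estimates, 1L)
  expect_identical(got$estimates, loocv(smp)$estimates)
  expect_equal(got$estimates, brute_force_cv(smp, seq_len(8)))
  # LOOCV is n-fold CV: identical for every repetition
  rk <- repeated_kfold(smp, k = 8, R = 3, seed = 5)
  expect_equal(rk$estimates, rep(got$estimates, 3))
})

test_that("repeated k-fold covers each point once per repetition with near-equal folds", {
  smp <- random_sample(p = 1, n = 20, delta = 1, seed = 22)
  rk <- repeated_kfold(smp, k = 10, R = 5, seed = 9, record = TRUE)
  expect_length(rk$estimates, 5L)
  for (r in 1:5) {
    sizes <- table(rk$folds[r, ])
    expect_length(sizes, 10L)
    expect_true(max(sizes) - min(sizes) <= 1)
  }
  # fixed partitions replayed by the naive oracle give identical estimates
  for (r in 1:5)
    expect_equal(rk$estimates[r], brute_force_cv(smp, rk$folds[r, ]))
})

test_that("uneven fold sizes differ by at most one and estimates match the oracle", {
  smp <- random_sample(p = 1, n = 10, delta = 2, seed = 30)
  rk <- repeated_kfold(smp, k = 4, R = 4, seed = 2, record = TRUE)
  for (r in 1:4) {
    sizes <- table(rk$folds[r, ])
    expect_true(max(sizes) - min(sizes) <= 1)
    expect_equal(rk$estimates[r], brute_force_cv(smp, rk$folds[r, ]))
  }
})

test_that("bootstrap CV replays exactly from its recorded resamples", {
  smp <- random_sample(p = 1, n = 10, delta = 1, seed = 23)
  spec <- scheme_spec("BCVn", B = 3L)
  ev <- bootstrap_cv(smp, spec, seed = 77, record = TRUE)
  expect_length(ev$estimates, 3L)
  for (r in 1:3)
    expect_equal(ev$estimates[r],
                 brute_force_cv(smp, seq_len(10), indices = ev$indices[r, ]))
  # every estimate is a fraction of the n bootstrap members
  expect_true(all(ev$estimates >= 0 & ev$estimates <= 1))
})

test_that("schemes are seed-reproducible; random schemes vary across seeds, LOOCV does not", {
  smp <- random_sample(p = 1, n = 20, delta = 1, seed = 24)
  spec <- scheme_spec("BCV10", B = 5L)
  a <- bootstrap_cv(smp, spec, seed = 1)$estimates
  b <- bootstrap_cv(smp, spec, seed = 1)$estimates
  c <- bootstrap_cv(smp, spec, seed = 2)$estimates
  expect_identical(a, b)
  expect_false(identical(a, c))
  k1 <- repeated_kfold(smp, 10, 5, seed = 1)$estimates
  k2 <- repeated_kfold(smp, 10, 5, seed = 2)$estimates
  expect_false(identical(k1, k2))
  expect_identical(loocv(smp)$estimates, loocv(smp)$estimates)
})

test_that("perfectly separated classes give zero error under all six schemes", {
  smp <- make_separable_sample(p = 1, n = 20, gap = 100, seed = 3)
  for (spec in table_schemes(1, B = 5L)) {
    ev <- estimate_scheme(smp, spec, seed = 4)
    expect_true(all(ev$estimates == 0), label = spec$name)
    expect_length(ev$estimates, scheme_plan(spec, 20)$R)
  }
})

test_that("bootstrap draws contain about 1 - (1 - 1/n)^n distinct observations", {
  smp <- random_sample(p = 1, n = 50, delta = 1, seed = 25)
  ev <- bootstrap_cv(smp, scheme_spec("BCVn", B = 2000L), seed = 6,
                     record = TRUE)
  frac <- apply(ev$indices, 1, function(ix) length(unique(ix)) / 50)
  expected <- 1 - (1 - 1 / 50)^50
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - expected), 4 * se)
})

test_that("stratified bootstrap draws n/2 members from each class", {
  smp <- random_sample(p = 5, n = 20, delta = 1, seed = 26)
  spec <- scheme_spec("BCVn", B = 20L, min_distinct_per_class = 8L,
                      stratified_bootstrap = TRUE)
  ev <- bootstrap_cv(smp, spec, seed = 8, record = TRUE)
  for (r in seq_len(nrow(ev$indices))) {
    cls <- smp$labels[ev$indices[r, ]]
    expect_equal(unname(table(cls)), c(10L, 10L), ignore_attr = TRUE)
    expect_true(all(table(cls, exclude = NULL) >= 8))
  }
})

test_that("the distinct-observation floor is enforced by redrawing", {
  # a tiny sample makes violations common enough to observe redraws
  smp <- random_sample(p = 1, n = 8, delta = 1, seed = 27)
  spec <- scheme_spec("BCVn", B = 200L, min_distinct_per_class = 4L)
  ev <- bootstrap_cv(smp, spec, seed = 10, record = TRUE)
  expect_gt(ev$redraw_count, 0)
  for (r in seq_len(nrow(ev$indices))) {
    cls <- smp$labels[ev$indices[r, ]]
    d1 <- length(unique(ev$indices[r, cls == 1L]))
    d2 <- length(unique(ev$indices[r, cls == 2L]))
    expect_true(d1 >= 4 && d2 >= 4)
  }
  # an unsatisfiable floor exhausts the redraw budget with a typed error
  spec_bad <- scheme_spec("BCVn", B = 2L, min_distinct_per_class = 5L,
                          max_redraws = 50L)
  expect_error(bootstrap_cv(smp, spec_bad, seed = 11),
               class = "cvbias_exhausted_error")
})

test_that("degenerate fold training propagates as a typed condition for fixed-sample schemes", {
  # class 1 collapses to a single value once one point is held out
  X <- matrix(c(0, 0, 0, 1, 5, 6, 7, 8), ncol = 1)
  smp <- labeled_sample(X, rep(1:2, each = 4))
  expect_error(loocv(smp), class = "cvbias_degenerate_error")
})
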