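# Small deterministic samples shared across test files.

toy_1d_sample <- function() {
  # class 1 = {-1, 0, 1, 2}, class 2 = {4, 5, 6, 7}
  labeled_sample(matrix(c(-1, 0, 1, 2, 4, 5, 6, 7), ncol = 1),
                 rep(1:2, each = 4))
}

random_sample <- function(p, n, delta = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), n / 2, p),
             matrix(rnorm(n / 2 * p) + delta / sqrt(p), n / 2, p))
  labeled_sample(X, rep(1:2, each = n / 2))
}

small_super_population <- function(p = 1, delta = 1, M = 500, seed = 11) {
  draw_super_population(
    population_config(p, delta, "equal", per_class_size = M), seed)
}
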