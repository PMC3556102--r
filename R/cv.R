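#' Resampling scheme specification
#'
#' The six schemes compared in the study, with retraining budgets equalized
#' at B x n classifier fits (LOOCV, `kCVn`, is the exception: it is unique,
#' so it is run once at n fits). Repetition counts follow the design:
#'
#' | name  | folds | repetitions R | sample type |
#' |-------|-------|---------------|-------------|
#' | kCVn  | n     | 1             | none (LOOCV) |
#' | BCVn  | n     | B             | bootstrap |
#' | kCVn2 | n/2   | 2B            | permutation |
#' | BCVn2 | n/2   | 2B            | bootstrap |
#' | kCV10 | 10    | B n/10        | permutation |
#' | BCV10 | 10    | B n/10        | bootstrap |
#'
#' Bootstrap schemes redraw any resample with fewer than
#' `min_distinct_per_class` distinct source observations in either class
#' (4 in the p = 1 study, 8 with stratified resampling in the p = 5 study).
#'
#' @param name One of `"kCVn"`, `"BCVn"`, `"kCVn2"`, `"BCVn2"`, `"kCV10"`,
#'   `"BCV10"`.
#' @param B Bootstrap budget parameter (default 50).
#' @param min_distinct_per_class Distinct-observation floor for bootstrap
#'   resamples.
#' @param stratified_bootstrap Draw n/2 bootstrap members per class instead
#'   of n unstratified.
#' @param max_redraws Rejection-sampling cap per repetition.
#' @return A `scheme_spec`.
#' @export
scheme_spec <- function(name, B = 50L, min_distinct_per_class = 4L,
                        stratified_bootstrap = FALSE, max_redraws = 10000L) {
  name <- match.arg(name, c("kCVn", "BCVn", "kCVn2", "BCVn2", "kCV10", "BCV10"))
  if (B < 1) stop_argument("`B` must be >= 1")
  structure(list(name = name, B = as.integer(B),
                 min_distinct_per_class = as.integer(min_distinct_per_class),
                 stratified_bootstrap = isTRUE(stratified_bootstrap),
                 max_redraws = as.integer(max_redraws)),
            class = "scheme_spec")
}

#' The full six-scheme registry for a given dimension
#'
#' Applies the study's dimension-dependent bootstrap safeguards: p = 1 uses
#' unstratified bootstrap draws with >= 4 distinct observations per class;
#' p > 1 uses stratified draws (n/2 per class) with >= 8 distinct per class.
#'
#' @param p Feature dimension.
#' @param B Bootstrap budget (default 50).
#' @return Named list of six [scheme_spec()] objects.
#' @export
table_schemes <- function(p, B = 50L) {
  strat <- p > 1
  md <- if (strat) 8L else 4L
  nm <- c("kCVn", "BCVn", "kCVn2", "BCVn2", "kCV10", "BCV10")
  setNames(lapply(nm, scheme_spec, B = B, min_distinct_per_class = md,
                  stratified_bootstrap = strat), nm)
}

#' Folds and repetitions implied by a scheme at sample size n
#'
#' @param spec A [scheme_spec()].
#' @param n Sample size (must be divisible as the scheme requires).
#' @return List with `k` (folds) and `R` (repetitions).
#' @export
scheme_plan <- function(spec, n) {
  B <- spec$B
  switch(spec$name,
    kCVn  = list(k = n,     R = 1L),
    BCVn  = list(k = n,     R = B),
    kCVn2 = list(k = n %/% 2L, R = 2L * B),
    BCVn2 = list(k = n %/% 2L, R = 2L * B),
    kCV10 = list(k = 10L,   R = as.integer(B * n / 10)),
    BCV10 = list(k = 10L,   R = as.integer(B * n / 10)))
}

#' Total number of classifier retrainings for a scheme
#'
#' n for LOOCV (`kCVn`); B x n for every other scheme (constraint-redraw
#' overhead excluded).
#'
#' @param spec A [scheme_spec()].
#' @param n Sample size.
#' @return Integer retraining count.
#' @export
scheme_retraining_count <- function(spec, n) {
  if (spec$name == "kCVn") as.integer(n) else as.integer(spec$B * n)
}

estimate_vector <- function(spec, estimates, redraw_count = 0L) {
  structure(list(scheme = spec, estimates = as.numeric(estimates),
                 redraw_count = as.integer(redraw_count)),
            class = "estimate_vector")
}

log_priors <- function(priors) {
  if (abs(sum(priors) - 1) > 1e-12) stop_argument("priors must sum to 1")
  log(priors)
}

#' Leave-one-out cross-validation
#'
#' Each of the n observations is left out once, QDA is retrained on the
#' remaining n - 1, and the estimate is the misclassified fraction of the n
#' held-out predictions. Deterministic: there is a single way to perform
#' LOOCV, so the result carries no seed dependence.
#'
#' @param sample A `labeled_sample`.
#' @param priors,unbiased Passed to the QDA fit.
#' @return An `estimate_vector` of length 1.
#' @export
loocv <- function(sample, priors = c(0.5, 0.5), unbiased = TRUE) {
  X <- as.matrix(sample$features)
  n <- nrow(X)
  lp <- log_priors(priors)
  m <- cpp_partition_miscount(X, sample$labels, seq_len(n), n,
                              unbiased, lp[1], lp[2])
  if (m < 0) stop_degenerate("degenerate QDA training in a LOOCV fold")
  estimate_vector(scheme_spec("kCVn"), m / n)
}

#' Repeated k-fold cross-validation
#'
#' For each repetition the n original observations are re-partitioned at
#' random into k folds with sizes differing by at most 1 (folds are not
#' class-stratified); each fold is predicted by a model trained on the other
#' k - 1 folds and the estimate is the misclassified fraction of all n
#' points.
#'
#' @param sample A `labeled_sample`.
#' @param k Number of folds, 2 <= k <= n (k = n reproduces [loocv()]).
#' @param R Number of independent repetitions.
#' @param seed Optional seed.
#' @param priors,unbiased Passed to the QDA fit.
#' @param record Also return the fold assignment matrix (R x n) for replay.
#' @return An `estimate_vector` of length R (with `folds` attached when
#'   `record = TRUE`).
#' @export
repeated_kfold <- function(sample, k, R, seed = NULL, priors = c(0.5, 0.5),
                           unbiased = TRUE, record = FALSE) {
  X <- as.matrix(sample$features)
  n <- nrow(X)
  if (k < 2 || k > n) stop_argument("`k` must be in [2, n]")
  if (R < 1) stop_argument("`R` must be >= 1")
  lp <- log_priors(priors)
  res <- with_seed(seed,
    cpp_repeated_kfold(X, sample$labels, as.integer(k), as.integer(R),
                       unbiased, lp[1], lp[2], record))
  if (anyNA(res$estimates))
    stop_degenerate("degenerate QDA training in a k-fold partition")
  out <- estimate_vector(scheme_spec("kCV10"), res$estimates)
  out$scheme$name <- if (k == n) "kCVn" else if (k == 10) "kCV10" else "kCVn2"
  if (record) out$folds <- res$folds
  out
}

#' Bootstrap cross-validation
#'
#' For each of R repetitions a with-replacement sample of size n is drawn
#' from the original n observations (n/2 per class when the spec requests
#' stratified draws) and redrawn until both classes contain at least the
#' spec's minimum number of distinct source observations; the resample is
#' then cross-validated entirely within itself -- LOOCV for `BCVn` (every
#' bootstrap member, duplicates included, left out once), n/2 folds for
#' `BCVn2`, 10 folds for `BCV10` -- and the estimate is the misclassified
#' fraction of the n bootstrap members. A resample whose class duplicates
#' still make QDA training degenerate is redrawn once more. Note the test
#' fold may contain rows whose duplicates sit in the training part: this
#' with-replacement leakage is the mechanism of the estimator's negative
#' bias and is intentional.
#'
#' @param sample A `labeled_sample`.
#' @param spec A bootstrap [scheme_spec()] (`BCVn`, `BCVn2`, `BCV10`).
#' @param seed Optional seed.
#' @param priors,unbiased Passed to the QDA fit.
#' @param record Also return the R x n matrix of drawn source-row indices.
#' @return An `estimate_vector` of length R with the total redraw count.
#' @export
bootstrap_cv <- function(sample, spec, seed = NULL, priors = c(0.5, 0.5),
                         unbiased = TRUE, record = FALSE) {
  if (!inherits(spec, "scheme_spec") ||
      !spec$name %in% c("BCVn", "BCVn2", "BCV10"))
    stop_argument("`spec` must be a bootstrap scheme (BCVn, BCVn2, BCV10)")
  X <- as.matrix(sample$features)
  n <- nrow(X)
  plan <- scheme_plan(spec, n)
  lp <- log_priors(priors)
  res <- with_seed(seed,
    cpp_bootstrap_cv(X, sample$labels, plan$k, plan$R,
                     spec$stratified_bootstrap, spec$min_distinct_per_class,
                     spec$max_redraws, unbiased, lp[1], lp[2], record))
  if (res$exhausted_at > 0)
    stop_exhausted(sprintf(
      "bootstrap repetition %d exceeded max_redraws = %d",
      res$exhausted_at, spec$max_redraws))
  out <- estimate_vector(spec, res$estimates, res$redraws)
  if (record) out$indices <- res$indices
  out
}

#' Run any of the six schemes on a sample
#'
#' Dispatches to [loocv()], [repeated_kfold()] or [bootstrap_cv()] according
#' to the spec, with the repetition counts of the equalized-retraining
#' design.
#'
#' @param sample A `labeled_sample`.
#' @param spec A [scheme_spec()].
#' @param seed Optional seed (ignored by the deterministic `kCVn`).
#' @param priors,unbiased Passed to the QDA fit.
#' @return An `estimate_vector`.
#' @export
estimate_scheme <- function(sample, spec, seed = NULL, priors = c(0.5, 0.5),
                            unbiased = TRUE) {
  plan <- scheme_plan(spec, sample$n)
  switch(spec$name,
    kCVn = loocv(sample, priors, unbiased),
    kCVn2 = ,
    kCV10 = repeated_kfold(sample, plan$k, plan$R, seed, priors, unbiased),
    bootstrap_cv(sample, spec, seed, priors, unbiased))
}
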