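#' Select top features by two-sample t-statistic
#'
#' Computes a Welch two-sample t-statistic per feature, adjusts the p-values
#' by Benjamini-Hochberg, and returns the m most significant features.
#' Ties on adjusted significance are broken by larger |t|, then by feature
#' index. A feature with zero variance in both classes has an undefined
#' statistic and is ranked last.
#'
#' @param data n x G numeric feature matrix (rows = samples).
#' @param labels Class labels in \{1, 2\}, length n.
#' @param m Number of features to keep.
#' @return Integer vector of m column indices, most significant first.
#' @export
select_top_features_by_t <- function(data, labels, m) {
  X <- as.matrix(data)
  if (m > ncol(X)) stop_argument("`m` exceeds the number of features")
  if (sum(labels == 1L) < 2L || sum(labels == 2L) < 2L)
    stop_argument("need at least two samples per class")
  X1 <- X[labels == 1L, , drop = FALSE]
  X2 <- X[labels == 2L, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  v1 <- apply(X1, 2, stats::var) / n1
  v2 <- apply(X2, 2, stats::var) / n2
  tstat <- (colMeans(X1) - colMeans(X2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  pval <- 2 * pt(-abs(tstat), df)
  pval[!is.finite(tstat)] <- 1  # zero variance in both classes: ranked last
  padj <- p.adjust(pval, method = "BH")
  abs_t <- abs(tstat)
  abs_t[!is.finite(abs_t)] <- -Inf
  ord <- order(padj, -abs_t, seq_along(padj))
  ord[seq_len(m)]
}

#' Resampling study on a user-supplied dataset
#'
#' Applies the super-population protocol to a finite labeled dataset: for
#' each of N runs (1) draw a stratified subsample of size n without
#' replacement, (2) select m features by t-statistic (by default within the
#' subsample; set `global_selection` to select once on the full dataset) and
#' train QDA on them, (3) measure the true conditional error on the
#' remaining dataset members, (4) estimate it with every requested scheme,
#' (5) aggregate the decomposition over runs.
#'
#' @param data n x G numeric feature matrix or data frame.
#' @param labels Class labels in \{1, 2\}.
#' @param n Subsample size (even; n/2 per class; must leave a nonempty
#'   holdout).
#' @param m Number of features to select.
#' @param schemes List of [scheme_spec()]s.
#' @param N Number of runs.
#' @param seed Master seed.
#' @param global_selection Select features once on the full dataset instead
#'   of inside each subsample.
#' @param priors,unbiased Passed to the QDA fit.
#' @return As [run_cell()]: list with `rows`, `archive`, `true_errors`,
#'   `redraws`.
#' @export
run_dataset_study <- function(data, labels, n, m, schemes, N, seed,
                              global_selection = FALSE,
                              priors = c(0.5, 0.5), unbiased = TRUE) {
  X <- as.matrix(data)
  labels <- as.integer(labels)
  if (n %% 2 != 0) stop_argument("`n` must be even")
  if (min(sum(labels == 1L), sum(labels == 2L)) < n / 2)
    stop_argument("each class needs at least n/2 members")
  if (nrow(X) <= n)
    stop_argument("`n` must leave a nonempty holdout")
  if (any(!is.finite(X))) stop_argument("features must be finite numeric")
  g_idx <- if (global_selection) select_top_features_by_t(X, labels, m)
           else NULL
  i1 <- which(labels == 1L); i2 <- which(labels == 2L)
  sch_names <- unname(vapply(schemes, `[[`, character(1), "name"))
  recs <- lapply(schemes, function(s) vector("list", N))
  redraws <- setNames(integer(length(schemes)), sch_names)
  e <- numeric(N)
  for (i in seq_len(N)) {
    set.seed(derive_seed(seed, i, 0))
    take <- c(sample(i1, n / 2), sample(i2, n / 2))
    feat <- if (global_selection) g_idx
            else select_top_features_by_t(X[take, , drop = FALSE],
                                          labels[take], m)
    smp <- labeled_sample(X[take, feat, drop = FALSE], labels[take],
                          source_indices = take)
    model <- train_qda(smp, priors, unbiased)
    hold <- setdiff(seq_len(nrow(X)), take)
    e[i] <- misclassification_rate(model, X[hold, feat, drop = FALSE],
                                   labels[hold])
    for (j in seq_along(schemes)) {
      ev <- estimate_scheme(smp, schemes[[j]], seed = derive_seed(seed, i, j),
                            priors = priors, unbiased = unbiased)
      recs[[j]][[i]] <- run_record(i, e[i], ev$estimates)
      redraws[j] <- redraws[j] + ev$redraw_count
    }
  }
  rows <- do.call(rbind, lapply(seq_along(schemes), function(j)
    aggregate_records(recs[[j]], method = sch_names[j], n = n,
                      B = schemes[[j]]$B)))
  archive <- do.call(rbind, lapply(seq_along(schemes), function(j)
    data.frame(run = seq_len(N), scheme = sch_names[j],
               e_i = records_field(recs[[j]], "e_i"),
               e_bar_Ri = records_field(recs[[j]], "mean_estimate"),
               bias_i = records_field(recs[[j]], "bias"),
               var_i = records_field(recs[[j]], "var"),
               mse_i = records_field(recs[[j]], "mse"),
               stringsAsFactors = FALSE)))
  list(rows = rows, archive = archive, true_errors = e, redraws = redraws)
}
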