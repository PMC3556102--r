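#' True conditional error on the super-population holdout
#'
#' The misclassification proportion of a trained model on the super-population
#' rows not used to train it (the 10000 - n remainder at default sizes):
#' the fixed estimand each resampling scheme tries to recover.
#'
#' @param model A [qda_model()].
#' @param sp The `super_population` the sample came from.
#' @param sample The `labeled_sample`, with `source_indices` recorded.
#' @return Proportion in \[0, 1\].
#' @export
true_conditional_error <- function(model, sp, sample) {
  if (is.null(sample$source_indices))
    stop_argument("`sample` must record source_indices into `sp`")
  hold <- setdiff(seq_len(nrow(sp$features)), sample$source_indices)
  misclassification_rate(model, sp$features[hold, , drop = FALSE],
                         sp$labels[hold])
}

#' Run one simulation cell
#'
#' One (population, n) cell of the Monte Carlo study: for each of N runs,
#' draw a stratified sample of size n from the super-population, train QDA,
#' measure its true conditional error on the holdout, estimate that error
#' with every requested scheme, and decompose each scheme's MSE per run.
#' Seeds are derived per (run, scheme) from the master seed, so any cell is
#' reproducible in isolation.
#'
#' @param sp A `super_population`.
#' @param n Sample size.
#' @param schemes List of [scheme_spec()]s (possibly empty: the cell then
#'   only measures true errors).
#' @param N Number of simulation runs.
#' @param seed Master seed for the cell.
#' @param priors,unbiased Passed to the QDA fit.
#' @return List with `rows` (one aggregate `data.frame` row per scheme, or
#'   NULL when `schemes` is empty), `archive` (per run x scheme:
#'   `run, scheme, e_i, e_bar_Ri, bias_i, var_i, mse_i`), `true_errors`
#'   (length-N vector), and `redraws` (total bootstrap redraw count per
#'   scheme).
#' @export
run_cell <- function(sp, n, schemes, N, seed, priors = c(0.5, 0.5),
                     unbiased = TRUE) {
  stopifnot(inherits(sp, "super_population"))
  cfg <- sp$config
  if (n / 2 <= cfg$p)
    stop_argument("n/2 must exceed p for QDA to be trainable")
  sch_names <- unname(vapply(schemes, `[[`, character(1), "name"))
  recs <- setNames(vector("list", length(schemes)), sch_names)
  for (s in sch_names) recs[[s]] <- vector("list", N)
  redraws <- setNames(integer(length(schemes)), sch_names)
  e <- numeric(N)
  for (i in seq_len(N)) {
    smp <- draw_stratified_sample(sp, n, seed = derive_seed(seed, i, 0))
    model <- train_qda(smp, priors, unbiased)
    e[i] <- true_conditional_error(model, sp, smp)
    for (j in seq_along(schemes)) {
      ev <- estimate_scheme(smp, schemes[[j]], seed = derive_seed(seed, i, j),
                            priors = priors, unbiased = unbiased)
      recs[[j]][[i]] <- run_record(i, e[i], ev$estimates)
      redraws[j] <- redraws[j] + ev$redraw_count
    }
  }
  rows <- NULL
  archive <- NULL
  if (length(schemes)) {
    rows <- do.call(rbind, lapply(seq_along(schemes), function(j)
      aggregate_records(recs[[j]], method = sch_names[j], n = n,
                        delta = cfg$delta, p = cfg$p,
                        cov_case = cfg$covariance_case,
                        B = schemes[[j]]$B)))
    archive <- do.call(rbind, lapply(seq_along(schemes), function(j) {
      rr <- recs[[j]]
      data.frame(run = seq_len(N), scheme = sch_names[j],
                 e_i = records_field(rr, "e_i"),
                 e_bar_Ri = records_field(rr, "mean_estimate"),
                 bias_i = records_field(rr, "bias"),
                 var_i = records_field(rr, "var"),
                 mse_i = records_field(rr, "mse"),
                 stringsAsFactors = FALSE)
    }))
  }
  list(rows = rows, archive = archive, true_errors = e, redraws = redraws)
}

#' Study configuration
#'
#' The default grid reproduces the simulation design: p in \{1, 5\} crossed
#' with delta in \{1, 3\} and both covariance cases; n in \{20, 50, 100\}
#' for p = 1 and \{50, 100\} for p = 5 (twenty configurations), all six
#' schemes, N simulations per cell, B = 50.
#'
#' @param p_values,delta_values,cov_cases,N,B,master_seed Grid and study
#'   parameters.
#' @param n_for Function mapping p to its n values.
#' @return A `study_config`.
#' @export
study_config <- function(p_values = c(1L, 5L), delta_values = c(1, 3),
                         cov_cases = c("equal", "unequal"), N = 1000L,
                         B = 50L, master_seed = 1L,
                         n_for = function(p) if (p == 1) c(20L, 50L, 100L)
                                             else c(50L, 100L)) {
  structure(list(p_values = p_values, delta_values = delta_values,
                 cov_cases = cov_cases, N = as.integer(N), B = as.integer(B),
                 master_seed = as.integer(master_seed), n_for = n_for),
            class = "study_config")
}

#' Run the full Monte Carlo study
#'
#' One super-population is drawn per (p, delta, covariance case) and shared
#' by all its n values; every (population, n) cell is executed with
#' [run_cell()]. Optionally writes the results table and the per-run archive
#' (sufficient to redraw the per-run bias scatter without recomputation) as
#' CSV.
#'
#' @param config A [study_config()].
#' @param results_path,archive_path Optional CSV output paths.
#' @param quiet Suppress per-cell progress messages.
#' @return List with `results` (one row per cell x scheme) and `archive`.
#' @export
run_study <- function(config = study_config(), results_path = NULL,
                      archive_path = NULL, quiet = FALSE) {
  all_rows <- list()
  all_arch <- list()
  for (p in config$p_values) {
    schemes <- table_schemes(p, config$B)
    for (delta in config$delta_values) {
      for (cc in config$cov_cases) {
        pc <- population_config(p, delta, cc)
        sp <- draw_super_population(
          pc, derive_seed(config$master_seed, p, round(delta * 100),
                          match(cc, c("equal", "unequal"))))
        for (n in config$n_for(p)) {
          if (!quiet)
            message(sprintf("cell p=%d delta=%g cov=%s n=%d", p, delta, cc, n))
          cell <- run_cell(sp, n, schemes, config$N,
                           seed = derive_seed(config$master_seed, p,
                                              round(delta * 100),
                                              match(cc, c("equal", "unequal")),
                                              n))
          key <- sprintf("p%d_d%g_%s_n%d", p, delta, cc, n)
          all_rows[[key]] <- cell$rows
          arch <- cell$archive
          arch$p <- p; arch$delta <- delta; arch$cov_case <- cc; arch$n <- n
          all_arch[[key]] <- arch
        }
      }
    }
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  archive <- do.call(rbind, all_arch)
  rownames(archive) <- NULL
  if (!is.null(results_path)) write.csv(results, results_path, row.names = FALSE)
  if (!is.null(archive_path)) write.csv(archive, archive_path, row.names = FALSE)
  list(results = results, archive = archive)
}

#' Recompute aggregate rows from a per-run archive
#'
#' Round-trip companion to [run_study()]: rebuilds each scheme's aggregate
#' statistics from the archived per-run decompositions. `var_bar`/`sd_var`
#' and `mse_bar`/`sd_mse` are direct means/SDs of the archived columns; the
#' MSB identity links them to the bias columns.
#'
#' @param archive The archive `data.frame` from [run_study()] or
#'   [run_cell()].
#' @return Aggregate `data.frame`, one row per (cell, scheme).
#' @export
aggregate_from_archive <- function(archive) {
  keys <- c("scheme", intersect(c("p", "delta", "cov_case", "n"),
                                names(archive)))
  split_idx <- split(seq_len(nrow(archive)), archive[keys], drop = TRUE)
  out <- lapply(split_idx, function(ii) {
    a <- archive[ii, ]
    N <- nrow(a)
    data.frame(method = a$scheme[1],
               e_bar = mean(a$e_i), e_bar_N = mean(a$e_bar_Ri),
               mse_bar = mean(a$mse_i), sd_mse = sd(a$mse_i),
               var_bar = mean(a$var_i), sd_var = sd(a$var_i),
               msb = mean(a$bias_i^2),
               bias_bar = mean(a$bias_i), sd_bias = sd(a$bias_i),
               N_sims = N, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
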