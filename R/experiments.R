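# Experiment runners: utility of the selection mechanisms over an epsilon
# grid, input- vs output-perturbation error, and a distance-method
# benchmark. All runners are deterministic given `seed` (paired sub-seeds
# across the epsilon grid, so utility curves can be compared pointwise).

run_seed <- function(seed, rep, k = 0L) {
  # keep derived seeds inside 32-bit integer range
  (seed * 1009L + rep * 131L + k * 7L) %% 2147483647L
}

#' Mean selection utility over an epsilon grid
#'
#' Simulates one cohort from `spec`, then for each mechanism, `m_ret` and
#' epsilon runs the private selection `replicates` times and averages
#' [utility_overlap()] against the true top-`m_ret` SNPs by allelic
#' statistic. Mechanisms: `"adaptive"` (the adaptive-threshold neighbor
#' method), `"neighbor"` (fixed threshold, Bonferroni-corrected
#' `fixed_alpha`), `"laplace"` and `"score"` baselines.
#'
#' @param spec a [simulation_spec()].
#' @param mechanisms subset of the four mechanism names.
#' @param m_ret vector of return-list sizes.
#' @param epsilons epsilon grid.
#' @param replicates mechanism runs to average per cell.
#' @param seed integer seed governing cohort and all mechanism randomness.
#' @param fixed_alpha family-wise alpha for the fixed-threshold variant.
#' @param csv optional path: write the result table as CSV.
#' @return data.frame with columns `mechanism`, `m_ret`, `epsilon`,
#'   `utility` (mean) and `replicates`.
#' @export
run_utility_experiment <- function(spec = simulation_spec(),
                                   mechanisms = c("adaptive", "laplace", "score"),
                                   m_ret = 3, epsilons = c(1, 3, 5),
                                   replicates = 20, seed = 1,
                                   fixed_alpha = 0.05, csv = NULL) {
  mechanisms <- match.arg(mechanisms,
                          c("adaptive", "neighbor", "laplace", "score"),
                          several.ok = TRUE)
  set.seed(run_seed(seed, 0L))
  tab <- simulate_cohort(spec)
  Y <- table_statistics(tab)
  out <- expand.grid(mechanism = mechanisms, m_ret = m_ret,
                     epsilon = epsilons, stringsAsFactors = FALSE)
  out$utility <- NA_real_
  out$replicates <- replicates
  d <- table_design(tab)
  om_fixed <- threshold(bonferroni_threshold(fixed_alpha, nrow(tab)), d)
  fixed_scores <- NULL
  for (row in seq_len(nrow(out))) {
    m <- out$m_ret[row]
    A <- tab$snp_id[order(Y, decreasing = TRUE)[seq_len(m)]]
    mech <- out$mechanism[row]
    if (mech == "neighbor" && is.null(fixed_scores))
      fixed_scores <- neighbor_scores(tab, om_fixed)
    us <- vapply(seq_len(replicates), function(r) {
      set.seed(run_seed(seed, r, match(mech, c("adaptive", "neighbor",
                                               "laplace", "score"))))
      sel <- switch(mech,
        adaptive = pick_snps_adaptive(tab, m, privacy_budget(out$epsilon[row])),
        neighbor = pick_snps_neighbor(tab, m, out$epsilon[row], om_fixed,
                                      scores = fixed_scores),
        laplace = pick_snps_laplace(tab, m, out$epsilon[row]),
        score = pick_snps_score(tab, m, out$epsilon[row]))
      utility_overlap(A, sel$chosen)
    }, numeric(1))
    out$utility[row] <- mean(us)
  }
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Input- vs output-perturbation error on the top SNPs
#'
#' Simulates one cohort, takes its `top_k` true highest-scoring SNPs, and
#' for each epsilon measures the mean absolute error of the released
#' statistic under both perturbation modes, averaged over `replicates`
#' noise draws.
#'
#' @inheritParams run_utility_experiment
#' @param epsilons per-SNP release budgets.
#' @param top_k number of top SNPs released.
#' @return data.frame with columns `epsilon`, `mode`, `mean_abs_error`,
#'   `replicates`.
#' @export
run_perturbation_experiment <- function(spec = simulation_spec(),
                                        epsilons = c(0.25, 0.5, 1, 2),
                                        replicates = 1000, top_k = 10,
                                        seed = 1, csv = NULL) {
  set.seed(run_seed(seed, 0L))
  tab <- simulate_cohort(spec)
  Y <- table_statistics(tab)
  top <- tab[order(Y, decreasing = TRUE)[seq_len(top_k)], , drop = FALSE]
  attr(top, "design") <- table_design(tab)
  class(top) <- class(tab)
  Ytrue <- table_statistics(top)
  grid <- expand.grid(epsilon = epsilons, mode = c("input", "output"),
                      stringsAsFactors = FALSE)
  grid$mean_abs_error <- NA_real_
  grid$replicates <- replicates
  for (i in seq_len(nrow(grid))) {
    set.seed(run_seed(seed, i, 5L))
    err <- vapply(seq_len(replicates), function(r) {
      mean(abs(release_allelic(top, grid$epsilon[i], grid$mode[i]) - Ytrue))
    }, numeric(1))
    grid$mean_abs_error[i] <- mean(err)
  }
  if (!is.null(csv)) utils::write.csv(grid, csv, row.names = FALSE)
  grid
}

#' Benchmark the distance methods
#'
#' Runs the fast (exact) method and the hill-climbing baseline over every
#' SNP of a simulated cohort at threshold `omega`, reporting wall times and
#' the mean absolute disagreement (the baseline's approximation error).
#' Runtimes are informational only.
#'
#' @inheritParams run_utility_experiment
#' @param omega threshold; default the Bonferroni cutoff at alpha 0.05.
#' @return data.frame with one row per method: `method`, `seconds`,
#'   `mean_abs_error_vs_fast`.
#' @export
run_distance_benchmark <- function(spec = simulation_spec(), omega = NULL,
                                   seed = 1, csv = NULL) {
  set.seed(run_seed(seed, 0L))
  tab <- simulate_cohort(spec)
  d <- table_design(tab)
  if (is.null(omega)) omega <- bonferroni_threshold(0.05, nrow(tab))
  omega <- threshold(omega, d)
  t_fast <- system.time(
    fast <- vapply(seq_len(nrow(tab)), function(i)
      nd_fast(row_counts(tab, i), as.numeric(omega), d)$distance,
      numeric(1)))[["elapsed"]]
  t_hc <- system.time(
    hc <- vapply(seq_len(nrow(tab)), function(i)
      nd_hillclimb(row_counts(tab, i), as.numeric(omega), d),
      numeric(1)))[["elapsed"]]
  ok <- is.finite(fast) & is.finite(hc)
  out <- data.frame(
    method = c("fast", "hillclimb"),
    seconds = c(t_fast, t_hc),
    mean_abs_error_vs_fast = c(0, mean(abs(hc[ok] - fast[ok]))))
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
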