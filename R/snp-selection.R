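# Differentially private top-m SNP selection and statistic release.

#' SNP count table
#'
#' A data.frame with columns `snp_id`, `r0`, `r1`, `r2`, `s0`, `s1`, `s2`
#' sharing one cohort design (attached as attribute `design`). The table is
#' the protected database: selection mechanisms see it only through the
#' per-SNP statistics and neighbor scores.
#'
#' @param df data.frame with the seven columns above.
#' @return Object of class `snp_table` (a data.frame).
#' @export
snp_table <- function(df) {
  need <- c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")
  if (!all(need %in% names(df)))
    stop("snp_table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  cells <- as.matrix(df[, -1])
  bad <- which(is.na(cells) | cells < 0 | cells != round(cells), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid genotype count in row ", bad[1, 1])
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id")
  Rs <- rowSums(cells[, 1:3, drop = FALSE])
  Ss <- rowSums(cells[, 4:6, drop = FALSE])
  if (length(unique(Rs)) != 1L || length(unique(Ss)) != 1L)
    stop("inconsistent implied cohort sizes across SNPs")
  attr(df, "design") <- cohort_design(Rs[1], Ss[1])
  class(df) <- c("snp_table", "data.frame")
  df
}

#' @export
print.snp_table <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("snp_table: %d SNPs, R = %d cases, S = %d controls\n",
              nrow(x), d$R, d$S))
  NextMethod()
}

table_design <- function(table) attr(table, "design")

row_counts <- function(table, i) {
  genotype_counts(table$r0[i], table$r1[i], table$r2[i],
                  table$s0[i], table$s1[i], table$s2[i],
                  design = table_design(table))
}

#' Allelic statistics of a whole table
#'
#' @param table a [snp_table()].
#' @param degenerate policy passed to [allelic_statistic()].
#' @return Numeric vector, one statistic per SNP.
#' @export
table_statistics <- function(table, degenerate = "zero") {
  d <- table_design(table)
  allelic_statistic(2 * table$r0 + table$r1, 2 * table$s0 + table$s1, d,
                    degenerate = degenerate)
}

#' Signed neighbor scores
#'
#' Per SNP: the neighbor distance `d` if the SNP is significant at `omega`,
#' and `1 - d` otherwise — so significant SNPs score positively, SNPs one
#' change away from significance score 0, and deeply non-significant SNPs
#' score negatively (`-Inf` when the boundary is unreachable).
#'
#' @param table a [snp_table()].
#' @param omega significance threshold (clamped [threshold()] or numeric at
#'   or above the admissible floor).
#' @param method distance method, see [neighbor_distance()].
#' @return Numeric vector of signed scores.
#' @export
neighbor_scores <- function(table, omega, method = "fast") {
  d <- table_design(table)
  omega <- as.numeric(omega)
  vapply(seq_len(nrow(table)), function(i) {
    cts <- row_counts(table, i)
    r <- neighbor_distance(cts, omega, d, method = method)
    dist <- if (is.list(r)) r$distance else r
    if (threshold_sign(cts, omega, d) > 0) dist else 1 - dist
  }, numeric(1))
}

selection_result <- function(chosen_ids, scores, omega, epsilon_spent,
                             mechanism) {
  structure(list(chosen = chosen_ids, scores = scores,
                 omega = omega, epsilon_spent = epsilon_spent,
                 mechanism = mechanism),
            class = "snp_selection")
}

#' @export
print.snp_selection <- function(x, ...) {
  cat(sprintf("%s selection (epsilon spent = %g, omega = %s):\n",
              x$mechanism, x$epsilon_spent,
              if (is.null(x$omega)) "-" else format(x$omega, digits = 4)))
  cat(" ", paste(x$chosen, collapse = ", "), "\n")
  invisible(x)
}

# Shared epsilon = Inf branch: exact top-m by score, ties sampled uniformly.
top_m_ties_random <- function(ids, score, m) {
  if (m == 0L) return(character(0))
  cut <- sort(score, decreasing = TRUE)[m]
  sure <- which(score > cut)
  tied <- which(score == cut)
  picked <- c(sure, tied[sample.int(length(tied), m - length(sure))])
  ids[picked]
}

#' Neighbor-score selection at a fixed threshold
#'
#' The exponential mechanism over signed neighbor scores: SNP weights
#' `exp(epsilon * d_i / (2 m_ret))`, drawn without replacement
#' ([weighted_select()]); epsilon-differentially private because a single
#' record moves every score by at most 1. `epsilon = Inf` returns the top
#' scores exactly (ties sampled); `epsilon = 0` is a uniform draw.
#'
#' @param table a [snp_table()].
#' @param m_ret number of SNPs to return.
#' @param epsilon privacy budget for the selection.
#' @param omega fixed significance threshold.
#' @param scores optional precomputed [neighbor_scores()] (to reuse across
#'   mechanisms in experiments).
#' @return A `snp_selection` result.
#' @export
pick_snps_neighbor <- function(table, m_ret, epsilon, omega, scores = NULL) {
  stopifnot(m_ret >= 1, m_ret <= nrow(table), epsilon >= 0)
  omega <- as.numeric(omega)
  if (is.null(scores)) scores <- neighbor_scores(table, omega)
  if (is.infinite(epsilon)) {
    chosen <- top_m_ties_random(table$snp_id, scores, m_ret)
  } else {
    lw <- if (epsilon == 0) rep(0, length(scores))
          else epsilon * scores / (2 * m_ret)
    idx <- weighted_select(lw, m_ret)
    chosen <- table$snp_id[idx]
  }
  selection_result(chosen, scores, omega, epsilon, "neighbor")
}

#' Privately estimated significance threshold
#'
#' The adaptive threshold: the mean of the `m_ret`-th and `(m_ret + 1)`-th
#' highest allelic statistics, released through the Laplace mechanism at
#' scale `DeltaY / epsilon1` (a one-record change moves each statistic, and
#' hence any order statistic and their mean, by at most `DeltaY` from
#' [allelic_sensitivity()]), then rounded up to the admissible floor
#' `2N/(2N-1)`.
#'
#' @inheritParams pick_snps_neighbor
#' @param epsilon1 budget for the threshold estimate (`Inf` = no noise).
#' @return A clamped [threshold()] with extra attribute `true_omega`.
#' @export
private_threshold <- function(table, m_ret, epsilon1) {
  stopifnot(nrow(table) >= m_ret + 1)
  d <- table_design(table)
  Y <- sort(table_statistics(table), decreasing = TRUE)
  om <- (Y[m_ret] + Y[m_ret + 1]) / 2
  om_dp <- laplace_mechanism(om, allelic_sensitivity(d), epsilon1)
  out <- threshold(om_dp, d)
  attr(out, "true_omega") <- om
  out
}

#' Adaptive neighbor selection
#'
#' The headline mechanism: spend `epsilon1` on a private threshold sitting
#' between the `m_ret`-th and `(m_ret + 1)`-th true scores, then `epsilon2`
#' on neighbor-score selection at that threshold. Total privacy
#' `epsilon1 + epsilon2`.
#'
#' @inheritParams pick_snps_neighbor
#' @param budget a [privacy_budget()], or a single number (default 0.1/0.9
#'   split).
#' @return A `snp_selection` result (reports the total budget spent and the
#'   threshold used).
#' @export
pick_snps_adaptive <- function(table, m_ret, budget) {
  if (!inherits(budget, "privacy_budget")) budget <- privacy_budget(budget)
  om_dp <- private_threshold(table, m_ret, budget$epsilon1)
  res <- pick_snps_neighbor(table, m_ret, budget$epsilon2, om_dp)
  res$mechanism <- "adaptive"
  res$omega <- as.numeric(om_dp)
  res$epsilon_spent <- budget$epsilon1 + budget$epsilon2
  res
}

#' Laplace-mechanism selection baseline
#'
#' Adds `Laplace(2 m_ret DeltaY / epsilon)` noise to each statistic
#' (standard top-k composition: budget `epsilon / m_ret` per reported SNP
#' on a statistic of sensitivity `DeltaY`) and returns the top `m_ret`
#' noisy scores.
#'
#' @inheritParams pick_snps_neighbor
#' @return A `snp_selection` result.
#' @export
pick_snps_laplace <- function(table, m_ret, epsilon) {
  stopifnot(m_ret >= 1, m_ret <= nrow(table), epsilon >= 0)
  Y <- table_statistics(table)
  if (epsilon == 0) {
    chosen <- table$snp_id[sample.int(nrow(table), m_ret)]
  } else if (is.infinite(epsilon)) {
    chosen <- top_m_ties_random(table$snp_id, Y, m_ret)
  } else {
    dY <- allelic_sensitivity(table_design(table))$value
    noisy <- Y + rlaplace(length(Y), 2 * m_ret * dY / epsilon)
    chosen <- table$snp_id[order(noisy, decreasing = TRUE)[seq_len(m_ret)]]
  }
  selection_result(chosen, Y, NULL, epsilon, "laplace")
}

#' Score-based (exponential mechanism) selection baseline
#'
#' Exponential mechanism directly on the allelic statistic: weights
#' `exp(epsilon * Y_i / (2 m_ret DeltaY))`, without replacement.
#'
#' @inheritParams pick_snps_neighbor
#' @return A `snp_selection` result.
#' @export
pick_snps_score <- function(table, m_ret, epsilon) {
  stopifnot(m_ret >= 1, m_ret <= nrow(table), epsilon >= 0)
  Y <- table_statistics(table)
  if (is.infinite(epsilon)) {
    chosen <- top_m_ties_random(table$snp_id, Y, m_ret)
  } else {
    dY <- allelic_sensitivity(table_design(table))$value
    lw <- if (epsilon == 0) rep(0, length(Y))
          else epsilon * Y / (2 * m_ret * dY)
    chosen <- table$snp_id[weighted_select(lw, m_ret)]
  }
  selection_result(chosen, Y, NULL, epsilon, "score")
}

#' Private release of allelic statistics
#'
#' Two routes, each epsilon-differentially private per SNP:
#'
#' * `"input"` — perturb the sufficient statistics: `x_dp = x + Lap(2/eps)`,
#'   `y_dp = y + Lap(2/eps)` (the pair `(x, y)` has L1 sensitivity 2, see
#'   [xy_sensitivity()]), then evaluate the statistic at the noisy pair —
#'   returning 0 whenever the noisy denominator is not positive.
#' * `"output"` — the classical baseline: `Y + Lap(DeltaY/eps)` with
#'   `DeltaY` from [allelic_sensitivity()].
#'
#' `epsilon` is the per-SNP release budget; releasing k SNPs costs
#' `k * epsilon` in total.
#'
#' @param table a [snp_table()].
#' @param epsilon per-SNP release budget (`Inf` = exact).
#' @param mode `"input"` or `"output"`.
#' @return Numeric vector of released statistics, one per SNP.
#' @export
release_allelic <- function(table, epsilon, mode = c("input", "output")) {
  mode <- match.arg(mode)
  stopifnot(epsilon > 0)
  d <- table_design(table)
  x <- 2 * table$r0 + table$r1
  y <- 2 * table$s0 + table$s1
  if (mode == "output") {
    Y <- allelic_statistic(x, y, d, degenerate = "zero")
    return(laplace_mechanism(Y, allelic_sensitivity(d), epsilon))
  }
  if (is.infinite(epsilon))
    return(allelic_statistic(x, y, d, degenerate = "zero"))
  x_dp <- x + rlaplace(length(x), 2 / epsilon)
  y_dp <- y + rlaplace(length(y), 2 / epsilon)
  ok <- (x_dp + y_dp) > 0 & (2 * d$N - x_dp - y_dp) > 0
  out <- numeric(length(x))
  out[ok] <- allelic_statistic(x_dp[ok], y_dp[ok], d, degenerate = "zero")
  out
}
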