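# Differential-privacy primitives. All randomness goes through R's global
# RNG: callers (runners, CLI, tests) own the seed, so every pipeline is
# reproducible from a single set.seed().

#' Draw from the centered Laplace distribution
#'
#' Density proportional to `exp(-|x| / scale)`. `scale = 0` is the
#' zero-noise (epsilon -> Inf) limit and returns exact zeros.
#'
#' @param n number of draws.
#' @param scale scale parameter (>= 0).
#' @return Numeric vector of length `n`.
#' @export
rlaplace <- function(n, scale) {
  stopifnot(length(scale) == 1L, is.finite(scale), scale >= 0)
  if (scale == 0) return(numeric(n))
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Laplace distribution function (test support)
#' @param q quantiles.
#' @param scale scale parameter (> 0).
#' @return Cumulative probabilities.
#' @export
plaplace <- function(q, scale) {
  ifelse(q < 0, 0.5 * exp(q / scale), 1 - 0.5 * exp(-q / scale))
}

#' The Laplace mechanism
#'
#' Releases `value + Laplace(sensitivity / epsilon)`; epsilon-differentially
#' private when `sensitivity` bounds the L1 change of the underlying
#' statistic between neighboring databases. `epsilon = Inf` returns the
#' value exactly.
#'
#' @param value numeric vector to privatise.
#' @param sensitivity L1 sensitivity bound (a positive number or a
#'   [sensitivity_bound] object).
#' @param epsilon privacy parameter (> 0, `Inf` allowed).
#' @return Noisy numeric vector of the same length.
#' @export
laplace_mechanism <- function(value, sensitivity, epsilon) {
  sens <- if (inherits(sensitivity, "sensitivity_bound")) sensitivity$value
          else sensitivity
  stopifnot(sens > 0, epsilon > 0)
  if (is.infinite(epsilon)) return(value)
  value + rlaplace(length(value), sens / epsilon)
}

#' Weighted selection without replacement
#'
#' Sequentially draws `m` distinct indices; at each draw the probability of
#' an index among the remaining ones is proportional to its weight. This is
#' the iterated exponential mechanism used by the neighbor selection
#' algorithm. Weights are supplied on the log scale so that huge score
#' gaps (large epsilon * distance) cannot overflow; `-Inf` log-weights get
#' probability zero unless every remaining weight vanishes, in which case
#' the draw degrades to uniform.
#'
#' @param log_weights numeric vector of log-weights (`-Inf` allowed).
#' @param m number of indices to draw (`<= length(log_weights)`).
#' @return Integer vector of `m` distinct indices, in draw order.
#' @export
weighted_select <- function(log_weights, m) {
  n <- length(log_weights)
  stopifnot(m >= 0, m <= n, !any(is.na(log_weights)), !any(log_weights == Inf))
  chosen <- integer(0)
  remaining <- seq_len(n)
  for (k in seq_len(m)) {
    lw <- log_weights[remaining]
    if (all(lw == -Inf)) {
      p <- rep(1, length(remaining))
    } else {
      p <- exp(lw - max(lw))
    }
    pick <- remaining[sample.int(length(remaining), 1L, prob = p)]
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  chosen
}

#' Privacy budget with threshold/selection split
#'
#' Total budget `epsilon` split into a share `epsilon1` for the private
#' threshold estimate and `epsilon2` for the SNP selection. Default split
#' 0.1/0.9.
#'
#' @param epsilon total budget (> 0, `Inf` allowed).
#' @param split length-2 positive vector summing to 1, `(threshold share,
#'   selection share)`.
#' @return Object of class `privacy_budget`: list with `epsilon`,
#'   `epsilon1`, `epsilon2`.
#' @export
privacy_budget <- function(epsilon, split = c(0.1, 0.9)) {
  stopifnot(epsilon > 0, length(split) == 2L, all(split > 0),
            abs(sum(split) - 1) < 1e-12)
  structure(list(epsilon = epsilon,
                 epsilon1 = split[1] * epsilon,
                 epsilon2 = split[2] * epsilon),
            class = "privacy_budget")
}

# cache of exhaustive sensitivity scans, keyed by "N:R:S"
.sens_cache <- new.env(parent = emptyenv())

#' Sensitivity of the allelic statistic (exhaustive scan)
#'
#' The maximum change of `Y` when one individual's genotype changes. A
#' single-record change moves `(x, y)` by `(dx, 0)` or `(0, dy)` with
#' `|dx|, |dy| in {1, 2}`, so the scan takes the exact maximum of
#' `|Y(x', y') - Y(x, y)|` over the whole integer grid
#' `[0, 2R] x [0, 2S]` and all such moves. Degenerate grid corners take
#' `Y = 0`, matching the release convention. Results are cached per
#' `(N, R, S)`.
#'
#' The bound also covers any order statistic of the per-SNP scores (hence
#' the adaptive threshold, which is a mean of two order statistics):
#' changing one record moves every per-SNP score by at most this amount.
#'
#' @param design a [cohort_design()].
#' @return Object of class `sensitivity_bound`: list with `value`,
#'   `method = "exhaustive_scan"`, and the `design` it was computed for.
#' @export
allelic_sensitivity <- function(design) {
  key <- sprintf("%d:%d:%d", design$N, design$R, design$S)
  if (!is.null(.sens_cache[[key]])) return(.sens_cache[[key]])
  R <- design$R; S <- design$S
  x <- 0:(2 * R); y <- 0:(2 * S)
  Y <- outer(x, y, function(xx, yy)
    allelic_statistic(xx, yy, design, degenerate = "zero"))
  best <- 0
  nx <- length(x); ny <- length(y)
  for (k in 1:2) {
    best <- max(best, abs(Y[seq_len(nx - k), , drop = FALSE] -
                          Y[seq_len(nx - k) + k, , drop = FALSE]))
    best <- max(best, abs(Y[, seq_len(ny - k), drop = FALSE] -
                          Y[, seq_len(ny - k) + k, drop = FALSE]))
  }
  out <- structure(list(value = best, method = "exhaustive_scan",
                        design = design),
                   class = "sensitivity_bound")
  .sens_cache[[key]] <- out
  out
}

#' Sensitivity of the allele-count pair (x, y)
#'
#' Enumerates every single-individual genotype transition (0 <-> 1 <-> 2
#' copies, in either cohort) and returns the maximum `|dx| + |dy|`. A
#' genotype with g copies of the minor allele contributes `2 - g` to the
#' projection, so the maximum is 2; the input-perturbation release
#' calibrates its Laplace noise with this bound.
#'
#' @return List with `value` (the max) and `transitions`, a data.frame of
#'   every enumerated move and its L1 displacement.
#' @export
xy_sensitivity <- function() {
  contrib <- c(`0` = 2, `1` = 1, `2` = 0)  # copies of minor allele -> x
  moves <- expand.grid(from = 0:2, to = 0:2, cohort = c("case", "control"))
  moves <- moves[moves$from != moves$to, ]
  dx <- ifelse(moves$cohort == "case",
               contrib[as.character(moves$to)] - contrib[as.character(moves$from)],
               0)
  dy <- ifelse(moves$cohort == "control",
               contrib[as.character(moves$to)] - contrib[as.character(moves$from)],
               0)
  moves$l1 <- abs(dx) + abs(dy)
  list(value = max(moves$l1), transitions = moves)
}
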