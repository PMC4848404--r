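#' dpgwas: differentially private GWAS on genotype count tables
#'
#' Case/control association scans under epsilon-differential privacy.
#' The canonical data unit is a per-SNP genotype count table
#' (r0, r1, r2, s0, s1, s2): the number of case (r) and control (s)
#' individuals carrying 0, 1 or 2 copies of the minor allele. Every
#' statistic in the package depends on the data only through these counts.
#'
#' Main entry points: [simulate_cohort()] to build a synthetic cohort,
#' [pick_snps_adaptive()] for private top-m SNP selection,
#' [neighbor_distance()] for the per-SNP neighbor distance, and
#' [release_allelic()] for private statistic release.
#'
#' @keywords internal
"_PACKAGE"

#' Cohort design constants
#'
#' A study-level container for the number of cases `R`, controls `S` and
#' total participants `N = R + S`. These are assumed public (they calibrate
#' sensitivities but are not themselves protected).
#'
#' @param R number of cases (>= 1).
#' @param S number of controls (>= 1).
#' @return An object of class `cohort_design`: list with elements `R`, `S`,
#'   `N`.
#' @examples
#' cohort_design(893, 1244)
#' @export
cohort_design <- function(R, S) {
  R <- as.integer(R); S <- as.integer(S)
  stopifnot(length(R) == 1L, length(S) == 1L, !is.na(R), !is.na(S),
            R >= 1L, S >= 1L)
  structure(list(R = R, S = S, N = R + S), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("cohort design: R = %d cases, S = %d controls, N = %d\n",
              x$R, x$S, x$N))
  invisible(x)
}

#' Per-SNP genotype count table
#'
#' Six non-negative integers: cases (`r0`, `r1`, `r2`) and controls
#' (`s0`, `s1`, `s2`) with 0/1/2 copies of the minor allele. Row sums must
#' match the owning design.
#'
#' @param r0,r1,r2 case genotype counts.
#' @param s0,s1,s2 control genotype counts.
#' @param design optional [cohort_design()]; inferred from the sums when
#'   omitted, checked against them when given.
#' @return Object of class `genotype_counts`: named integer vector of the
#'   six cells with the design attached as attribute `design`.
#' @examples
#' genotype_counts(10, 10, 10, 20, 5, 5)
#' @export
genotype_counts <- function(r0, r1, r2, s0, s1, s2, design = NULL) {
  v <- c(r0 = r0, r1 = r1, r2 = r2, s0 = s0, s1 = s1, s2 = s2)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("genotype counts must be non-negative integers")
  v <- as.integer(round(v))
  names(v) <- c("r0", "r1", "r2", "s0", "s1", "s2")
  R <- sum(v[1:3]); S <- sum(v[4:6])
  if (is.null(design)) {
    design <- cohort_design(R, S)
  } else if (design$R != R || design$S != S) {
    stop(sprintf("counts sum to (R=%d, S=%d) but design says (R=%d, S=%d)",
                 R, S, design$R, design$S))
  }
  structure(v, design = design, class = "genotype_counts")
}

design_of <- function(counts) attr(counts, "design")

#' Allele-count projection (x, y)
#'
#' The allelic statistic depends on the genotype table only through
#' `x = 2*r0 + r1` and `y = 2*s0 + s1`. This projects a count table down to
#' that pair.
#'
#' @param counts a [genotype_counts()] object (or plain named vector with
#'   the six cells).
#' @return Named numeric vector `c(x, y)`.
#' @examples
#' allele_counts(genotype_counts(10, 10, 10, 20, 5, 5))  # x = 30, y = 45
#' @export
allele_counts <- function(counts) {
  c(x = unname(2 * counts[["r0"]] + counts[["r1"]]),
    y = unname(2 * counts[["s0"]] + counts[["s1"]]))
}

#' Allelic test statistic
#'
#' The 1-df chi-square statistic of the 2x2 allele-by-status table,
#' `Y(x, y) = 2N (xS - yR)^2 / (RS (x+y) (2N - x - y))`. Vectorised over
#' `x` and `y`.
#'
#' The denominator vanishes for monomorphic SNPs (`x + y` equal to 0 or
#' `2N`). Callers choose the policy: `degenerate = "error"` (default)
#' raises; `"zero"` maps such SNPs to `Y = 0`, the convention used by the
#' private release path and by the significance-sign function.
#'
#' @param x,y allele-count projections (real-valued allowed: the relaxed
#'   solver and the input-perturbation release evaluate Y off the integer
#'   grid).
#' @param design a [cohort_design()].
#' @param degenerate one of `"error"`, `"zero"`.
#' @return Numeric vector of statistics.
#' @examples
#' d <- cohort_design(30, 30)
#' allelic_statistic(30, 45, d)  # 8
#' @export
allelic_statistic <- function(x, y, design, degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  R <- design$R; S <- design$S; N <- design$N
  den <- R * S * (x + y) * (2 * N - x - y)
  bad <- !(den > 0)
  if (any(bad)) {
    if (degenerate == "error")
      stop("degenerate allelic denominator: x + y in {0, 2N} (monomorphic SNP)")
  }
  out <- numeric(length(den))
  ok <- !bad
  out[ok] <- 2 * N * (x[ok] * S - y[ok] * R)^2 / den[ok]
  out[bad] <- 0
  out
}

#' Pearson chi-square of the 2x2 allele table (test oracle)
#'
#' Classical Pearson statistic of the table `[[x, 2R-x], [y, 2S-y]]`,
#' computed from the generic contingency-table formula
#' `n (ad - bc)^2 / (row1 row2 col1 col2)`. Kept as an independent route to
#' the same quantity as [allelic_statistic()]; used in tests only.
#'
#' @inheritParams allelic_statistic
#' @return Numeric vector.
#' @export
pearson_2x2 <- function(x, y, design) {
  a <- x; b <- 2 * design$R - x
  c_ <- y; d <- 2 * design$S - y
  n <- a + b + c_ + d
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (any(!(den > 0)))
    stop("degenerate 2x2 table (zero marginal)")
  n * (a * d - b * c_)^2 / den
}

#' Smallest admissible significance threshold
#'
#' The fast neighbor-distance algorithm requires `omega >= 2N/(2N-1)`; any
#' private threshold estimate below that floor is rounded up to it. The
#' floor is harmless in practice: the corresponding 1-df chi-square p-value
#' exceeds 0.05 for every usable N.
#'
#' @param design a [cohort_design()].
#' @return The scalar `2N / (2N - 1)`.
#' @export
min_admissible_threshold <- function(design) {
  2 * design$N / (2 * design$N - 1)
}

#' Significance threshold with admissibility clamp
#'
#' Wraps a raw threshold value, clamping it up to
#' [min_admissible_threshold()] for the design.
#'
#' @param omega raw threshold value.
#' @param design a [cohort_design()].
#' @return Object of class `dp_threshold`: numeric scalar with attributes
#'   `raw` (pre-clamp value) and `clamped` (logical).
#' @export
threshold <- function(omega, design) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega))
  floor_ <- min_admissible_threshold(design)
  structure(max(omega, floor_), raw = omega, clamped = omega < floor_,
            class = "dp_threshold")
}

#' Threshold from a p-value
#'
#' Converts a 1-df chi-square upper-tail p-value to the corresponding
#' statistic cutoff; `bonferroni_threshold()` applies the family-wise
#' correction `alpha / n_tests` first (the fixed-cutoff variant of the
#' selection mechanism).
#'
#' @param p upper-tail p-value in (0, 1).
#' @return Statistic cutoff (numeric scalar).
#' @export
threshold_from_pvalue <- function(p) {
  stopifnot(p > 0, p < 1)
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' @rdname threshold_from_pvalue
#' @param alpha family-wise error rate.
#' @param n_tests number of SNPs tested.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  threshold_from_pvalue(alpha / n_tests)
}

#' Utility of a private SNP selection
#'
#' `|A intersect B| / |A|`, where `A` is the true top-m SNP-id set and `B`
#' the ids returned by a private mechanism.
#'
#' @param A character/integer vector of true top SNP ids (non-empty).
#' @param B ids returned by the mechanism.
#' @return Fraction in `[0, 1]`.
#' @examples
#' utility_overlap(c("a", "b", "c"), c("b", "c", "z"))  # 2/3
#' @export
utility_overlap <- function(A, B) {
  if (length(A) == 0L) stop("reference set A must be non-empty")
  length(intersect(A, B)) / length(A)
}
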