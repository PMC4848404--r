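# Synthetic case/control cohort generator. Genotypes are drawn per SNP from
# Hardy-Weinberg proportions at a cohort-specific minor-allele frequency;
# associated SNPs use different case and control frequencies. This emulates
# the count-table structure of a real GWAS cohort (it does not model LD,
# population structure or genotyping error; see the methods vignette).

#' Specification of a synthetic cohort
#'
#' Defaults state the desk-scale evaluation world used throughout the
#' package: 500 SNPs, 500 cases and 500 controls, 3 truly associated SNPs
#' with case/control minor-allele frequencies 0.4 / 0.2 (a strong,
#' genome-wide-detectable effect at this sample size), null SNPs with MAF
#' uniform on [0.05, 0.5] (matching the standard MAF >= 0.05 input filter).
#'
#' @param n_snps number of SNPs.
#' @param R,S number of cases / controls.
#' @param n_associated number of truly associated SNPs (placed first in the
#'   table, ids flagged in attribute `associated`).
#' @param maf_range range of the common case/control MAF for null SNPs.
#' @param case_freq,control_freq minor-allele frequencies of associated
#'   SNPs in cases / controls (recycled to `n_associated`).
#' @return Object of class `simulation_spec` (a list of the above).
#' @export
simulation_spec <- function(n_snps = 500, R = 500, S = 500, n_associated = 3,
                            maf_range = c(0.05, 0.5),
                            case_freq = 0.4, control_freq = 0.2) {
  stopifnot(n_associated <= n_snps, n_snps >= 1,
            all(maf_range > 0), all(maf_range <= 0.5),
            maf_range[1] <= maf_range[2],
            all(case_freq > 0), all(case_freq <= 0.5),
            all(control_freq > 0), all(control_freq <= 0.5))
  structure(list(n_snps = as.integer(n_snps), R = as.integer(R),
                 S = as.integer(S), n_associated = as.integer(n_associated),
                 maf_range = maf_range,
                 case_freq = rep_len(case_freq, n_associated),
                 control_freq = rep_len(control_freq, n_associated)),
            class = "simulation_spec")
}

# Hardy-Weinberg class probabilities indexed by copies of the minor allele.
hwe_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

#' Simulate a case/control cohort as a SNP count table
#'
#' For each SNP, case genotype counts are one trinomial draw of size `R`
#' from Hardy-Weinberg proportions at the case allele frequency, and
#' likewise for controls. Uses the current RNG state: call `set.seed()`
#' first for reproducibility.
#'
#' @param spec a [simulation_spec()].
#' @return A [snp_table()] with attribute `associated` (the associated SNP
#'   ids) and `maf` (the generating null/case frequencies).
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_snps
  p_case <- p_ctrl <- stats::runif(n, spec$maf_range[1], spec$maf_range[2])
  if (spec$n_associated > 0) {
    idx <- seq_len(spec$n_associated)
    p_case[idx] <- spec$case_freq
    p_ctrl[idx] <- spec$control_freq
  }
  cases <- vapply(p_case, function(p) stats::rmultinom(1, spec$R, hwe_probs(p))[, 1],
                  integer(3))
  ctrls <- vapply(p_ctrl, function(p) stats::rmultinom(1, spec$S, hwe_probs(p))[, 1],
                  integer(3))
  ids <- sprintf("snp_%04d", seq_len(n))
  tab <- snp_table(data.frame(
    snp_id = ids,
    r0 = cases[1, ], r1 = cases[2, ], r2 = cases[3, ],
    s0 = ctrls[1, ], s1 = ctrls[2, ], s2 = ctrls[3, ],
    stringsAsFactors = FALSE))
  attr(tab, "associated") <- ids[seq_len(spec$n_associated)]
  attr(tab, "maf") <- p_case
  tab
}
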