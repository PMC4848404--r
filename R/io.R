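# File I/O and preprocessing: the TSV count-table interchange format, VCF +
# phenotype ingestion, and the minor-allele-frequency filter.

COUNTS_HEADER <- c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")

#' Read / write SNP count tables as TSV
#'
#' The interchange format is a tab-separated file with the exact header
#' `snp_id r0 r1 r2 s0 s1 s2`. Reading validates cells and the constancy of
#' the implied cohort sizes; writing is the exact inverse.
#'
#' @param path file path.
#' @return [read_counts_tsv()] returns a [snp_table()];
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), COUNTS_HEADER))
    stop("bad counts header; expected: ", paste(COUNTS_HEADER, collapse = "\t"))
  snp_table(df)
}

#' @rdname read_counts_tsv
#' @param table a [snp_table()].
#' @export
write_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "snp_table"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Genotype counts from a VCF and a phenotype file
#'
#' Tallies biallelic SNPs from the GT field into per-SNP case/control count
#' tables. The minor allele is determined on the combined cohort; records
#' with any missing call are dropped (the statistic requires every
#' individual called), and non-biallelic records are skipped with a
#' message. Requires the VariantAnnotation package.
#'
#' @param vcf_path path to a VCF 4.x file (uncompressed or bgzipped).
#' @param phenotype_path two-column TSV `sample_id`, `status` with status
#'   in `{case, control}`, covering every VCF sample.
#' @return A [snp_table()].
#' @export
vcf_to_counts <- function(vcf_path, phenotype_path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("vcf_to_counts requires the VariantAnnotation package")
  ph <- utils::read.delim(phenotype_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(ph)))
    stop("phenotype file needs columns sample_id, status")
  if (!all(ph$status %in% c("case", "control")))
    stop("phenotype status must be 'case' or 'control'")
  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  samples <- colnames(gt)
  missing_ph <- setdiff(samples, ph$sample_id)
  if (length(missing_ph))
    stop("samples absent from phenotype file: ",
         paste(missing_ph, collapse = ", "))
  status <- ph$status[match(samples, ph$sample_id)]
  # alt-allele dosage per call; NA for missing
  dose <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(g %in% c("0/0"), 0L,
           ifelse(g %in% c("0/1", "1/0"), 1L,
                  ifelse(g %in% c("1/1"), 2L, NA_integer_)))
  }
  n_alt <- lengths(VariantAnnotation::alt(vcf))
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    if (n_alt[i] != 1L) {
      message("skipping non-biallelic record ", rownames(gt)[i])
      next
    }
    dg <- dose(gt[i, ])
    if (anyNA(dg)) next  # missing call: drop the SNP
    # orient to the minor allele on the combined cohort
    if (sum(dg) > length(dg)) dg <- 2L - dg
    rows[[length(rows) + 1L]] <- c(
      list(snp_id = rownames(gt)[i]),
      as.list(c(
        r0 = sum(dg == 0 & status == "case"),
        r1 = sum(dg == 1 & status == "case"),
        r2 = sum(dg == 2 & status == "case"),
        s0 = sum(dg == 0 & status == "control"),
        s1 = sum(dg == 1 & status == "control"),
        s2 = sum(dg == 2 & status == "control"))))
  }
  if (!length(rows)) stop("no usable biallelic, fully called SNPs in VCF")
  snp_table(do.call(rbind.data.frame, rows))
}

#' Minor-allele-frequency filter
#'
#' Keeps SNPs whose combined-cohort minor allele frequency is at least
#' `thresh` (the standard preprocessing step; monomorphic SNPs — whose
#' statistic is degenerate — are removed by any positive threshold).
#'
#' @param table a [snp_table()].
#' @param thresh MAF cutoff in `[0, 0.5]`; boundary SNPs are kept.
#' @return Filtered [snp_table()].
#' @export
filter_maf <- function(table, thresh = 0.05) {
  stopifnot(thresh >= 0, thresh <= 0.5)
  d <- table_design(table)
  a <- 2 * (table$r2 + table$s2) + table$r1 + table$s1  # minor-allele count
  maf <- pmin(a, 2 * d$N - a) / (2 * d$N)
  out <- table[maf >= thresh, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- d
  class(out) <- class(table)
  out
}
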