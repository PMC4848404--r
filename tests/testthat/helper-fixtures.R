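# Shared fixtures: all synthetic, built in code.

# Random small genotype-count instance, biased toward edge compositions
# (empty het cells, single-cell cohorts) that stress the rounding rules.
rand_counts <- function(max_n = 25) {
  R <- sample(seq_len(max_n), 1)
  S <- sample(seq_len(max_n), 1)
  draw <- function(Tn) {
    mode <- sample(3, 1)
    if (mode == 1) {            # whole cohort in one genotype class
      v <- c(0L, 0L, 0L); v[sample(3, 1)] <- Tn; v
    } else if (mode == 2) {     # one empty cell (often the het cell)
      v <- as.vector(stats::rmultinom(1, Tn, stats::runif(3) + 0.02))
      i <- sample(2:3, 1); v[1] <- v[1] + v[i]; v[i] <- 0L; v
    } else {
      as.vector(stats::rmultinom(1, Tn, stats::runif(3) + 0.02))
    }
  }
  r <- draw(R); s <- draw(S)
  genotype_counts(r[1], r[2], r[3], s[1], s[2], s[3])
}

# Random admissible threshold spanning the attainable statistic range
# (up to slightly above Y_max = 2N, to exercise unreachable boundaries).
rand_omega <- function(design) {
  stats::runif(1, min_admissible_threshold(design), 2 * design$N * 1.05)
}

# Counts row realising a given allele-count projection (x, y).
counts_from_xy <- function(x, y, design) {
  r1 <- x %% 2; r0 <- (x - r1) / 2; r2 <- design$R - r0 - r1
  s1 <- y %% 2; s0 <- (y - s1) / 2; s2 <- design$S - s0 - s1
  genotype_counts(r0, r1, r2, s0, s1, s2, design)
}

# Small deterministic table for selection tests.
toy_table <- function() {
  d <- cohort_design(20, 20)
  # no mirrored (x, y)/(y, x) pairs: those tie exactly when R = S
  xy <- rbind(c(38, 6), c(34, 10), c(28, 14), c(24, 16), c(20, 19),
              c(14, 22), c(12, 25))
  rows <- lapply(seq_len(nrow(xy)), function(i) {
    cts <- counts_from_xy(xy[i, 1], xy[i, 2], d)
    c(list(snp_id = sprintf("s%d", i)), as.list(as.integer(cts)))
  })
  df <- do.call(rbind.data.frame, rows)
  names(df) <- c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")
  snp_table(df)
}

# Cohort engineered so that ranks 12-18 have nearly tied statistics but
# heterogeneous minor-allele frequencies: the fixed-threshold neighbor
# method then ranks them differently from the statistic, while an adaptive
# threshold sits in the rank-15/16 gap.
tied_rank_table <- function() {
  R <- 200; S <- 200
  d <- cohort_design(R, S)
  find_xy <- function(targetY, asum) {
    xs <- max(0, asum - 2 * S):min(2 * R, asum)
    Ys <- allelic_statistic(xs, asum - xs, d, degenerate = "zero")
    i <- which.min(abs(Ys - targetY) + ifelse(xs < asum - xs, 1e6, 0))
    c(xs[i], asum - xs[i])
  }
  specs <- rbind(
    cbind(60 + 5 * (1:11), 380),                 # 11 strong SNPs
    cbind(c(30, 28, 27, 26, 25, 24.5, 24),       # near-tied group,
          c(120, 200, 280, 360, 440, 520, 600)), # spread allele sums
    cbind(stats::runif(42, 0.1, 6), round(stats::runif(42, 150, 650))))
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    xy <- find_xy(specs[i, 1], specs[i, 2])
    cts <- counts_from_xy(xy[1], xy[2], d)
    c(list(snp_id = sprintf("snp%02d", i)), as.list(as.integer(cts)))
  })
  df <- do.call(rbind.data.frame, rows)
  names(df) <- c("snp_id", "r0", "r1", "r2", "s0", "s1", "s2")
  snp_table(df)
}

# Tiny VCF + phenotype fixture written to a temp dir; 3 samples
# (1 case, 2 controls). rs2 has a missing call, rs3 is multi-allelic,
# rs4 is the allele-swap of rs1.
write_vcf_fixture <- function(dir = tempdir()) {
  vcf <- file.path(dir, "toy.vcf")
  ph <- file.path(dir, "pheno.tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT",
          "./.", "0/1", "1/1", sep = "\t"),
    paste("1", "300", "rs3", "A", "G,T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "400", "rs4", "A", "G", ".", "PASS", ".", "GT",
          "1/1", "1/0", "0/0", sep = "\t")), vcf)
  writeLines(c("sample_id\tstatus", "A\tcase", "B\tcontrol", "C\tcontrol"),
             ph)
  list(vcf = vcf, phenotype = ph)
}
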