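Package: dpgwas
Title: Differentially Private Selection and Release of GWAS Allelic Test
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running case/control genome-wide association scans
    under epsilon-differential privacy. Implements the allelic (2x2) test
    statistic on per-SNP genotype count tables, an exact constant-work
    neighbor-distance algorithm based on a convex relaxation of the
    minimum-individuals-to-flip-significance integer program, exponential
    mechanism top-m SNP selection with an adaptively chosen significance
    threshold, Laplace-mechanism baselines, and input-perturbation release
    of allelic statistics. Includes a Hardy-Weinberg case/control cohort
    simulator, TSV/VCF ingestion, brute-force oracles for every private
    primitive, and experiment runners for utility and error benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
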