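---
title: "Private GWAS with dpgwas: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private GWAS with dpgwas: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpgwas)
```

## 1. The statistical model

A case/control association scan reduces, per SNP, to a genotype count
table `(r0, r1, r2, s0, s1, s2)`: cases and controls with 0, 1 or 2 copies
of the minor allele, with fixed cohort sizes `R` and `S` (`N = R + S`). The
allelic test statistic is the 1-df Pearson chi-square of the 2×2
allele-by-status table, and depends on the table only through the
projections `x = 2 r0 + r1`, `y = 2 s0 + s1`:

$$Y(x, y) = \frac{2N (xS - yR)^2}{RS\,(x+y)\,(2N - x - y)}.$$

`allelic_statistic()` implements this directly; the test suite checks it to
`1e-9` relative accuracy against `pearson_2x2()`, an independent evaluation
of the generic contingency-table formula. Monomorphic SNPs make the
denominator vanish; the package raises a typed error by default and lets
each caller pick its policy: the release path and the significance sign
define `Y := 0` there, and the MAF filter removes such SNPs upstream.

Two symmetries pin the conventions down: `Y(x, y; R, S) = Y(y, x; S, R)`
(cases and controls are exchangeable labels) and
`Y(x, y) = Y(2R - x, 2S - y)` (relabeling which allele is "minor"). Both
are property-tested; because of the first, nothing in the package depends
on which cohort letter a data source calls "cases".

## 2. Differential privacy primitives

A mechanism `F` is ε-differentially private if its output distribution
changes by at most a factor `e^ε` when one individual's record changes.
The package uses:

* the **Laplace mechanism** `f(D) + Lap(Δf/ε)`, with `Δf` an L1
  sensitivity bound;
* the **exponential mechanism**, realised as sequential weighted sampling
  without replacement (`weighted_select()`), with weights supplied on the
  log scale so large `ε × score` products cannot overflow.

Sensitivities are obtained two ways:

* `xy_sensitivity()` — the pair `(x, y)` moves by at most 2 under any
  single genotype change (dosage contributions are `{2, 1, 0}`); verified
  by enumerating all twelve transitions.
* `allelic_sensitivity()` — the statistic's sensitivity `ΔY` is computed by
  an exhaustive scan: the exact maximum of `|Y(x', y') - Y(x, y)|` over the
  whole integer grid `[0, 2R] × [0, 2S]` and all single-record moves
  (`|Δx| ∈ {1, 2}` or `|Δy| ∈ {1, 2}`). A closed form for this bound is not
  restated in the accessible literature, so the scan *defines* the
  package's bound; it is an O(RS) one-time cost per design (0.15 s at
  R = S = 500) and is cached. The scan treats the two degenerate corners as
  `Y = 0`, matching the release convention. Because one record moves every
  per-SNP statistic by at most `ΔY`, the same bound covers any order
  statistic of the scores and in particular the adaptive threshold (a mean
  of two order statistics).

## 3. Neighbor distance

The neighbor distance of a SNP at threshold `ω` is the minimum number of
individuals whose genotypes must change to flip the SNP across `ω` — an
integer program over count tables with fixed cohort sizes. Since the
objective separates over the two cohorts and the constraint depends only on
`(x, y)`, the program projects to the allele-count plane.

### 3.1 Relaxation

Per axis, the relaxed cost of moving the projection from `x0 = 2 r0 + r1`
to `x` is continuous piecewise linear (`relaxed_cost()`): slope 1/2 while
"2-unit" movers remain (homozygotes that can be re-assigned to the other
homozygote class), slope 1 beyond. Written out for the case axis:

* `(x - x0)/2` on `[x0, 2R - r1]`, then `r2 + x - 2(r0 + r2) - r1`
  (slope 1) up to `2R`;
* `(x0 - x)/2` on `[r1, x0]`, then `r0 + r1 - x` (slope 1) down to 0.

One transcription note: a printed form of the third piece can be misread
with a trailing "/2" (making it collinear with the first piece, i.e. a
breakpoint with no slope change). The slope-1 reading is the one that is
consistent — it makes the ceiling of the relaxed cost at integer points
equal the exact reassignment minimum — and it is what the package
implements; the per-axis enumeration oracle in the test suite confirms it.

The integer per-axis cost (`integer_cost()`) has the closed form
`ceil(d/2)` for offsets `|d| ≤ 2·cap` (cap = the relevant homozygote
count), and `cap + (|d| - 2 cap)` beyond. Published pseudocode instead uses
`β = ceil(g) + 1` when the het cell is empty and the offset odd. That
correction over-counts: an odd offset is achievable at cost `ceil(d/2)` by
re-assigning one homozygote to the het class (e.g. `(r0,r1,r2) = (3,0,0)`,
`x' = 5` costs 1, not 2). The exhaustive oracle governs, so the exact
closed form is the default and the printed rule is kept behind
`paper_mode = TRUE` for comparison.

### 3.2 Solving the relaxation

The constraint boundary `Y = ω` is the conic
`C: 2N(xS - yR)² = RSω(x+y)(2N - x - y)`. For an infeasible current point,
the relaxed minimum lies on `C ∩ [0,2R]×[0,2S]`, at one of:

* **tangency points** (`conic_tangency_candidates()`): where `dy/dx` of `C`
  equals a ratio of per-axis slopes. The per-axis slopes take both signs,
  so the full set `{±1, ±2, ±1/2}` is used (a printed slope set mentions
  only the positive half; extra candidates can only tighten the bound, so
  the symmetric set is used from the start). Each slope gives a *line*
  `h_x + s·h_y = 0`, and line ∩ conic is a quadratic solve.
* **breakpoint points** (`breakpoint_candidates()`): `x` fixed at a case
  cost breakpoint `{0, r1, 2r0+r1, 2R-r1, 2R}` (or the `y` analogues),
  again a quadratic solve.

One subtlety found by randomized testing: the degenerate corners `(0, 0)`
and `(2R, 2S)` always satisfy the conic *equation* (both sides vanish) but
carry `Y := 0`, not `ω`, and are isolated points of `C` inside the box.
For a significant SNP they are genuine feasible destinations and are kept;
for a non-significant SNP (which must *raise* `Y` to `ω`) they are not on
the true boundary, and keeping them can collapse the bound (an all-minor /
all-minor instance produced relaxed bound 0 against a true distance of 20).
`relaxed_minimum()` therefore keeps, on that side, only candidates that
actually attain `Y = ω` (relative tolerance `1e-4`).

`ĝ = ceil(min g over candidates)` is then a certified lower bound on the
distance (property-tested against the oracle; also checked against a dense
`1e-3`-step scan of the whole boundary on small designs).

### 3.3 Rounding

The integer optimum is found by scanning total costs
`δ = ĝ, ĝ+1, …` and asking whether some integer `(x, y)` on the required
side has per-axis costs summing to exactly `δ`
(`integer_feasible_exists()`). Level sets of the closed-form cost contain
at most four projections per axis and value, so each check touches O(δ)
candidate pairs and the first feasible `δ` is provably the minimum —
giving an exact algorithm regardless of how far the relaxation is from the
integer optimum. In practice the gap never exceeded 5 (the published
window) on any of the 5000-instance acceptance runs; the implementation
does not rely on that, but warns if it ever scans past `ĝ + 5`.
Published pseudocode also returns `ĝ` directly (no rounding search) for
non-significant SNPs; whether that is always exact is unproven here, so the
default runs the same δ-search on both sides and `paper_mode = TRUE`
reproduces the printed early return.

Conventions: `Y = ω` counts as *not significant* (selection uses strict
`>`), while the crossing constraint accepts landing exactly on `ω`. In the
measure-zero case `Y(ρ) = ω` exactly, both the oracle and the fast path
return distance 0; random thresholds never hit it.

### 3.4 Oracles and baseline

`neighbor_distance(..., method = "oracle")` enumerates all per-axis
reassignments (`axis_cost_enum`) and the full `(x, y)` grid — exact by
construction, guarded to `R + S ≤ 200`, and the governing reference: the
fast path is required to match it on every tested instance (5000 randomized
instances with `R, S ≤ 25`, edge compositions included, zero mismatches).
`method = "hillclimb"` is the greedy single-individual baseline of earlier
approximate implementations; it upper-bounds the distance and its per-SNP
error is reported by `run_distance_benchmark()`.

## 4. Private selection

`neighbor_scores()` maps each SNP to `d` (significant) or `1 - d`
(non-significant), so a SNP one change short of significance scores 0.
Changing one record moves each score by at most 1, so the exponential
mechanism with weights `exp(ε d_i / (2 m_ret))`, iterated without
replacement `m_ret` times, is ε-differentially private.

`pick_snps_adaptive()` first buys a threshold with `ε₁`: the midpoint of
the `m_ret`-th and `(m_ret+1)`-st order statistics plus `Lap(ΔY/ε₁)` noise,
clamped up to the admissible floor `2N/(2N-1)` (below which the conic
candidates degenerate; the floor corresponds to p ≈ 0.3 at N = 6 and → 0.32
as N grows, so it never excludes a meaningful cutoff — verified for all
N ≤ 10⁴). The default split `ε₁ = 0.1ε, ε₂ = 0.9ε` follows stated practice
and is exposed as a parameter because the trade-off is acknowledged to be
unexplored. If the noisy threshold exceeds the attainable maximum
statistic `2N`, non-significant SNPs get score `-∞` and weight 0; if every
weight vanishes the draw degrades to uniform (the continuous limit of the
weights).

Baselines follow the standard top-k composition (per-pick budget
`ε/m_ret`): `pick_snps_laplace()` adds `Lap(2 m_ret ΔY / ε)` to each
statistic and takes the top `m_ret`; `pick_snps_score()` runs the
exponential mechanism with weights `exp(ε Y_i / (2 m_ret ΔY))`. At
`ε = ∞` every picker returns the exact top set with ties sampled
uniformly; at `ε = 0` selection is uniform.

One convention was open: the printed non-significant score is `1 - d`
rather than `-d`; the package implements `1 - d` as printed (the choice
shifts all non-significant log-weights by the constant `ε/(2 m_ret)` and
does not change their relative odds).

## 5. Statistic release

`release_allelic(mode = "input")` noises the sufficient statistics
(`Lap(2/ε)` each, joint L1 sensitivity 2) and evaluates `Y` at the noisy
pair, returning 0 when the noisy denominator is not positive.
`mode = "output"` is the classical `Y + Lap(ΔY/ε)`. Because `ΔY` is large
(≈ 8 at R = S = 500) while `Y` is smooth in `(x, y)` away from the
degenerate corners, input perturbation is far more accurate on the top
SNPs; the acceptance suite verifies the strict ordering at
`ε ∈ {0.25, 0.5, 1, 2}` over 1000 replicates. `ε` is a per-SNP budget;
releasing k SNPs costs `k·ε` (the CLI logs the multiplied total), since no
composition rule across released SNPs is prescribed by the method itself.

## 6. The synthetic world

`simulate_cohort()` draws, per SNP, trinomial genotype counts from
Hardy–Weinberg proportions at a cohort-specific minor-allele frequency.
Defaults state the evaluation world used throughout: 500 SNPs, 500 cases /
500 controls, 3 associated SNPs with case/control frequencies 0.4 / 0.2,
null MAF uniform on [0.05, 0.5]. The effect size is deliberately strong
(Y ≈ 60–200 against a null background of ≈ 1–12): it emulates the
well-separated hits of a real scan at desk scale, where the reference
evaluations used a cohort of ~2100 samples and 62k SNPs. The generator
draws each SNP independently: no linkage disequilibrium, population
structure, genotyping error or missingness. A green utility test therefore
establishes the mechanisms' behaviour on clean, independent, HWE-consistent
tables — not robustness to confounding, and not absolute utilities on any
real cohort.

The near-tie experiment (`tied_rank_table()` in the test helpers)
constructs count rows directly: 11 strong SNPs, then 7 SNPs with nearly
tied statistics but very different allele totals, so that distance-to-a-
fixed-cutoff ranks them differently from the statistic. This reproduces,
qualitatively, the known failure mode of the fixed-threshold neighbor
method (utility plateau at large ε) and the adaptive threshold's fix.

## 7. Numerical choices

* Conic coefficients are normalised by their max modulus; candidate
  membership is asserted at `1e-8` relative residual; quadratic
  discriminants within `1e-10` (relative) of zero are clamped to zero;
  roots within `1e-7` (relative) of the box are clamped inside.
* `ĝ` uses `ceiling(min_g - 1e-9)` so a float sitting just above an
  integer rounds down to it.
* Integer feasibility compares `Y` directly (same arithmetic as the oracle
  predicate), not the conic polynomial, so the fast path and the oracle
  cannot disagree by floating-point sign flips near the boundary.
* Derived experiment seeds are kept below 2³¹.

## 8. Known limitations

* Pure ε-DP only; no (ε, δ) accounting, no Gaussian mechanism.
* The sensitivity scan is O(RS); fine to N ≈ 5000, a coarse-to-fine scan
  would be needed far beyond that and is not implemented.
* The exhaustive distance oracle is guarded to `R + S ≤ 200`; above that
  only the fast path (validated at small scale) is available.
* The hill-climbing baseline may fail to terminate on plateaus; it returns
  `Inf` after `4N` steps or when no single move improves.
* VCF ingestion handles diploid biallelic GT calls only; no strand
  flipping, no dosage/imputation formats.
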