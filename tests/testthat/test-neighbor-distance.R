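# The distance machinery is validated oracle-first: exhaustive enumeration
# of genotype reassignments defines every expected value.

test_that("relaxed per-axis cost matches the piecewise form", {
  cts <- genotype_counts(3, 0, 0, 0, 0, 3)  # x = 6, y = 0
  expect_equal(relaxed_cost(6, cts, "case"), 0)
  expect_equal(relaxed_cost(4, cts, "case"), 1)
  expect_equal(relaxed_cost(5, cts, "case"), 0.5)
  expect_equal(relaxed_cost(0, cts, "control"), 0)
  expect_equal(relaxed_cost(6, cts, "control"), 3)  # all controls 2 -> 0

  # continuity across every breakpoint, random compositions
  set.seed(21)
  for (k in 1:50) {
    cts <- rand_counts()
    r <- cts[c("r0", "r1", "r2")]
    R <- sum(r)
    bp <- c(r[["r1"]], 2 * r[["r0"]] + r[["r1"]], 2 * R - r[["r1"]])
    for (b in bp) {
      eps <- min(1e-7, b, 2 * R - b)
      lo <- relaxed_cost(max(b - eps, 0), cts, "case")
      hi <- relaxed_cost(min(b + eps, 2 * R), cts, "case")
      expect_lt(abs(lo - hi), 1e-5)
    }
  }
})

test_that("integer per-axis cost equals the exhaustive reassignment minimum", {
  set.seed(22)
  for (k in 1:60) {
    cts <- rand_counts(15)
    r <- cts[c("r0", "r1", "r2")]
    enum <- dpgwas:::axis_cost_enum(r[["r0"]], r[["r1"]], r[["r2"]])
    xs <- 0:(2 * sum(r))
    expect_identical(integer_cost(xs, cts, "case"), as.integer(enum))
    # exact cost = ceiling of the relaxed cost at integers
    expect_identical(integer_cost(xs, cts, "case"),
                     as.integer(ceiling(relaxed_cost(xs, cts, "case"))))
  }
})

test_that("printed rounding rule over-counts odd offsets with empty het cell", {
  cts <- genotype_counts(3, 0, 0, 0, 0, 3)
  # (r0,r1,r2) = (3,0,0), x' = 5: one 0->1 reassignment suffices
  expect_equal(integer_cost(5, cts, "case"), 1)
  expect_equal(integer_cost(5, cts, "case", paper_mode = TRUE), 2)
  # with a het cell present the two agree
  cts2 <- genotype_counts(2, 1, 0, 0, 0, 3)
  expect_equal(integer_cost(3, cts2, "case"),
               integer_cost(3, cts2, "case", paper_mode = TRUE))
})

test_that("boundary candidates lie on the conic, in the box, symmetrically", {
  set.seed(23)
  for (k in 1:25) {
    cts <- rand_counts()
    d <- attr(cts, "design")
    om <- rand_omega(d)
    cc <- dpgwas:::conic_coeffs(om, d)
    pts <- rbind(conic_tangency_candidates(om, d),
                 breakpoint_candidates(cts, om, d))
    if (nrow(pts) == 0) next
    expect_true(all(abs(dpgwas:::conic_residual(cc, pts[, 1], pts[, 2])) < 1e-8))
    expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 2 * d$R))
    expect_true(all(pts[, 2] >= 0 & pts[, 2] <= 2 * d$S))
  }

  # R = S: the tangency set is symmetric under (x, y) -> (y, x)
  d <- cohort_design(12, 12)
  pts <- conic_tangency_candidates(3, d)
  for (i in seq_len(nrow(pts))) {
    mirror_gap <- min(abs(pts[i, 1] - pts[, 2]) + abs(pts[i, 2] - pts[, 1]))
    expect_lt(mirror_gap, 1e-6)
  }
})

test_that("candidate set attains the boundary minimum of the relaxed cost", {
  # dense scan of the whole boundary as oracle, small design
  d <- cohort_design(10, 10)
  om <- 3
  cc <- dpgwas:::conic_coeffs(om, d)
  set.seed(24)
  for (k in 1:10) {
    r <- as.vector(rmultinom(1, d$R, runif(3) + 0.05))
    s <- as.vector(rmultinom(1, d$S, runif(3) + 0.05))
    cts <- genotype_counts(r[1], r[2], r[3], s[1], s[2], s[3])
    xg <- seq(0, 2 * d$R, by = 1e-3)
    ys <- vapply(xg, function(v) {
      roots <- dpgwas:::quad_roots(cc[["c"]], cc[["b"]] * v + cc[["e"]],
                                   cc[["a"]] * v^2 + cc[["d"]] * v)
      roots <- roots[roots >= 0 & roots <= 2 * d$S]
      if (!length(roots)) return(c(NA_real_, NA_real_))
      c(roots, NA_real_)[1:2]
    }, numeric(2))
    on_c <- cbind(rep(xg, 2), c(ys[1, ], ys[2, ]))
    on_c <- on_c[!is.na(on_c[, 2]), , drop = FALSE]
    # drop the degenerate corners, which satisfy the conic equation but do
    # not attain Y = omega (same convention as relaxed_minimum)
    tot <- on_c[, 1] + on_c[, 2]
    on_c <- on_c[tot > 1e-6 & tot < 2 * d$N - 1e-6, , drop = FALSE]
    g_grid <- relaxed_cost(on_c[, 1], cts, "case") +
      relaxed_cost(on_c[, 2], cts, "control")
    rel <- relaxed_minimum(cts, om, d)
    expect_lte(rel$min_g, min(g_grid) + 1e-9)
    expect_lt(abs(rel$min_g - min(g_grid)), 0.01)
  }
})

test_that("significance sign follows the strict-exceedance convention", {
  cts <- genotype_counts(3, 0, 0, 0, 0, 3)  # Y = 12
  expect_identical(threshold_sign(cts, 2), 1L)
  expect_identical(threshold_sign(cts, 12), -1L)    # boundary is not significant
  expect_identical(threshold_sign(cts, 12.5), -1L)
  degen <- genotype_counts(3, 0, 0, 3, 0, 0)        # x + y = 2N -> Y := 0
  expect_identical(threshold_sign(degen, 2), -1L)
})

test_that("integer feasibility agrees with brute force on the frozen example", {
  cts <- genotype_counts(3, 0, 0, 0, 0, 3)
  expect_false(integer_feasible_exists(0, cts, 2))
  expect_false(integer_feasible_exists(1, cts, 2))
  expect_true(integer_feasible_exists(2, cts, 2))   # (x', y') = (4, 2), Y = 4/3

  set.seed(25)
  for (k in 1:40) {
    cts <- rand_counts(8)
    d <- attr(cts, "design")
    om <- rand_omega(d)
    u <- threshold_sign(cts, om, d)
    cx <- dpgwas:::axis_cost_enum(cts[["r0"]], cts[["r1"]], cts[["r2"]])
    cy <- dpgwas:::axis_cost_enum(cts[["s0"]], cts[["s1"]], cts[["s2"]])
    feas <- outer(0:(2 * d$R), 0:(2 * d$S),
                  function(xx, yy) dpgwas:::feasible_xy(xx, yy, u, om, d))
    costs <- outer(cx, cy, `+`)
    for (delta in 0:6)
      expect_identical(integer_feasible_exists(delta, cts, om, d),
                       any(feas & costs == delta))
  }
})

test_that("fast distance reproduces the hand-enumerated instance", {
  cts <- genotype_counts(3, 0, 0, 0, 0, 3)   # Y = 12, significant at omega = 2
  res <- neighbor_distance(cts, 2)
  expect_s3_class(res, "distance_result")
  expect_equal(res$distance, 2)
  expect_identical(res$side, "significant")
  expect_lte(res$relaxed_bound, 2)
  expect_equal(neighbor_distance(cts, 2, method = "oracle"), 2)
  # every single-individual change keeps Y at or above 2:
  # reachable (x', y') are (4,0),(5,0),(6,1),(6,2) with Y {6, 60/7, 60/7, 6}
  d <- attr(cts, "design")
  one_moves <- rbind(c(4, 0), c(5, 0), c(6, 1), c(6, 2))
  Y1 <- allelic_statistic(one_moves[, 1], one_moves[, 2], d)
  expect_equal(sort(unique(Y1)), c(6, 60 / 7))
})

test_that("fast distance equals the exhaustive oracle on random instances", {
  set.seed(26)
  n_cases <- 400
  for (k in seq_len(n_cases)) {
    cts <- rand_counts()
    d <- attr(cts, "design")
    om <- rand_omega(d)
    f <- suppressWarnings(neighbor_distance(cts, om))
    o <- neighbor_distance(cts, om, method = "oracle")
    expect_equal(f$distance, o,
                 info = sprintf("counts=%s omega=%.6f",
                                paste(as.integer(cts), collapse = ","), om))
    if (is.finite(o)) {
      expect_lte(f$relaxed_bound, o)
      expect_lte(o - f$relaxed_bound, 5)
    }
  }
})

test_that("distance is monotone in omega and allele-relabeling invariant", {
  set.seed(27)
  for (k in 1:30) {
    cts <- rand_counts(15)
    d <- attr(cts, "design")
    xy <- allele_counts(cts)
    Y <- allelic_statistic(xy[["x"]], xy[["y"]], d, degenerate = "zero")
    lo <- min_admissible_threshold(d)
    grid <- sort(runif(5, lo, 2 * d$N))
    dist <- vapply(grid, function(om)
      suppressWarnings(neighbor_distance(cts, om))$distance, numeric(1))
    dist <- pmin(dist, 1e9)  # unreachable boundaries compare as "very far"
    sig <- Y > grid
    # significant side: crossing down gets easier as omega rises
    if (sum(sig) > 1) expect_true(all(diff(dist[sig]) <= 0))
    # non-significant side: crossing up gets harder
    if (sum(!sig) > 1) expect_true(all(diff(dist[!sig]) >= 0))

    # relabeling minor/major allele reverses each cohort's count vector
    flip <- genotype_counts(cts[["r2"]], cts[["r1"]], cts[["r0"]],
                            cts[["s2"]], cts[["s1"]], cts[["s0"]])
    om <- rand_omega(d)
    expect_equal(suppressWarnings(neighbor_distance(cts, om))$distance,
                 suppressWarnings(neighbor_distance(flip, om))$distance)
  }
})

test_that("oracle signals unreachable boundaries; hill-climb upper-bounds", {
  cts <- genotype_counts(5, 3, 2, 4, 4, 2)
  d <- attr(cts, "design")
  # omega above the attainable maximum 2N: upward crossing impossible
  expect_identical(neighbor_distance(cts, 2 * d$N * 1.2, method = "oracle"),
                   Inf)
  expect_identical(suppressWarnings(
    neighbor_distance(cts, 2 * d$N * 1.2))$distance, Inf)

  set.seed(28)
  for (k in 1:25) {
    cts <- rand_counts(12)
    d <- attr(cts, "design")
    om <- rand_omega(d)
    o <- neighbor_distance(cts, om, method = "oracle")
    h <- neighbor_distance(cts, om, method = "hillclimb")
    if (is.finite(o)) expect_gte(h, o)
  }
  expect_gte(neighbor_distance(genotype_counts(3, 0, 0, 0, 0, 3), 2,
                               method = "hillclimb"), 2)
})

test_that("paper-mode pseudocode agrees with the oracle away from the beta edge cases", {
  set.seed(29)
  for (k in 1:60) {
    cts <- rand_counts(12)
    if (cts[["r1"]] == 0 || cts[["s1"]] == 0) next  # the documented divergence
    d <- attr(cts, "design")
    om <- rand_omega(d)
    o <- neighbor_distance(cts, om, method = "oracle")
    if (!is.finite(o)) next
    p <- suppressWarnings(neighbor_distance(cts, om, paper_mode = TRUE))
    if (p$side == "significant")
      expect_equal(p$distance, o)
    else
      expect_lte(p$distance, o)  # early-returned relaxed bound
  }
})
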