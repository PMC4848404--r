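# Neighbor distance: the minimum number of individuals whose genotypes must
# change to flip one SNP across the significance threshold omega. The fast
# path solves a separable piecewise-linear relaxation over the allele-count
# plane, whose binding constraint is the conic
#     C: 2N (xS - yR)^2 = RS * omega * (x + y)(2N - x - y),
# then rounds by searching integer per-axis costs upward from the relaxed
# bound. Exhaustive oracles (enumeration of all count reassignments) define
# correctness; a hill-climbing baseline mirrors earlier approximate methods.

# ---- per-axis relaxed and integer costs -----------------------------------

# Relaxed per-axis cost g (continuous, piecewise linear, zero at the current
# projection 2*n0 + n1). Slopes: 1/2 within the "cheap" range where each
# changed individual moves the projection by 2, then 1 when only het-type
# moves remain. n0,n1,n2 are the axis's genotype counts, Tn = n0+n1+n2.
g_axis_relaxed <- function(x, n0, n1, n2) {
  Tn <- n0 + n1 + n2
  x0 <- 2 * n0 + n1
  out <- numeric(length(x))
  up_cheap <- x >= x0 & x <= 2 * Tn - n1
  dn_cheap <- x >= n1 & x < x0
  up_steep <- x > 2 * Tn - n1
  dn_steep <- x < n1
  out[up_cheap] <- (x[up_cheap] - x0) / 2
  out[dn_cheap] <- (x0 - x[dn_cheap]) / 2
  out[up_steep] <- n2 + x[up_steep] - 2 * (n0 + n2) - n1
  out[dn_steep] <- n0 + n1 - x[dn_steep]
  out
}

# Exact integer per-axis cost: minimum number of individuals reassigned on
# one axis to move the projection from x0 to x. Each reassigned individual
# moves the projection by +-1 or +-2; +-2 moves are capped by the relevant
# homozygote count. Equals ceiling(g_axis_relaxed) at integer x.
cost_axis_exact <- function(x, n0, n1, n2) {
  x0 <- 2 * n0 + n1
  d <- x - x0
  up <- d >= 0
  e <- abs(d)
  out <- numeric(length(x))
  cap <- ifelse(up, n2, n0)  # individuals able to move the projection by 2
  cheap <- e <= 2 * cap
  out[cheap] <- ceiling(e[cheap] / 2)
  out[!cheap] <- cap[!cheap] + (e[!cheap] - 2 * cap[!cheap])
  out
}

# The printed beta (paper mode): ceiling(g) with a +1 correction when the
# het cell is empty and the offset is odd. Over-counts relative to the
# exhaustive reassignment minimum (see package vignette); kept verbatim for
# comparison.
cost_axis_paper <- function(x, n0, n1, n2) {
  g <- ceiling(g_axis_relaxed(x, n0, n1, n2))
  x0 <- 2 * n0 + n1
  g + as.integer(n1 == 0 & (x - x0) %% 2 != 0)
}

# Integer level set {x in [0, 2T] : exact cost == a}, via the closed form.
axis_level_set <- function(a, n0, n1, n2) {
  x0 <- 2 * n0 + n1
  if (a == 0) return(x0)
  vals <- integer(0)
  # increase side: +2 moves capped by n2, then +1 moves capped by n1
  if (a <= n2) vals <- c(vals, x0 + 2 * a - 1, x0 + 2 * a)
  else if (a <= n2 + n1) vals <- c(vals, x0 + n2 + a)
  # decrease side, symmetric with n0
  if (a <= n0) vals <- c(vals, x0 - 2 * a + 1, x0 - 2 * a)
  else if (a <= n0 + n1) vals <- c(vals, x0 - n0 - a)
  vals
}

#' Relaxed per-axis change cost
#'
#' Evaluates the continuous piecewise-linear cost `g1` (case axis) or `g2`
#' (control axis) of moving a SNP's allele-count projection to `x`: the
#' relaxation of the number of individuals whose genotypes must be
#' reassigned on that axis. Zero at the current projection; slope 1/2 while
#' homozygote moves (which shift the projection by 2) remain, slope 1
#' beyond.
#'
#' @param x target projection value(s) in `[0, 2R]` (case) or `[0, 2S]`
#'   (control); real-valued allowed.
#' @param counts a [genotype_counts()] object.
#' @param axis `"case"` or `"control"`.
#' @return Numeric vector of relaxed costs.
#' @export
relaxed_cost <- function(x, counts, axis = c("case", "control")) {
  axis <- match.arg(axis)
  n <- if (axis == "case") counts[c("r0", "r1", "r2")]
       else counts[c("s0", "s1", "s2")]
  if (any(x < 0) || any(x > 2 * sum(n))) stop("x outside the allele-count box")
  g_axis_relaxed(x, n[[1]], n[[2]], n[[3]])
}

#' Integer per-axis change cost
#'
#' The minimum number of individuals reassigned on one axis to reach an
#' integer projection `x`. The default (`paper_mode = FALSE`) is the exact
#' reassignment minimum (equal to the ceiling of [relaxed_cost()] at
#' integers); `paper_mode = TRUE` reproduces the printed rounding rule
#' beta = ceiling(g) + 1 when the het cell is empty and the offset odd,
#' which over-counts on some instances (the exhaustive oracle governs).
#'
#' @inheritParams relaxed_cost
#' @param paper_mode use the printed beta formula verbatim.
#' @return Integer vector of costs.
#' @export
integer_cost <- function(x, counts, axis = c("case", "control"),
                         paper_mode = FALSE) {
  axis <- match.arg(axis)
  n <- if (axis == "case") counts[c("r0", "r1", "r2")]
       else counts[c("s0", "s1", "s2")]
  if (any(x != round(x))) stop("integer_cost needs integer x")
  if (any(x < 0) || any(x > 2 * sum(n))) stop("x outside the allele-count box")
  f <- if (paper_mode) cost_axis_paper else cost_axis_exact
  as.integer(f(x, n[[1]], n[[2]], n[[3]]))
}

# ---- the significance boundary conic --------------------------------------

# Coefficients of h(x, y) = a x^2 + b xy + c y^2 + d x + e y; h = 0 is the
# boundary Y = omega, h > 0 the significant side (where the denominator is
# positive). Normalised for conditioning.
conic_coeffs <- function(omega, design) {
  R <- design$R; S <- design$S; N <- design$N
  cc <- c(a = 2 * N * S^2 + R * S * omega,
          b = 2 * R * S * omega - 4 * N * R * S,
          c = 2 * N * R^2 + R * S * omega,
          d = -2 * N * R * S * omega,
          e = -2 * N * R * S * omega)
  cc / max(abs(cc))
}

conic_residual <- function(cc, x, y) {
  h <- cc[["a"]] * x^2 + cc[["b"]] * x * y + cc[["c"]] * y^2 +
    cc[["d"]] * x + cc[["e"]] * y
  scale <- abs(cc[["a"]]) * x^2 + abs(cc[["b"]] * x * y) +
    abs(cc[["c"]]) * y^2 + abs(cc[["d"]] * x) + abs(cc[["e"]] * y) + 1
  h / scale
}

# Real roots of A t^2 + B t + C = 0, tolerant of a vanishing leading
# coefficient and of tiny negative discriminants.
quad_roots <- function(A, B, C) {
  scale <- max(abs(A), abs(B), abs(C))
  if (scale == 0) return(numeric(0))
  if (abs(A) < 1e-14 * scale) {
    if (abs(B) < 1e-14 * scale) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    if (disc > -1e-10 * (B^2 + 4 * abs(A * C) + scale^2)) disc <- 0
    else return(numeric(0))
  }
  sq <- sqrt(disc)
  if (B >= 0) q <- -(B + sq) / 2 else q <- -(B - sq) / 2
  r <- q / A
  if (abs(q) > 0) r <- c(r, C / q)
  unique(r)
}

in_box <- function(p, design, tol = 1e-7) {
  bx <- 2 * design$R; by <- 2 * design$S
  keep <- p[, 1] >= -tol * (1 + bx) & p[, 1] <= bx * (1 + tol) + tol &
    p[, 2] >= -tol * (1 + by) & p[, 2] <= by * (1 + tol) + tol
  p <- p[keep, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 0), bx)
  p[, 2] <- pmin(pmax(p[, 2], 0), by)
  p
}

#' Tangency candidates on the significance boundary
#'
#' Points of the boundary conic inside the allele-count box where the
#' tangent slope `dy/dx` matches one of the slope ratios of the separable
#' relaxed cost. The per-axis slopes are `+-1/2` and `+-1`, so the full
#' sign-symmetric ratio set `{+-1, +-2, +-1/2}` is used. For each slope `s`
#' the tangency condition `h_x + s h_y = 0` is a line; intersecting it with
#' the conic is a quadratic solve.
#'
#' @param omega admissible threshold (a [threshold()] or numeric).
#' @param design a [cohort_design()].
#' @param slopes slope set to use.
#' @return Matrix with columns `x`, `y` (possibly zero rows).
#' @export
conic_tangency_candidates <- function(omega, design,
                                      slopes = c(1, 2, 0.5, -1, -2, -0.5)) {
  cc <- conic_coeffs(as.numeric(omega), design)
  a <- cc[["a"]]; b <- cc[["b"]]; c2 <- cc[["c"]]; d <- cc[["d"]]; e <- cc[["e"]]
  pts <- matrix(numeric(0), ncol = 2)
  for (s in slopes) {
    lx <- 2 * a + s * b
    ly <- b + 2 * s * c2
    l0 <- d + s * e
    lsc <- max(abs(lx), abs(ly))
    if (lsc < 1e-14) next
    if (abs(ly) >= abs(lx)) {
      al <- -lx / ly; be <- -l0 / ly   # y = al x + be
      A <- a + b * al + c2 * al^2
      B <- b * be + 2 * c2 * al * be + d + e * al
      C <- c2 * be^2 + e * be
      xs <- quad_roots(A, B, C)
      if (length(xs)) pts <- rbind(pts, cbind(xs, al * xs + be))
    } else {
      al <- -ly / lx; be <- -l0 / lx   # x = al y + be
      A <- a * al^2 + b * al + c2
      B <- 2 * a * al * be + b * be + d * al + e
      C <- a * be^2 + d * be
      ys <- quad_roots(A, B, C)
      if (length(ys)) pts <- rbind(pts, cbind(al * ys + be, ys))
    }
  }
  colnames(pts) <- c("x", "y")
  in_box(pts, design)
}

#' Breakpoint candidates on the significance boundary
#'
#' Boundary points whose `x` coordinate sits at a breakpoint of the case
#' cost (`{0, r1, 2r0 + r1, 2R - r1, 2R}`) or whose `y` coordinate sits at
#' a control-cost breakpoint — each found by solving the conic as a
#' quadratic in the free coordinate. Together with
#' [conic_tangency_candidates()] these cover every local minimum of the
#' relaxed cost restricted to the boundary.
#'
#' @param counts a [genotype_counts()] object.
#' @inheritParams conic_tangency_candidates
#' @return Matrix with columns `x`, `y`.
#' @export
breakpoint_candidates <- function(counts, omega, design = design_of(counts)) {
  cc <- conic_coeffs(as.numeric(omega), design)
  a <- cc[["a"]]; b <- cc[["b"]]; c2 <- cc[["c"]]; d <- cc[["d"]]; e <- cc[["e"]]
  r <- counts[c("r0", "r1", "r2")]; s <- counts[c("s0", "s1", "s2")]
  xs <- unique(c(0, r[[2]], 2 * r[[1]] + r[[2]],
                 2 * design$R - r[[2]], 2 * design$R))
  ys <- unique(c(0, s[[2]], 2 * s[[1]] + s[[2]],
                 2 * design$S - s[[2]], 2 * design$S))
  pts <- matrix(numeric(0), ncol = 2)
  for (v in xs) {
    roots <- quad_roots(c2, b * v + e, a * v^2 + d * v)
    if (length(roots)) pts <- rbind(pts, cbind(v, roots))
  }
  for (w in ys) {
    roots <- quad_roots(a, b * w + d, c2 * w^2 + e * w)
    if (length(roots)) pts <- rbind(pts, cbind(roots, w))
  }
  colnames(pts) <- c("x", "y")
  in_box(pts, design)
}

# ---- feasibility and distance ---------------------------------------------

#' Significance sign of a SNP
#'
#' `+1` if the SNP's statistic strictly exceeds `omega` (significant), `-1`
#' otherwise; the boundary `Y = omega` and degenerate (monomorphic, `Y`
#' taken as 0) SNPs are not significant, matching the strict `>` of the
#' selection algorithm.
#'
#' @inheritParams breakpoint_candidates
#' @return `+1` or `-1`.
#' @export
threshold_sign <- function(counts, omega, design = design_of(counts)) {
  xy <- allele_counts(counts)
  Y <- allelic_statistic(xy[["x"]], xy[["y"]], design, degenerate = "zero")
  if (Y > as.numeric(omega)) 1L else -1L
}

# u * (Y - omega) <= 0, with Y = 0 at degenerate points. Vectorised.
feasible_xy <- function(x, y, u, omega, design) {
  Y <- allelic_statistic(x, y, design, degenerate = "zero")
  u * (Y - omega) <= 0
}

#' Relaxed lower bound on the neighbor distance
#'
#' Minimises the separable relaxed cost over the candidate points (tangency
#' and breakpoint) of the significance boundary and returns the ceiling: a
#' valid lower bound for the integer neighbor distance.
#'
#' @inheritParams breakpoint_candidates
#' @return List with `ghat` (the integer bound), `min_g` (the relaxed
#'   minimum) and `argmin` (the minimising boundary point).
#' @export
relaxed_minimum <- function(counts, omega, design = design_of(counts)) {
  omega <- as.numeric(omega)
  pts <- rbind(conic_tangency_candidates(omega, design),
               breakpoint_candidates(counts, omega, design))
  # The degenerate corners (0,0) and (2R,2S) always satisfy the conic
  # equation but carry Y = 0 (by the monomorphic convention), not omega,
  # and are isolated points of the conic inside the box. They are feasible
  # destinations only when crossing downward (significant SNPs); for upward
  # crossings keep only candidates that genuinely attain Y = omega.
  if (nrow(pts) > 0L && threshold_sign(counts, omega, design) < 0) {
    Yp <- allelic_statistic(pts[, 1], pts[, 2], design, degenerate = "zero")
    pts <- pts[abs(Yp - omega) <= 1e-4 * max(1, omega), , drop = FALSE]
  }
  if (nrow(pts) == 0L)
    return(list(ghat = NA_integer_, min_g = NA_real_, argmin = NULL))
  r <- counts[c("r0", "r1", "r2")]; s <- counts[c("s0", "s1", "s2")]
  g <- g_axis_relaxed(pts[, 1], r[[1]], r[[2]], r[[3]]) +
    g_axis_relaxed(pts[, 2], s[[1]], s[[2]], s[[3]])
  i <- which.min(g)
  list(ghat = max(0L, as.integer(ceiling(g[i] - 1e-9))),
       min_g = g[i], argmin = pts[i, ])
}

#' Is a total change cost achievable on the required side?
#'
#' True iff some integer point `(x, y)` of the allele-count box lies on (or
#' beyond) the significance boundary, on the side opposite the SNP's
#' current one, with per-axis integer costs summing exactly to `delta`.
#' Works through the closed-form level sets of the per-axis cost (at most
#' four projections per axis and cost value), so each call touches O(delta)
#' candidate pairs.
#'
#' @param delta candidate total cost (>= 0).
#' @inheritParams breakpoint_candidates
#' @param paper_mode use the printed beta costs instead of the exact ones.
#' @return Logical scalar.
#' @export
integer_feasible_exists <- function(delta, counts, omega,
                                    design = design_of(counts),
                                    paper_mode = FALSE) {
  stopifnot(delta >= 0)
  omega <- as.numeric(omega)
  u <- threshold_sign(counts, omega, design)
  r <- counts[c("r0", "r1", "r2")]; s <- counts[c("s0", "s1", "s2")]
  if (paper_mode) {
    cx <- cost_axis_paper(0:(2 * design$R), r[[1]], r[[2]], r[[3]])
    cy <- cost_axis_paper(0:(2 * design$S), s[[1]], s[[2]], s[[3]])
    lev1 <- function(a) which(cx == a) - 1L
    lev2 <- function(a) which(cy == a) - 1L
    maxc1 <- max(cx); maxc2 <- max(cy)
  } else {
    lev1 <- function(a) axis_level_set(a, r[[1]], r[[2]], r[[3]])
    lev2 <- function(a) axis_level_set(a, s[[1]], s[[2]], s[[3]])
    maxc1 <- max(cost_axis_exact(c(0, 2 * design$R), r[[1]], r[[2]], r[[3]]))
    maxc2 <- max(cost_axis_exact(c(0, 2 * design$S), s[[1]], s[[2]], s[[3]]))
  }
  for (a in max(0, delta - maxc2):min(delta, maxc1)) {
    xs <- lev1(a)
    if (!length(xs)) next
    ys <- lev2(delta - a)
    if (!length(ys)) next
    grid <- expand.grid(x = xs, y = ys)
    if (any(feasible_xy(grid$x, grid$y, u, omega, design))) return(TRUE)
  }
  FALSE
}

#' Neighbor distance of a SNP to the significance boundary
#'
#' The minimum number of individuals whose genotypes must change to flip
#' the SNP across `omega`. Methods:
#'
#' * `"fast"` — the relaxation-and-rounding algorithm: compute the relaxed
#'   bound over the boundary candidates, then search total integer costs
#'   `delta = ghat, ghat + 1, ...` for the first achievable one. With the
#'   exact per-axis costs this search is provably exact; with
#'   `paper_mode = TRUE` it reproduces the printed pseudocode verbatim
#'   (early return of the relaxed bound for non-significant SNPs, printed
#'   beta costs, rounding window of 5).
#' * `"oracle"` — exhaustive enumeration over all per-axis genotype
#'   reassignments and the full allele-count grid (guarded to
#'   `R + S <= 200`); defines correctness.
#' * `"hillclimb"` — the greedy single-individual baseline used by earlier
#'   approximate implementations.
#'
#' A non-significant SNP whose design cannot reach `omega` at all has
#' infinite distance.
#'
#' @inheritParams breakpoint_candidates
#' @param method one of `"fast"`, `"oracle"`, `"hillclimb"`.
#' @param paper_mode (fast only) follow the printed pseudocode exactly.
#' @param max_d (oracle only) give up beyond this distance and return `Inf`.
#' @return For `"fast"`, an object of class `distance_result`: list with
#'   `distance`, `relaxed_bound`, `delta_used`, `side`, `statistic`,
#'   `omega`. For the other methods, a bare numeric distance.
#' @examples
#' cts <- genotype_counts(3, 0, 0, 0, 0, 3)
#' neighbor_distance(cts, omega = 2)$distance  # 2
#' @export
neighbor_distance <- function(counts, omega, design = design_of(counts),
                              method = c("fast", "oracle", "hillclimb"),
                              paper_mode = FALSE, max_d = Inf) {
  method <- match.arg(method)
  omega <- as.numeric(omega)
  if (omega < min_admissible_threshold(design) - 1e-12)
    stop("omega below the admissible floor 2N/(2N-1); clamp it first")
  switch(method,
    fast = nd_fast(counts, omega, design, paper_mode),
    oracle = nd_oracle(counts, omega, design, max_d),
    hillclimb = nd_hillclimb(counts, omega, design))
}

nd_fast <- function(counts, omega, design, paper_mode = FALSE) {
  u <- threshold_sign(counts, omega, design)
  xy <- allele_counts(counts)
  Y <- allelic_statistic(xy[["x"]], xy[["y"]], design, degenerate = "zero")
  rel <- relaxed_minimum(counts, omega, design)
  side <- if (u > 0) "significant" else "not_significant"
  res <- function(distance, delta_used = NA_integer_)
    structure(list(distance = distance, relaxed_bound = rel$ghat,
                   delta_used = delta_used, side = side, statistic = Y,
                   omega = omega),
              class = "distance_result")
  if (is.na(rel$ghat)) {
    # boundary misses the box entirely: unreachable for non-significant
    # SNPs; cannot happen for significant ones (the zero-statistic line is
    # always feasible).
    if (u < 0) return(res(Inf))
    warning("no boundary candidates for a significant SNP; scanning from 0")
    rel$ghat <- 0L
  }
  if (paper_mode && u < 0) return(res(rel$ghat, rel$ghat))
  r <- counts[c("r0", "r1", "r2")]; s <- counts[c("s0", "s1", "s2")]
  dmax <- max(cost_axis_exact(c(0, 2 * design$R), r[[1]], r[[2]], r[[3]])) +
    max(cost_axis_exact(c(0, 2 * design$S), s[[1]], s[[2]], s[[3]]))
  hi <- if (paper_mode) rel$ghat + 5L else dmax
  for (delta in rel$ghat:max(rel$ghat, hi)) {
    if (integer_feasible_exists(delta, counts, omega, design, paper_mode)) {
      if (delta > rel$ghat + 5L)
        warning(sprintf(
          "rounding search exceeded the +5 window (ghat=%d, delta=%d)",
          rel$ghat, delta))
      return(res(delta, as.integer(delta)))
    }
  }
  if (paper_mode) {
    # printed window failed: fall back to the exact search, as documented
    warning("paper-mode rounding window exhausted; falling back to exact search")
    return(nd_fast(counts, omega, design, paper_mode = FALSE))
  }
  res(Inf)
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("neighbor distance %s (side: %s, Y = %.4g, omega = %.4g, ghat = %s)\n",
              format(x$distance), x$side, x$statistic, x$omega,
              format(x$relaxed_bound)))
  invisible(x)
}

# Exhaustive per-axis cost table: for every reachable projection x', the
# minimum half-L1 reassignment over all (n0', n1', n2') with the same total.
# Independent of the closed forms above; used by the oracle and in tests.
axis_cost_enum <- function(n0, n1, n2) {
  Tn <- n0 + n1 + n2
  a0 <- rep(0:Tn, each = Tn + 1)
  a1 <- rep(0:Tn, times = Tn + 1)
  keep <- a0 + a1 <= Tn
  a0 <- a0[keep]; a1 <- a1[keep]; a2 <- Tn - a0 - a1
  xv <- 2 * a0 + a1
  cost <- (abs(a0 - n0) + abs(a1 - n1) + abs(a2 - n2)) / 2
  out <- rep(Inf, 2 * Tn + 1)
  agg <- tapply(cost, xv, min)
  out[as.integer(names(agg)) + 1L] <- agg
  out
}

nd_oracle <- function(counts, omega, design, max_d = Inf) {
  if (design$R + design$S > 200)
    stop("oracle guarded to R + S <= 200")
  u <- threshold_sign(counts, omega, design)
  r <- counts[c("r0", "r1", "r2")]; s <- counts[c("s0", "s1", "s2")]
  cx <- axis_cost_enum(r[[1]], r[[2]], r[[3]])
  cy <- axis_cost_enum(s[[1]], s[[2]], s[[3]])
  xg <- 0:(2 * design$R); yg <- 0:(2 * design$S)
  feas <- outer(xg, yg, function(xx, yy) feasible_xy(xx, yy, u, omega, design))
  if (!any(feas)) return(Inf)
  d <- min(outer(cx, cy, `+`)[feas])
  if (d > max_d) Inf else d
}

nd_hillclimb <- function(counts, omega, design, max_steps = 4 * design$N) {
  u <- threshold_sign(counts, omega, design)
  state <- as.integer(counts)
  names(state) <- names(counts)[1:6]
  score <- function(st) {
    x <- 2 * st[["r0"]] + st[["r1"]]; y <- 2 * st[["s0"]] + st[["s1"]]
    u * (allelic_statistic(x, y, design, degenerate = "zero") - omega)
  }
  steps <- 0L
  cur <- score(state)
  while (cur > 0) {
    if (steps >= max_steps) return(Inf)
    best <- NULL; best_val <- Inf
    for (cohort in c(0L, 3L)) {
      for (from in 1:3) {
        if (state[cohort + from] == 0L) next
        for (to in 1:3) {
          if (to == from) next
          cand <- state
          cand[cohort + from] <- cand[cohort + from] - 1L
          cand[cohort + to] <- cand[cohort + to] + 1L
          v <- score(cand)
          if (v < best_val) { best_val <- v; best <- cand }
        }
      }
    }
    if (best_val >= cur) return(Inf)  # stuck: no move approaches the boundary
    state <- best; cur <- best_val; steps <- steps + 1L
  }
  steps
}
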