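# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive quantities by routes different from the
# package implementation.

# perpendicular distance from point p to the infinite line through a, b
oracle_point_line_dist <- function(p, a, b) {
  d <- b - a
  abs(d[1] * (p[2] - a[2]) - d[2] * (p[1] - a[1])) / sqrt(sum(d^2))
}

# circumcenter as the intersection of two perpendicular bisectors,
# solved as explicit line intersection (not the package's linear system)
oracle_circumcenter <- function(p1, p2, p3) {
  m1 <- (p1 + p2) / 2
  m2 <- (p2 + p3) / 2
  d1 <- c(-(p2 - p1)[2], (p2 - p1)[1])  # bisector directions
  d2 <- c(-(p3 - p2)[2], (p3 - p2)[1])
  A <- cbind(d1, -d2)
  t <- solve(A, m2 - m1)
  m1 + t[1] * d1
}

# symmetric Hausdorff distance between two polylines (point-to-segment,
# so it measures curve deviation, not sampling density)
oracle_hausdorff <- function(ax, ay, bx, by) {
  dir_dist <- function(px, py, qx, qy) {
    best <- rep(Inf, length(px))
    for (k in seq_len(length(qx) - 1)) {
      sx <- qx[k]; sy <- qy[k]
      dx <- qx[k + 1] - sx; dy <- qy[k + 1] - sy
      len2 <- dx^2 + dy^2
      t <- pmin(pmax(((px - sx) * dx + (py - sy) * dy) / len2, 0), 1)
      d2 <- (px - (sx + t * dx))^2 + (py - (sy + t * dy))^2
      best <- pmin(best, d2)
    }
    sqrt(max(best))
  }
  max(dir_dist(ax, ay, bx, by), dir_dist(bx, by, ax, ay))
}

# O(n^2) search for the common support line on the low-y side of the
# thoracic and sacral point sets: the pair whose connecting line leaves
# every point of both sets on or above it
oracle_support_line <- function(th_x, th_y, sa_x, sa_y, tol = 1e-9) {
  px <- c(th_x, sa_x); py <- c(th_y, sa_y)
  best <- NULL
  for (i in seq_along(th_x)) {
    for (j in seq_along(sa_x)) {
      a <- c(th_x[i], th_y[i]); b <- c(sa_x[j], sa_y[j])
      dx <- b[1] - a[1]; dy <- b[2] - a[2]
      len <- sqrt(dx^2 + dy^2)
      if (len == 0) next
      sdist <- (dx * (py - a[2]) - dy * (px - a[1])) / len
      if (all(sdist >= -tol)) best <- list(a = a, b = b)
    }
  }
  best
}

# equal-stress split of a two-layer stack by brute-force grid search over
# the deflection split
oracle_two_spring <- function(law1, t1, law2, t2, w, n_grid = 20000) {
  w1 <- seq(max(0, w - 0.949 * t2), min(w, 0.949 * t1), length.out = n_grid)
  s1 <- law1(w1 / t1)
  s2 <- law2((w - w1) / t2)
  k <- which.min(abs(s1 - s2))
  (s1[k] + s2[k]) / 2
}

# 29 noise-free elements along a circle of the given diameter (open arc)
circle_elements <- function(diameter_mm = 200, n_elements = 29,
                            arc_fraction = 0.9) {
  r <- diameter_mm / 2
  th <- seq(0, 2 * pi * arc_fraction, length.out = 2 * n_elements + 1)
  px <- r * cos(th); py <- r * sin(th)
  i0 <- seq(1, 2 * n_elements - 1, by = 2)
  arc_elements(data.frame(
    element_id = seq_len(n_elements) - 1L,
    x_start = px[i0], y_start = py[i0],
    x_mid = px[i0 + 1], y_mid = py[i0 + 1],
    x_end = px[i0 + 2], y_end = py[i0 + 2]))
}

# straight-tape fixture: n collinear 30 mm line elements
straight_elements <- function(n = 29, len_mm = 30) {
  x0 <- (seq_len(n) - 1) * len_mm
  arc_elements(data.frame(
    element_id = seq_len(n) - 1L,
    x_start = x0, y_start = 0,
    x_mid = x0 + len_mm / 2, y_mid = 0,
    x_end = x0 + len_mm, y_end = 0))
}

# material scaled pointwise by a factor (preserves thickness attribute)
scaled_material <- function(m, factor, name = "scaled") {
  m2 <- fit_foam_law(stress_strain_curve(m$data$strain,
                                         m$data$stress_kPa * factor),
                     poisson = m$poisson, name = name)
  attr(m2, "thickness_mm") <- attr(m, "thickness_mm")
  m2
}

# the bundled synthetic material library, loaded once per test session
test_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- foam_library()
    lib
  }
})

# random feasible spine-parameter draws (seeded by caller)
random_feasible_params <- function(n) {
  out <- list()
  while (length(out) < n) {
    p <- c(TI = runif(1, 0, 12), HD = runif(1, 20, 120),
           CLD = runif(1, 40, 130), LLD = runif(1, 0, 45))
    if (profile_feasible(p["TI"], p["HD"], p["CLD"], p["LLD"])) {
      out[[length(out) + 1]] <- p
    }
  }
  out
}
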