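# Internal geometry and unit helpers shared across modules.
# Sagittal-plane convention: +x runs caudally along the mattress top,
# +y points vertically away from the mattress; all lengths in mm.

# unit conversions (single authoritative table)
.units <- list(
  N_per_lbf   = 4.4482216152605,
  mm2_per_cm2 = 100,
  cm2_per_in2 = 6.4516,
  kPa_per_MPa = 1000
)

.cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx

# Signed perpendicular distance from points (px, py) to the infinite line
# through a and b; positive on the left of a->b.
.signed_line_dist <- function(px, py, a, b) {
  dx <- b[1] - a[1]
  dy <- b[2] - a[2]
  len <- sqrt(dx^2 + dy^2)
  if (len <= 0) stop("degenerate line: identical endpoints")
  (dx * (py - a[2]) - dy * (px - a[1])) / len
}

# Rotate an n x 2 matrix of points by `deg` degrees about `center`.
.rotate_pts <- function(xy, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(xy, 2, center) %*% t(R), 2, center, `+`)
}

# Cumulative trapezoidal integral of y over x (same length, x increasing).
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Indices of the lower convex hull (smallest y side) of points sorted by x.
# Andrew's monotone chain; collinear interior points are dropped.
.lower_hull <- function(x, y) {
  ord <- order(x, y)
  hull <- integer(0)
  for (i in ord) {
    while (length(hull) >= 2) {
      j <- hull[length(hull) - 1]
      k <- hull[length(hull)]
      if (.cross2(x[k] - x[j], y[k] - y[j], x[i] - x[j], y[i] - y[j]) <= 0) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  hull
}

# Algebraic (Kasa) least-squares circle fit.  Returns center and radius.
.fit_circle_kasa <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  list(center = c(cx, cy), radius = r)
}

#' Least-squares circle fit
#'
#' Fits a circle to a set of 2-D points by algebraic (Kasa) least squares.
#' Used, e.g., to benchmark the tape-reconstruction pipeline against a
#' circle of known diameter.
#'
#' @param x,y numeric vectors of point coordinates (mm), or `x` may be a
#'   [spinal_curve] whose points are used.
#' @return list with `center` (length-2, mm), `radius` (mm) and
#'   `diameter` (mm).
#' @examples
#' th <- seq(0, pi, length.out = 50)
#' fit_circle(100 * cos(th), 100 * sin(th))$diameter
#' @export
fit_circle <- function(x, y = NULL) {
  if (inherits(x, "spinal_curve")) {
    y <- x$y
    x <- x$x
  }
  stopifnot(length(x) == length(y), length(x) >= 3)
  f <- .fit_circle_kasa(x, y)
  f$diameter <- 2 * f$radius
  f
}
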