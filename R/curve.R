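# SpinalCurve: an ordered sagittal polyline (cranial end first) with
# cumulative arclength.  This is the continuous back profile obtained by
# chaining tape elements, and also the native output of the synthetic
# profile generator.

#' Construct a spinal curve
#'
#' @param x,y point coordinates (mm), cranial end first.
#' @param s cumulative arclength (mm) per point; computed from chord lengths
#'   when omitted.  Must be strictly increasing and start at 0.
#' @return object of class `spinal_curve`: a list with `x`, `y`, `s`.
#' @export
spinal_curve <- function(x, y, s = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (is.null(s)) {
    s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  }
  if (length(s) != length(x)) stop("s must match point count")
  if (s[1] != 0) stop("s must start at 0")
  if (any(diff(s) <= 0)) stop("s must be strictly increasing")
  structure(list(x = as.numeric(x), y = as.numeric(y), s = as.numeric(s)),
            class = "spinal_curve")
}

#' Total arclength of a spinal curve
#' @param c a `spinal_curve`.
#' @return length in mm.
#' @export
curve_length <- function(c) c$s[length(c$s)]

#' @export
print.spinal_curve <- function(x, ...) {
  cat("<spinal_curve> ", length(x$x), " points, length ",
      format(curve_length(x), digits = 6), " mm\n", sep = "")
  invisible(x)
}

#' @export
plot.spinal_curve <- function(x, ..., asp = 1) {
  graphics::plot(x$x, x$y, type = "l", asp = asp,
                 xlab = "x (mm, cranial to caudal)", ylab = "y (mm)", ...)
  invisible(x)
}

#' Apply a rigid motion to a spinal curve
#'
#' @param c a `spinal_curve`.
#' @param deg rotation angle (degrees, counter-clockwise).
#' @param shift length-2 translation (mm), applied after the rotation.
#' @param center rotation center (mm).
#' @return transformed `spinal_curve` (arclength unchanged).
#' @export
transform_curve <- function(c, deg = 0, shift = c(0, 0), center = c(0, 0)) {
  xy <- .rotate_pts(cbind(c$x, c$y), deg, center)
  spinal_curve(xy[, 1] + shift[1], xy[, 2] + shift[2], c$s)
}

#' Chain tape elements into a continuous spinal curve
#'
#' Each element is densely sampled (default 20 points) and the samples are
#' concatenated in tape order.  If the start of element i+1 misses the end of
#' element i by more than `gap_tol` the later element is rigidly translated
#' (no rotation, preserving the measured inclination) so the endpoints
#' coincide, and a warning is emitted.  The returned cumulative arclength is
#' the analytic per-element arclength, so the total curve length equals the
#' sum of element arclengths.
#'
#' @param elements an `arc_elements` object (>= 1 row, tape order).
#' @param gap_tol endpoint-gap tolerance (mm) before translation repair.
#' @param n_per_element sample points per element.
#' @param tol_line collinearity tolerance passed to [classify_element()].
#' @return a `spinal_curve`.
#' @export
chain_elements <- function(elements, gap_tol = 0.5, n_per_element = 20,
                           tol_line = 0.05) {
  if (!inherits(elements, "arc_elements")) elements <- arc_elements(elements)
  if (nrow(elements) < 1) stop("empty element list")
  xs <- ys <- ss <- numeric(0)
  s0 <- 0
  repaired <- 0L
  for (i in seq_len(nrow(elements))) {
    sm <- .sample_element(elements[i, ], n = n_per_element,
                          tol_line = tol_line)
    if (i > 1) {
      gap <- c(xs[length(xs)] - sm$x[1], ys[length(ys)] - sm$y[1])
      gnorm <- sqrt(sum(gap^2))
      if (gnorm > gap_tol) {
        sm$x <- sm$x + gap[1]
        sm$y <- sm$y + gap[2]
        repaired <- repaired + 1L
      }
      # the first sample duplicates the previous element's end arclength;
      # drop it (any residual sub-tolerance position gap stays, as measured)
      sm$x <- sm$x[-1]; sm$y <- sm$y[-1]; sm$s <- sm$s[-1]
    }
    xs <- c(xs, sm$x)
    ys <- c(ys, sm$y)
    ss <- c(ss, s0 + sm$s)
    s0 <- s0 + element_arclength(elements[i, ], tol_line)
  }
  if (repaired > 0) {
    warning(repaired, " inter-element gap(s) exceeded gap_tol = ", gap_tol,
            " mm; later elements translated to restore continuity")
  }
  spinal_curve(xs, ys, ss)
}

#' Resample a spinal curve at uniform arclength spacing
#'
#' Points are placed at (near-)equal arclength steps by linear interpolation
#' along the existing polyline; endpoints are preserved exactly and the total
#' length is preserved.
#'
#' @param c a `spinal_curve`.
#' @param spacing target spacing (mm); must be positive and smaller than the
#'   curve length.  The realised spacing is `L / ceiling(L / spacing)`, i.e.
#'   never larger than requested.
#' @return a `spinal_curve`.
#' @export
resample_curve <- function(c, spacing) {
  L <- curve_length(c)
  if (spacing <= 0) stop("spacing must be positive")
  if (spacing >= L) stop("spacing must be smaller than the curve length")
  n_seg <- ceiling(L / spacing - 1e-9)
  s_new <- seq(0, L, length.out = n_seg + 1)
  x_new <- stats::approx(c$s, c$x, xout = s_new)$y
  y_new <- stats::approx(c$s, c$y, xout = s_new)$y
  spinal_curve(x_new, y_new, s_new)
}

#' Read / write spinal-curve CSV
#'
#' CSV dialect: header `s_mm,x_mm,y_mm`, units mm.
#'
#' @param path file path.
#' @return `read_curve_csv`: a `spinal_curve`.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("s_mm", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop("curve CSV must have columns ", paste(need, collapse = ","))
  }
  spinal_curve(df$x_mm, df$y_mm, df$s_mm)
}

#' @rdname read_curve_csv
#' @param c a `spinal_curve`.
#' @export
write_curve_csv <- function(c, path) {
  utils::write.csv(data.frame(s_mm = c$s, x_mm = c$x, y_mm = c$y),
                   path, row.names = FALSE)
  invisible(path)
}
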