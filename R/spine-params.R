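# Sagittal alignment metrics extracted from a supine back profile:
#   TI  - torso inclination: angle of the common tangent (support) line
#         through the thoracic and sacral regions, relative to the mattress
#         top (+x axis);
#   HD  - perpendicular distance of the cranial curve endpoint to that line;
#   CLD - cervical lordosis apex height above the line;
#   LLD - lumbar lordosis apex height above the line.
# Distances are perpendicular (rotation-invariant), on the side of the line
# away from the mattress.

#' Region partition of the back profile
#'
#' Arclength fractions (of total curve length, cranial to caudal) delimiting
#' the occiput/head `[0, f1)`, cervical `[f1, f2)`, thoracic `[f2, f3)`,
#' lumbar `[f3, f4)` and sacral `[f4, f5]` regions.  The tape does not
#' localise vertebral levels, so the boundaries are anthropometric defaults
#' and fully configurable.
#'
#' @param f1,f2,f3,f4,f5 strictly increasing fractions in (0, 1].
#' @return object of class `region_partition`.
#' @export
region_partition <- function(f1 = 0.10, f2 = 0.20, f3 = 0.55,
                             f4 = 0.75, f5 = 0.90) {
  f <- c(f1, f2, f3, f4, f5)
  if (any(diff(c(0, f)) <= 0) || f5 > 1) {
    stop("require 0 < f1 < f2 < f3 < f4 < f5 <= 1")
  }
  structure(list(f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5),
            class = "region_partition")
}

# indices of curve points in a named region
.region_idx <- function(c, part, region) {
  fr <- c$s / curve_length(c)
  switch(region,
    head     = which(fr < part$f1),
    cervical = which(fr >= part$f1 & fr < part$f2),
    thoracic = which(fr >= part$f2 & fr < part$f3),
    lumbar   = which(fr >= part$f3 & fr < part$f4),
    sacral   = which(fr >= part$f4 & fr <= part$f5),
    stop("unknown region: ", region)
  )
}

# +1 if the body side (away from mattress) is the positive side of the
# signed distance to the line, else -1; decided by the mean side of the
# whole curve.
.body_side <- function(c, line) {
  d <- .signed_line_dist(c$x, c$y, line$a, line$b)
  if (mean(d) >= 0) 1 else -1
}

#' Torso-inclination support line
#'
#' Finds the common tangent line on the mattress side of the thoracic and
#' sacral regions: the pair of curve points (one per region) whose connecting
#' line leaves every thoracic and sacral point on or above it.  Implemented
#' via the lower convex hull of the union of the two regions, taking the
#' hull edge that spans them.  TI is the absolute angle of this line to the
#' +x (mattress top) axis.
#'
#' @param c a [spinal_curve].
#' @param part a [region_partition].
#' @return list with `a`, `b` (the two tangent points, thoracic then sacral,
#'   mm), `TI_deg` and `tangent_idx` (point indices into the curve).
#' @export
torso_inclination_line <- function(c, part = region_partition()) {
  ith <- .region_idx(c, part, "thoracic")
  isa <- .region_idx(c, part, "sacral")
  if (length(ith) < 3 || length(isa) < 3) {
    stop("need at least 3 curve points in each of the thoracic and sacral regions")
  }
  idx <- c(ith, isa)
  lab <- rep(c("thoracic", "sacral"), c(length(ith), length(isa)))
  hull <- .lower_hull(c$x[idx], c$y[idx])
  hl <- lab[hull]
  span <- which(hl[-length(hl)] == "thoracic" & hl[-1] == "sacral")
  if (length(span) == 0) stop("no spanning tangent edge between thoracic and sacral regions")
  i <- hull[span[1]]
  j <- hull[span[1] + 1]
  a <- c(c$x[idx[i]], c$y[idx[i]])
  b <- c(c$x[idx[j]], c$y[idx[j]])
  TI <- abs(atan2(b[2] - a[2], b[1] - a[1])) * 180 / pi
  if (TI > 90) TI <- 180 - TI  # line direction is sign-free
  list(a = a, b = b, TI_deg = TI, tangent_idx = c(idx[i], idx[j]))
}

#' Head distance to the torso-inclination line
#'
#' Perpendicular distance from the cranial endpoint (s = 0) of the curve to
#' the TI line, positive on the away-from-mattress side.  A negative value
#' (head below the support line) is clipped to 0 with a warning.
#'
#' @param c a [spinal_curve].
#' @param line result of [torso_inclination_line()].
#' @return distance in mm.
#' @export
head_distance <- function(c, line) {
  side <- .body_side(c, line)
  d <- side * .signed_line_dist(c$x[1], c$y[1], line$a, line$b)
  if (d < 0) {
    warning("head point lies below the support line; clipping HD to 0")
    d <- 0
  }
  d
}

.lordosis_distance <- function(c, line, part, region) {
  idx <- .region_idx(c, part, region)
  if (length(idx) == 0) stop("empty ", region, " region")
  side <- .body_side(c, line)
  d <- max(side * .signed_line_dist(c$x[idx], c$y[idx], line$a, line$b))
  if (d < 0) {
    warning(region, " region lies entirely below the support line; clipping to 0")
    d <- 0
  }
  d
}

#' Cervical / lumbar lordosis distance
#'
#' Maximum perpendicular distance to the TI line over the curve points of the
#' named region, on the away-from-mattress side (the lordosis apex height
#' above the support line).
#'
#' @inheritParams head_distance
#' @param part a [region_partition].
#' @return distance in mm.
#' @export
cervical_lordosis_distance <- function(c, line, part = region_partition()) {
  .lordosis_distance(c, line, part, "cervical")
}

#' @rdname cervical_lordosis_distance
#' @export
lumbar_lordosis_distance <- function(c, line, part = region_partition()) {
  .lordosis_distance(c, line, part, "lumbar")
}

#' Extract all spine parameters from a back profile
#'
#' Composition of [torso_inclination_line()], [head_distance()] and the two
#' lordosis distances.
#'
#' @param c a [spinal_curve].
#' @param part a [region_partition].
#' @return object of class `spine_params`: list with `TI_deg`, `HD_mm`,
#'   `CLD_mm`, `LLD_mm`, `tangent_points` (2 x 2 matrix, rows thoracic and
#'   sacral) and the support `line`.
#' @export
extract_spine_params <- function(c, part = region_partition()) {
  line <- torso_inclination_line(c, part)
  structure(list(
    TI_deg = line$TI_deg,
    HD_mm = head_distance(c, line),
    CLD_mm = cervical_lordosis_distance(c, line, part),
    LLD_mm = lumbar_lordosis_distance(c, line, part),
    tangent_points = rbind(thoracic = line$a, sacral = line$b),
    line = line
  ), class = "spine_params")
}

#' @export
print.spine_params <- function(x, digits = 3, ...) {
  cat("Supine spine parameters\n")
  cat(sprintf("  TI  %8.*f deg\n", digits, x$TI_deg))
  cat(sprintf("  HD  %8.*f mm\n", digits, x$HD_mm))
  cat(sprintf("  CLD %8.*f mm\n", digits, x$CLD_mm))
  cat(sprintf("  LLD %8.*f mm\n", digits, x$LLD_mm))
  invisible(x)
}

#' @export
as.data.frame.spine_params <- function(x, ...) {
  data.frame(TI_deg = x$TI_deg, HD_mm = x$HD_mm,
             CLD_mm = x$CLD_mm, LLD_mm = x$LLD_mm)
}
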