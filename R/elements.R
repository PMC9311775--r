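# Tape elements: one curvature-measurement-tape segment is reported as three
# sagittal-plane points (start, mid, end).  A 870 mm tape with 30 sensors
# yields 29 such elements of nominally 30 mm each; every element is either a
# circular arc through its three points or a straight line.

#' Construct a set of tape arc/line elements
#'
#' An `arc_elements` object is a data frame with one row per tape element and
#' columns `element_id, x_start, y_start, x_mid, y_mid, x_end, y_end`
#' (units mm).  Row order is tape order, cranial end first.
#'
#' @param df data frame with the columns above (`element_id` optional; row
#'   order defines it when missing).
#' @param check_length if `TRUE`, warn when an element's arclength is outside
#'   `nominal_mm * (1 +/- tol_len)` (tape-native data: 870/29 = 30 mm each).
#' @param nominal_mm nominal element arclength (mm).
#' @param tol_len relative tolerance on element arclength.
#' @return data frame of class `arc_elements`.
#' @export
arc_elements <- function(df, check_length = FALSE, nominal_mm = 30,
                         tol_len = 0.05) {
  need <- c("x_start", "y_start", "x_mid", "y_mid", "x_end", "y_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$element_id)) df$element_id <- seq_len(nrow(df)) - 1L
  if (anyDuplicated(df$element_id)) stop("duplicate element_id")
  if (is.unsorted(df$element_id, strictly = TRUE)) {
    stop("elements must be ordered by increasing element_id")
  }
  df <- df[, c("element_id", need)]
  for (nm in need) {
    if (!is.numeric(df[[nm]]) || anyNA(df[[nm]])) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop("non-numeric or missing value in column '", nm, "' at row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  chord <- sqrt((df$x_end - df$x_start)^2 + (df$y_end - df$y_start)^2)
  if (any(chord <= 0)) {
    stop("invalid element: p_start equals p_end at row ",
         which(chord <= 0)[1])
  }
  class(df) <- c("arc_elements", "data.frame")
  if (check_length) {
    len <- vapply(seq_len(nrow(df)), function(i) element_arclength(df[i, ]),
                  numeric(1))
    off <- abs(len - nominal_mm) > nominal_mm * tol_len
    if (any(off)) {
      warning(sum(off), " element(s) deviate from the nominal ", nominal_mm,
              " mm arclength by more than ", 100 * tol_len, "%")
    }
  }
  df
}

.elem_pts <- function(e) {
  list(p1 = c(e$x_start, e$y_start),
       pm = c(e$x_mid, e$y_mid),
       p2 = c(e$x_end, e$y_end))
}

#' Classify a tape element as arc or line
#'
#' An element is a line iff the perpendicular distance of its mid point from
#' the start--end chord is below `tol_line`; otherwise it is a circular arc.
#'
#' @param e one-row `arc_elements` (or coercible list with the element
#'   point fields).
#' @param tol_line collinearity tolerance (mm), default 0.05.
#' @return `"line"` or `"arc"`.
#' @export
classify_element <- function(e, tol_line = 0.05) {
  stopifnot(tol_line > 0)
  p <- .elem_pts(e)
  if (all(p$p1 == p$p2)) stop("invalid element: p_start equals p_end")
  d <- abs(.signed_line_dist(p$pm[1], p$pm[2], p$p1, p$p2))
  if (d < tol_line) "line" else "arc"
}

#' Circumscribed circle through an arc element's three points
#'
#' @param e one-row `arc_elements` classified as an arc.
#' @return list with `center` (mm), `radius` (mm), `theta_start` (rad, angle
#'   of the start point about the center) and `sweep` (rad, signed swept
#'   angle from start to end, traversing the mid point; positive =
#'   counter-clockwise).
#' @export
fit_arc <- function(e) {
  p <- .elem_pts(e)
  u <- p$pm - p$p1
  v <- p$p2 - p$p1
  cr <- .cross2(u[1], u[2], v[1], v[2])
  scale <- max(abs(c(u, v)))
  if (abs(cr) < 1e-12 * max(scale^2, 1)) {
    stop("collinear element points: must be treated as a line")
  }
  # circumcenter from perpendicular-bisector linear system
  A <- rbind(2 * u, 2 * v)
  b <- c(sum(u^2), sum(v^2))
  cen_rel <- solve(A, b)
  center <- p$p1 + cen_rel
  radius <- sqrt(sum(cen_rel^2))
  a1 <- atan2(p$p1[2] - center[2], p$p1[1] - center[1])
  am <- atan2(p$pm[2] - center[2], p$pm[1] - center[1])
  a2 <- atan2(p$p2[2] - center[2], p$p2[1] - center[1])
  ccw_end <- (a2 - a1) %% (2 * pi)
  ccw_mid <- (am - a1) %% (2 * pi)
  sweep <- if (ccw_mid <= ccw_end) ccw_end else ccw_end - 2 * pi
  list(center = center, radius = radius, theta_start = a1, sweep = sweep)
}

#' Arclength of a tape element
#'
#' Chord length for line elements; radius times absolute swept angle for
#' arc elements.
#'
#' @inheritParams classify_element
#' @return length in mm.
#' @export
element_arclength <- function(e, tol_line = 0.05) {
  p <- .elem_pts(e)
  if (classify_element(e, tol_line) == "line") {
    sqrt(sum((p$p2 - p$p1)^2))
  } else {
    a <- fit_arc(e)
    a$radius * abs(a$sweep)
  }
}

# Sample n points along one element, with exact within-element arclength.
# Returns list(x, y, s).
.sample_element <- function(e, n = 20, tol_line = 0.05) {
  p <- .elem_pts(e)
  u <- seq(0, 1, length.out = n)
  if (classify_element(e, tol_line) == "line") {
    L <- sqrt(sum((p$p2 - p$p1)^2))
    list(x = p$p1[1] + u * (p$p2[1] - p$p1[1]),
         y = p$p1[2] + u * (p$p2[2] - p$p1[2]),
         s = u * L)
  } else {
    a <- fit_arc(e)
    th <- a$theta_start + u * a$sweep
    list(x = a$center[1] + a$radius * cos(th),
         y = a$center[2] + a$radius * sin(th),
         s = u * a$radius * abs(a$sweep))
  }
}

#' Read / write tape-element CSV
#'
#' CSV dialect: header `element_id,x_start,y_start,x_mid,y_mid,x_end,y_end`,
#' units mm, one row per element in tape order (cranial end first).
#'
#' @param path file path.
#' @param n_expected expected element count (the 870 mm tape yields 29);
#'   a differing count gives a warning, not an error.
#' @return `read_tape_csv`: an `arc_elements` object.
#' @export
read_tape_csv <- function(path, n_expected = 29) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element_id", "x_start", "y_start", "x_mid", "y_mid",
            "x_end", "y_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("tape CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (nm in need) {
    v <- df[[nm]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop("tape CSV parse error: non-numeric or empty '", nm,
           "' at row ", which(is.na(v))[1])
    }
    df[[nm]] <- v
  }
  if (!is.null(n_expected) && nrow(df) != n_expected) {
    warning("expected ", n_expected, " elements, found ", nrow(df))
  }
  arc_elements(df)
}

#' @rdname read_tape_csv
#' @param elements an `arc_elements` object.
#' @export
write_tape_csv <- function(elements, path) {
  stopifnot(inherits(elements, "arc_elements"))
  utils::write.csv(as.data.frame(elements), path, row.names = FALSE)
  invisible(path)
}
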