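# Post-processing of an equilibrium solution: regional contact-pressure
# peaks, contact area above a pressure threshold, intervertebral-disc
# stress proxies, and reporting arithmetic.

# node indices of the named pressure-report regions
.pressure_regions <- function(body) {
  nd <- body$nodes
  list(
    occiput  = which(nd$group == "head"),
    cervical = which(nd$group == "cervical"),
    scapula  = which(nd$name %in% paste0("T", 1:6)),
    buttock  = which(nd$name %in% c("L5", "sacrum")),
    calf     = which(nd$group == "shank"),
    heel     = which(nd$group == "heel")
  )
}

#' Contact-pressure profile and regional peaks
#'
#' @param r a converged `spinemat_equilibrium`.
#' @return list with `nodes` (data frame `name,x_mm,deflection_mm,
#'   pressure_kPa`) and `region_peaks_kPa` (named vector: occiput, cervical,
#'   scapula, buttock, calf, heel).
#' @export
contact_pressure_profile <- function(r) {
  stopifnot(inherits(r, "spinemat_equilibrium"))
  if (!r$converged) stop("equilibrium result is not converged")
  nd <- r$body$nodes
  regions <- .pressure_regions(r$body)
  peaks <- vapply(regions, function(idx) {
    if (length(idx)) max(r$pressure_kPa[idx]) else NA_real_
  }, numeric(1))
  list(nodes = data.frame(name = nd$name, x_mm = nd$x,
                          deflection_mm = r$deflection_mm,
                          pressure_kPa = r$pressure_kPa),
       region_peaks_kPa = peaks)
}

#' Contact area above a pressure threshold
#'
#' Sums the tributary area (node spacing x effective contact width) of the
#' nodes whose contact pressure exceeds `threshold_kPa`, split between the
#' pillow x-extent and the rest of the mattress.
#'
#' @param r a converged `spinemat_equilibrium`.
#' @param threshold_kPa pressure threshold (kPa), default 1.
#' @return list with `pillow_cm2`, `mattress_cm2`, `total_cm2`.
#' @export
contact_area <- function(r, threshold_kPa = 1) {
  stopifnot(inherits(r, "spinemat_equilibrium"))
  if (threshold_kPa < 0) stop("threshold must be non-negative")
  if (!r$converged) stop("equilibrium result is not converged")
  nd <- r$body$nodes
  hit <- r$pressure_kPa > threshold_kPa
  on_pillow <- rep(FALSE, nrow(nd))
  if (!is.null(r$surface$pillow)) {
    on_pillow <- nd$x >= r$surface$pillow_extent_mm[1] &
      nd$x <= r$surface$pillow_extent_mm[2]
  }
  a <- nd$area_mm2 / .units$mm2_per_cm2
  list(pillow_cm2 = sum(a[hit & on_pillow]),
       mattress_cm2 = sum(a[hit & !on_pillow]),
       total_cm2 = sum(a[hit]))
}

#' Intervertebral-disc stress proxy
#'
#' Converts joint axial force and bending moment into a per-disc stress
#' proxy, `|F| / A + |M| c / I`, using the disc geometry table carried by
#' the body model.  The moment at a disc is the mean of the bending moments
#' at its two adjacent nodes.  This is a loading *proxy* of a reduced
#' model: regional orderings and changes, not absolute disc pressures, are
#' the meaningful output.
#'
#' @param r a converged `spinemat_equilibrium`.
#' @param body body model (defaults to the one in `r`).
#' @return data frame `level, region, stress_kPa` with attribute
#'   `region_peaks_kPa` (named vector cervical/thoracic/lumbar).
#' @export
ivd_peak_stress <- function(r, body = r$body) {
  stopifnot(inherits(r, "spinemat_equilibrium"))
  discs <- body$discs
  if (any(is.na(discs$area_mm2))) stop("missing disc geometry")
  mom <- rep(0, nrow(body$nodes))
  mom[body$rotations$node] <- r$node_moment_Nmm
  F <- abs(r$joint_axial_N[discs$joint])
  M <- (abs(mom[discs$joint]) + abs(mom[discs$joint + 1])) / 2
  stress_Nmm2 <- F / discs$area_mm2 + M * discs$c_mm / discs$I_mm4
  out <- data.frame(level = discs$level, region = discs$region,
                    stress_kPa = stress_Nmm2 * .units$kPa_per_MPa)
  peaks <- tapply(out$stress_kPa, out$region, max)
  attr(out, "region_peaks_kPa") <-
    peaks[c("cervical", "thoracic", "lumbar")]
  out
}

#' Percent change between two loadings
#'
#' `(a - b) / b * 100`, reported both unrounded and rounded to the nearest
#' integer (the convention used when quoting peak-loading increases).
#'
#' @param a,b loadings (same units); `b` must be positive.
#' @return list with `percent` (rounded) and `percent_unrounded`.
#' @export
percent_change <- function(a, b) {
  if (any(b <= 0)) stop("reference value b must be positive")
  pc <- (a - b) / b * 100
  list(percent = round(pc), percent_unrounded = pc)
}
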