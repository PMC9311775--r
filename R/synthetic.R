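# Synthetic supine back profiles, simulated tape measurements and seeded
# cohorts.  The generator is the constructive inverse of the parameter
# extraction: it builds a smooth arclength-parameterised height profile
# whose extracted TI/HD/CLD/LLD reproduce the requested values, then tilts
# it by the requested torso inclination.

# C1 monotone "smoothed ramp" between (0, a) and (w, b): quadratic
# ease-in/out blends of fraction beta at each end, linear in between.
# Max |slope| = |b - a| / (w * (1 - beta)).
.ramp_eval <- function(tau, a, b, w, beta = 0.3) {
  u <- tau / w
  m <- (b - a) / (w * (1 - beta))
  h <- ifelse(u <= beta,
              a + m * w * u^2 / (2 * beta),
              ifelse(u < 1 - beta,
                     a + m * w * (u - beta / 2),
                     b - m * w * (1 - u)^2 / (2 * beta)))
  hp <- ifelse(u <= beta, m * u / beta,
               ifelse(u < 1 - beta, m, m * (1 - u) / beta))
  list(h = h, hp = hp)
}

# Shape knots (arclength, height) for a profile; conditional head knot when
# the head sits above the cervical apex.
.profile_knots <- function(HD, CLD, LLD, L, part) {
  t_ac <- L * (part$f1 + 0.6 * (part$f2 - part$f1))  # cervical apex
  k <- list()
  add <- function(k, t, h) c(k, list(c(t, h)))
  k <- add(k, 0, HD)
  if (HD > CLD) k <- add(k, L * part$f1, CLD)
  k <- add(k, t_ac, CLD)
  k <- add(k, L * (part$f2 + 0.55 * (part$f3 - part$f2)), 0)  # thoracic plateau
  k <- add(k, L * (part$f2 + 0.75 * (part$f3 - part$f2)), 0)
  k <- add(k, L * (part$f3 + part$f4) / 2, LLD)  # lumbar apex
  k <- add(k, L * (part$f4 + 0.25 * (part$f5 - part$f4)), 0)  # sacral plateau
  k <- add(k, L * (part$f4 + 0.85 * (part$f5 - part$f4)), 0)
  k <- add(k, L, 0)
  do.call(rbind, k)
}

# Maximum |dh/ds| over all ramp segments; the profile is realisable as an
# arclength-parameterised curve only if this stays below 1.
.profile_max_slope <- function(kn, beta = 0.3) {
  dw <- diff(kn[, 1])
  dh <- abs(diff(kn[, 2]))
  max(ifelse(dh == 0, 0, dh / (dw * (1 - beta))))
}

.check_profile_params <- function(TI_deg, HD_mm, CLD_mm, LLD_mm) {
  if (any(c(HD_mm, CLD_mm, LLD_mm) < 0)) stop("distances must be >= 0")
  if (TI_deg < 0 || TI_deg >= 45) stop("require 0 <= TI_deg < 45")
}

#' Is a spine-parameter quadruple realisable as a profile?
#'
#' Checks the slope-feasibility of the arclength-parameterised construction
#' used by [make_profile()] (the height profile must never be steeper than
#' the arclength parameterisation allows, |dh/ds| < 0.95).
#'
#' @inheritParams make_profile
#' @return `TRUE` or `FALSE`.
#' @export
profile_feasible <- function(TI_deg, HD_mm, CLD_mm, LLD_mm,
                             total_length_mm = 870,
                             part = region_partition()) {
  if (any(c(HD_mm, CLD_mm, LLD_mm) < 0) || TI_deg < 0 || TI_deg >= 45) {
    return(FALSE)
  }
  kn <- .profile_knots(HD_mm, CLD_mm, LLD_mm, total_length_mm, part)
  .profile_max_slope(kn) < 0.95
}

#' Construct a synthetic supine back profile with given spine parameters
#'
#' Builds a C1 height profile over arclength: the head point at `HD_mm`,
#' a cervical lobe peaking at `CLD_mm`, flat tangent plateaus in the thoracic
#' and sacral regions (realising the torso-inclination support line exactly),
#' and a lumbar lobe peaking at `LLD_mm`; the whole curve is then tilted by
#' `TI_deg` (caudal end towards the mattress).  Extraction with
#' [extract_spine_params()] under the same partition reproduces the inputs
#' to well within 1 mm / 0.2 degrees.
#'
#' @param TI_deg torso inclination (degrees, `0 <= TI < 45`).
#' @param HD_mm,CLD_mm,LLD_mm head / cervical-lordosis / lumbar-lordosis
#'   distances (mm, non-negative).
#' @param total_length_mm curve length (mm); the 870 mm tape is the default.
#' @param part a [region_partition].
#' @param spacing output point spacing (mm).
#' @return a [spinal_curve] with the ground-truth parameters attached as
#'   attribute `"params"`.
#' @export
make_profile <- function(TI_deg = 0, HD_mm = 0, CLD_mm = 0, LLD_mm = 0,
                         total_length_mm = 870, part = region_partition(),
                         spacing = 2) {
  .check_profile_params(TI_deg, HD_mm, CLD_mm, LLD_mm)
  L <- total_length_mm
  kn <- .profile_knots(HD_mm, CLD_mm, LLD_mm, L, part)
  if (.profile_max_slope(kn) >= 0.95) {
    stop("infeasible profile: height changes too steep for an arclength-",
         "parameterised curve (|dh/ds| >= 0.95)")
  }
  dt <- 0.5
  t <- seq(0, L, by = dt)
  if (t[length(t)] < L) t <- c(t, L)
  h <- hp <- numeric(length(t))
  for (seg in seq_len(nrow(kn) - 1)) {
    t0 <- kn[seg, 1]; t1 <- kn[seg + 1, 1]
    sel <- t >= t0 - 1e-12 & t <= t1 + 1e-12
    r <- .ramp_eval(pmin(pmax(t[sel] - t0, 0), t1 - t0),
                    kn[seg, 2], kn[seg + 1, 2], t1 - t0)
    h[sel] <- r$h
    hp[sel] <- r$hp
  }
  x <- .cumtrapz(t, sqrt(pmax(1 - hp^2, 0)))
  keep <- unique(c(seq(1, length(t), by = max(1L, round(spacing / dt))),
                   length(t)))
  crv <- spinal_curve(x[keep], h[keep], t[keep])
  crv <- transform_curve(crv, deg = -TI_deg)
  attr(crv, "params") <- c(TI_deg = TI_deg, HD_mm = HD_mm,
                           CLD_mm = CLD_mm, LLD_mm = LLD_mm)
  crv
}

#' Simulate a tape measurement of a back profile
#'
#' Cuts the curve into `n_elements` equal-arclength pieces; each piece's
#' start / mid / end arclength points become one three-point tape element.
#' Isotropic Gaussian noise of SD `noise_mm` is added per coordinate of the
#' `2 n + 1` sampled points before they are split into elements, so
#' adjacent elements share their (noisy) joint sensor point exactly, as on
#' the physical tape.  Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param c a [spinal_curve] of length at least `n_elements` mm.
#' @param n_elements number of tape elements (the 870 mm tape has 29).
#' @param noise_mm per-coordinate Gaussian noise SD (mm).
#' @return an [arc_elements] object.
#' @export
sample_tape <- function(c, n_elements = 29, noise_mm = 0) {
  L <- curve_length(c)
  if (L < n_elements * 1) stop("curve too short for ", n_elements, " elements")
  bp <- seq(0, L, length.out = 2 * n_elements + 1)
  px <- stats::approx(c$s, c$x, xout = bp)$y
  py <- stats::approx(c$s, c$y, xout = bp)$y
  if (noise_mm > 0) {
    px <- px + stats::rnorm(length(px), sd = noise_mm)
    py <- py + stats::rnorm(length(py), sd = noise_mm)
  }
  i0 <- seq(1, 2 * n_elements - 1, by = 2)
  arc_elements(data.frame(
    element_id = seq_len(n_elements) - 1L,
    x_start = px[i0],     y_start = py[i0],
    x_mid   = px[i0 + 1], y_mid   = py[i0 + 1],
    x_end   = px[i0 + 2], y_end   = py[i0 + 2]
  ))
}

#' Per-mattress spine-parameter distributions of the reference experiment
#'
#' Mean and SD of each spine parameter for the soft (SM), medium (MM) and
#' hard (HM) mattress conditions, as measured in the supine crossover
#' experiment the synthetic cohort emulates.
#'
#' @return named list of conditions; each is a list of `c(mean, sd)` per
#'   parameter.
#' @export
default_conditions <- function() {
  list(
    SM = list(TI_deg = c(6.86, 4.85), HD_mm = c(85.8, 21.5),
              CLD_mm = c(96.6, 18.3), LLD_mm = c(22.9, 6.5)),
    MM = list(TI_deg = c(3.64, 1.09), HD_mm = c(55.3, 8.9),
              CLD_mm = c(69.9, 6.8), LLD_mm = c(22.2, 4.8)),
    HM = list(TI_deg = c(1.56, 0.63), HD_mm = c(60.0, 11.0),
              CLD_mm = c(70.2, 6.3), LLD_mm = c(11.6, 5.2))
  )
}

#' Specify a synthetic crossover cohort
#'
#' @param n_participants number of participants (crossover design: every
#'   participant is measured under every condition).
#' @param conditions named list of per-condition parameter `(mean, sd)`
#'   pairs; see [default_conditions()].
#' @param seed integer seed fixing all randomness.
#' @param noise_mm tape point noise SD (mm).
#' @param rho fraction of each parameter's variance carried by a shared
#'   participant random effect (within-participant correlation across
#'   conditions).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 16, conditions = default_conditions(),
                        seed = 1L, noise_mm = 0.5, rho = 0.5) {
  stopifnot(n_participants >= 2, rho >= 0, rho <= 1, noise_mm >= 0)
  for (cn in names(conditions)) {
    for (pn in names(conditions[[cn]])) {
      if (conditions[[cn]][[pn]][2] < 0) stop("negative SD in condition ", cn)
    }
  }
  structure(list(n_participants = n_participants, conditions = conditions,
                 seed = as.integer(seed), noise_mm = noise_mm, rho = rho),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Per participant and condition, spine parameters are drawn from
#' truncated-at-zero normals with the condition's (mean, SD); correlation of
#' a participant's parameters across conditions is induced by a shared
#' participant random effect carrying fraction `rho` of the variance.
#' Draws that are infeasible for the profile constructor (or negative, or
#' TI outside [0, 45)) are re-sampled up to 100 times, then an error is
#' raised.  Fully reproducible given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param curves if `TRUE` also build, per cell, the synthetic back profile
#'   and its simulated tape measurement.
#' @param part a [region_partition] used by the profile constructor.
#' @return object of class `spinemat_cohort`: list with `params` (long data
#'   frame participant x condition x parameters), `curves` (nested list or
#'   `NULL`) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), curves = TRUE,
                            part = region_partition()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cn <- names(spec$conditions)
  pn <- c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm")
  rows <- list()
  crv <- if (curves) list() else NULL
  for (i in seq_len(spec$n_participants)) {
    z <- stats::rnorm(length(pn))
    names(z) <- pn
    if (curves) crv[[i]] <- list()
    for (cond in cn) {
      pars <- NULL
      for (attempt in seq_len(100)) {
        e <- stats::rnorm(length(pn))
        val <- vapply(seq_along(pn), function(k) {
          ms <- spec$conditions[[cond]][[pn[k]]]
          ms[1] + ms[2] * (sqrt(spec$rho) * z[k] + sqrt(1 - spec$rho) * e[k])
        }, numeric(1))
        names(val) <- pn
        ok <- profile_feasible(val["TI_deg"], val["HD_mm"], val["CLD_mm"],
                               val["LLD_mm"], part = part)
        if (ok) { pars <- val; break }
      }
      if (is.null(pars)) {
        stop("no feasible draw for participant ", i, ", condition ", cond,
             " after 100 attempts")
      }
      rows[[length(rows) + 1]] <- data.frame(
        participant = i, condition = cond,
        TI_deg = pars["TI_deg"], HD_mm = pars["HD_mm"],
        CLD_mm = pars["CLD_mm"], LLD_mm = pars["LLD_mm"],
        row.names = NULL)
      if (curves) {
        prof <- make_profile(pars["TI_deg"], pars["HD_mm"], pars["CLD_mm"],
                             pars["LLD_mm"], part = part)
        tape <- sample_tape(prof, n_elements = 29, noise_mm = spec$noise_mm)
        crv[[i]][[cond]] <- list(profile = prof, elements = tape)
      }
    }
  }
  params <- do.call(rbind, rows)
  params$condition <- factor(params$condition, levels = cn)
  structure(list(params = params, curves = crv, spec = spec),
            class = "spinemat_cohort")
}

#' @export
print.spinemat_cohort <- function(x, ...) {
  cat("<spinemat_cohort> ", x$spec$n_participants, " participants x ",
      length(x$spec$conditions), " conditions (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per participant/condition cell holding the tape CSV and a
#' params JSON, plus a cohort `manifest.csv`
#' (`participant,condition,TI_deg,HD_mm,CLD_mm,LLD_mm,seed`).
#'
#' @param cohort a `spinemat_cohort` generated with `curves = TRUE`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "spinemat_cohort"))
  if (is.null(cohort$curves)) stop("cohort was generated without curves")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$params
  for (r in seq_len(nrow(p))) {
    i <- p$participant[r]
    cond <- as.character(p$condition[r])
    cell <- file.path(dir, sprintf("participant_%02d", i), cond)
    dir.create(cell, recursive = TRUE, showWarnings = FALSE)
    write_tape_csv(cohort$curves[[i]][[cond]]$elements,
                   file.path(cell, "tape.csv"))
    jsonlite::write_json(as.list(p[r, c("TI_deg", "HD_mm", "CLD_mm",
                                        "LLD_mm")]),
                         file.path(cell, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  man <- cbind(p, seed = cohort$spec$seed)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}
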