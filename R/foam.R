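# Compressive foam material laws and Winkler-type foundation laws.
# A mattress (or pillow) slab of thickness t acts as independent vertical
# columns: a column compressed by deflection w carries stress law(w/t).
# Stacked slabs (pillow on mattress) act as springs in series: both layers
# carry the same stress and the layer deflections sum.

#' Compressive stress--strain data
#'
#' @param strain dimensionless compressive strains, starting at 0, strictly
#'   increasing, all below 1.
#' @param stress_kPa stress at each strain (kPa), starting at 0,
#'   non-decreasing.
#' @return object of class `stress_strain`, a data frame.
#' @export
stress_strain_curve <- function(strain, stress_kPa) {
  stopifnot(length(strain) == length(stress_kPa))
  if (strain[1] != 0 || stress_kPa[1] != 0) {
    stop("stress-strain data must start at (0, 0)")
  }
  if (any(diff(strain) <= 0)) stop("strains must be strictly increasing")
  if (max(strain) >= 1) stop("strains must be below 1")
  bad <- which(diff(stress_kPa) < 0)
  if (length(bad)) {
    stop("non-monotone stress at index ", bad[1] + 1)
  }
  structure(data.frame(strain = strain, stress_kPa = stress_kPa),
            class = c("stress_strain", "data.frame"))
}

#' Fit a monotone foam material law
#'
#' Monotone cubic interpolant (Hyman-filtered spline) through the measured
#' compressive stress--strain points, extended linearly beyond the last
#' measured strain using the terminal slope.  Exact at the data points.
#'
#' @param data a [stress_strain_curve()] (>= 4 points).
#' @param poisson Poisson ratio of the foam (near zero for open-cell
#'   polymer foams, justifying the independent-column reduction).
#' @param name material label.
#' @return object of class `foam_material` with a vectorised `law(strain)`
#'   returning kPa.
#' @export
fit_foam_law <- function(data, poisson = 0.01, name = "foam") {
  if (!inherits(data, "stress_strain")) {
    data <- stress_strain_curve(data$strain, data$stress_kPa)
  }
  if (nrow(data) < 4) stop("need at least 4 stress-strain points")
  eps_max <- max(data$strain)
  sf <- stats::splinefun(data$strain, data$stress_kPa, method = "hyman")
  slope_end <- sf(eps_max, deriv = 1)
  sig_max <- sf(eps_max)
  law <- function(eps) {
    out <- numeric(length(eps))
    inside <- eps <= eps_max
    out[inside] <- sf(pmax(eps[inside], 0))
    out[!inside] <- sig_max + slope_end * (eps[!inside] - eps_max)
    out
  }
  structure(list(law = law, poisson = poisson, name = name,
                 data = as.data.frame(data), eps_max = eps_max),
            class = "foam_material")
}

#' @export
print.foam_material <- function(x, ...) {
  cat("<foam_material> ", x$name, ": ", nrow(x$data),
      " points, sigma(0.25) = ", format(x$law(0.25), digits = 4),
      " kPa, nu = ", x$poisson, "\n", sep = "")
  invisible(x)
}

#' @export
plot.foam_material <- function(x, ...) {
  eps <- seq(0, x$eps_max, length.out = 200)
  graphics::plot(eps, x$law(eps), type = "l", xlab = "compressive strain",
                 ylab = "stress (kPa)", main = x$name, ...)
  graphics::points(x$data$strain, x$data$stress_kPa)
  invisible(x)
}

#' Surrogate 25% indentation load deflection
#'
#' Uniaxial surrogate of the IFD firmness test: the force on a flat indenter
#' of `indenter_area` when the slab is compressed to 25% strain,
#' `law(0.25) * area`, converted to pounds-force.  An approximation of the
#' standardised test (which involves a round indenter on a full slab), so
#' only firmness orderings -- not absolute pounds -- should be read off it.
#'
#' @param m a `foam_material`.
#' @param indenter_area_cm2 indenter area (cm^2); default 323 cm^2, the
#'   standard 50 in^2 IFD indenter.
#' @return force in lbf.
#' @export
ild_25 <- function(m, indenter_area_cm2 = 323) {
  stopifnot(inherits(m, "foam_material"), indenter_area_cm2 > 0)
  stress_kPa <- m$law(0.25)
  force_N <- stress_kPa * 1e-3 * indenter_area_cm2 * .units$mm2_per_cm2
  force_N / .units$N_per_lbf
}

#' Foundation law: foam slab(s) as a nonlinear vertical spring per unit area
#'
#' @param materials a `foam_material` or list of them (top layer first,
#'   e.g. pillow over mattress).
#' @param thickness_mm per-layer thickness (mm), recycled if scalar.
#' @return object of class `foundation_law`.
#' @export
foundation_law <- function(materials, thickness_mm) {
  if (inherits(materials, "foam_material")) materials <- list(materials)
  stopifnot(length(materials) >= 1, all(thickness_mm > 0))
  thickness_mm <- rep(thickness_mm, length.out = length(materials))
  structure(list(materials = materials, thickness_mm = thickness_mm,
                 total_thickness_mm = sum(thickness_mm)),
            class = "foundation_law")
}

#' @export
print.foundation_law <- function(x, ...) {
  cat("<foundation_law> ", length(x$materials), " layer(s), total ",
      x$total_thickness_mm, " mm: ",
      paste(vapply(x$materials, `[[`, "", "name"), x$thickness_mm,
            collapse = " over ", sep = " "), "\n", sep = "")
  invisible(x)
}

# strain in layer i carrying stress p (kPa); inverse of the layer law by
# monotone root solving
.layer_strain_at <- function(m, p, tol = 1e-9) {
  if (p <= 0) return(0)
  # bracket: extend beyond eps_max via the linear extension if needed
  hi <- 0.95
  while (m$law(hi) < p && hi < 50) hi <- hi * 2
  stats::uniroot(function(e) m$law(e) - p, c(0, hi), tol = tol)$root
}

#' Contact pressure of a foundation at a given deflection
#'
#' Single layer: `law(deflection / thickness)`.  Stacked layers: the unique
#' equal-stress (springs-in-series) split of the total deflection, found by
#' monotone root solving to 1e-6 kPa.
#'
#' @param f a [foundation_law()].
#' @param deflection_mm total surface deflection (mm); must be below 95% of
#'   the total thickness (densification limit).
#' @return pressure in kPa.
#' @export
foundation_pressure <- function(f, deflection_mm) {
  stopifnot(inherits(f, "foundation_law"))
  vapply(deflection_mm, function(w) {
    if (w < 0) stop("deflection must be non-negative")
    if (w >= 0.95 * f$total_thickness_mm) {
      stop("deflection ", w, " mm reaches the densification limit (95% of ",
           f$total_thickness_mm, " mm)")
    }
    if (w == 0) return(0)
    if (length(f$materials) == 1) {
      return(f$materials[[1]]$law(w / f$thickness_mm[1]))
    }
    # find stress p with sum_i t_i * strain_i(p) = w
    total_def <- function(p) {
      sum(vapply(seq_along(f$materials), function(i) {
        f$thickness_mm[i] * .layer_strain_at(f$materials[[i]], p)
      }, numeric(1)))
    }
    p_hi <- max(vapply(seq_along(f$materials), function(i) {
      f$materials[[i]]$law(w / f$thickness_mm[i])
    }, numeric(1)))  # stiffest single-layer stress bounds the answer
    while (total_def(p_hi) < w) p_hi <- p_hi * 2
    stats::uniroot(function(p) total_def(p) - w, c(0, p_hi),
                   tol = 1e-6)$root
  }, numeric(1))
}

# --- bundled synthetic material library ------------------------------------

# Typical open-cell-foam shape function: stiff elastic toe, long plateau to
# ~0.6 strain, then densification upturn.
.foam_shape <- function(eps) {
  (1 - exp(-eps / 0.06)) + 0.25 * (eps / (0.9 - eps))^3
}

#' Bundled synthetic mattress and pillow materials
#'
#' The reference experiment's foam stress--strain curves are published only
#' as a figure, so the package ships *synthetic* curves with a typical
#' hyperelastic-foam shape, calibrated so the [ild_25()] surrogate gives
#' 20 / 42 / 120 lbf for the soft (SM) / medium (MM) / hard (HM) mattress
#' and so the pillow law tracks the MM law.  Shipped as plain-text CSVs in
#' `inst/extdata/materials/` together with a registry YAML naming files,
#' thicknesses (mattress 200 mm, pillow 90 mm) and Poisson ratios.
#'
#' @param registry path to a material registry YAML; default: the bundled
#'   synthetic registry.
#' @return named list of `foam_material` objects with a `thickness_mm`
#'   attribute each.
#' @export
foam_library <- function(registry = system.file("extdata", "materials",
                                                "registry.yaml",
                                                package = "spinemat")) {
  reg <- yaml::read_yaml(registry)
  base <- dirname(registry)
  out <- list()
  for (nm in names(reg$materials)) {
    entry <- reg$materials[[nm]]
    df <- utils::read.csv(file.path(base, entry$file))
    m <- fit_foam_law(stress_strain_curve(df$strain, df$stress_kPa),
                      poisson = entry$poisson, name = nm)
    attr(m, "thickness_mm") <- entry$thickness_mm
    out[[nm]] <- m
  }
  out
}
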