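# Static equilibrium of the supine body chain on pillow + mattress
# foundations, by total-potential-energy minimisation over vertical nodal
# displacements:
#   E(y) = sum m_i g y_i                      (gravity, N.mm)
#        + sum 1/2 k_ax (L - L0)^2            (joint axial strain)
#        + sum 1/2 k_rot (theta - theta0)^2   (joint bending about rest shape)
#        + sum 1/2 k_lig max(0, L - L0)^2     (tension-only ligaments)
#        + sum A_i Phi_i(S_i - y_i)           (foundation strain energy)
# with Phi the integral of the (stacked) foam pressure-deflection law and
# unilateral contact (no tension).  x coordinates stay at their rest values:
# the body settles vertically, which removes the translational null space of
# a Winkler foundation and matches the fixed initial guess (rest profile
# lowered until first contact).

#' Define a sleeping support surface
#'
#' A mattress foundation over the full length, optionally with a pillow
#' foundation stacked on top of it over a limited x-extent near the head
#' (undeformed surface height = pillow thickness there).
#'
#' @param mattress a [foundation_law()], a `foam_material` (thickness taken
#'   from its `thickness_mm` attribute, default 200 mm), or a material name
#'   looked up in `library`.
#' @param pillow as `mattress`, or `NULL` for no pillow; default thickness
#'   90 mm (the cervical pillow height).
#' @param pillow_extent_mm x-interval covered by the pillow (mm); the
#'   default spans the 350 mm sagittal depth of the 550 x 350 mm pillow
#'   footprint, positioned with its caudal edge at the shoulder line
#'   (x = 190 mm) as a cervical pillow is used: head and neck supported,
#'   the cranial overhang unloaded, the upper back clear of the pillow.
#' @param pillow_spread stress attenuation factor for the mattress layer
#'   under the pillow: the pillow diffuses the narrow craniocervical load
#'   over its much larger base, so the mattress below sees only this
#'   fraction of the contact stress (the contact-to-base footprint ratio;
#'   a 272 cm^2 craniocervical contact over a 55 x 35 cm = 1925 cm^2 base
#'   gives ~0.14).
#' @param library named list of materials used to resolve character names;
#'   default [foam_library()].
#' @return object of class `support_surface`.
#' @export
support_surface <- function(mattress = "MM", pillow = "pillow",
                            pillow_extent_mm = c(-160, 190),
                            pillow_spread = 0.15,
                            library = NULL) {
  as_found <- function(m, default_thick) {
    if (is.character(m)) {
      if (is.null(library)) library <- foam_library()
      if (!m %in% names(library)) stop("unknown material: ", m)
      m <- library[[m]]
    }
    if (inherits(m, "foam_material")) {
      th <- attr(m, "thickness_mm")
      if (is.null(th)) th <- default_thick
      m <- foundation_law(m, th)
    }
    stopifnot(inherits(m, "foundation_law"))
    m
  }
  if (is.character(mattress) || is.character(pillow)) {
    if (is.null(library)) library <- foam_library()
  }
  mattress <- as_found(mattress, 200)
  if (!is.null(pillow)) {
    pillow <- as_found(pillow, 90)
    stopifnot(length(pillow_extent_mm) == 2,
              pillow_extent_mm[1] < pillow_extent_mm[2])
  }
  structure(list(mattress = mattress, pillow = pillow,
                 pillow_extent_mm = pillow_extent_mm,
                 pillow_spread = pillow_spread),
            class = "support_surface")
}

#' Pillow extent fitted to a body's shoulder line
#'
#' Positions the 350 mm pillow footprint so its caudal edge lies at the
#' body's shoulder line (midway between the C7 and T1 nodes), as a cervical
#' pillow is placed in practice.
#'
#' @param body a [build_default_body()] model.
#' @param depth_mm sagittal pillow depth (mm).
#' @return length-2 numeric x-interval (mm) for `pillow_extent_mm`.
#' @export
fit_pillow_extent <- function(body, depth_mm = 350) {
  x7 <- body$nodes$x[body$nodes$name == "C7"]
  x1 <- body$nodes$x[body$nodes$name == "T1"]
  edge <- (x7 + x1) / 2
  c(edge - depth_mm, edge)
}

#' @export
print.support_surface <- function(x, ...) {
  cat("<support_surface> mattress:", x$mattress$materials[[1]]$name,
      if (!is.null(x$pillow)) {
        paste0("; pillow: ", x$pillow$materials[[1]]$name, " over x = [",
               x$pillow_extent_mm[1], ", ", x$pillow_extent_mm[2], "] mm")
      } else "; no pillow", "\n")
  invisible(x)
}

# Precomputed pressure-deflection table for a (possibly stacked) foundation,
# in N/mm^2 vs mm, with cumulative strain-energy density Phi and a stiff
# linear barrier beyond the densification limit.
.stack_table <- function(materials, thicknesses, scale = 1, n = 600,
                         stress_factors = rep(1, length(materials))) {
  eg <- seq(0, 0.949, length.out = 2000)
  sig <- lapply(materials, function(m) m$law(eg) * 1e-3 * scale)  # N/mm^2
  p_max <- min(vapply(seq_along(sig),
                      function(i) max(sig[[i]]) / stress_factors[i],
                      numeric(1)))
  # stress grid: union of every layer's own stress values (so plateaus are
  # resolved at the strain-grid resolution) plus a quadratic fill
  p <- sort(unique(c(
    p_max * seq(0, 1, length.out = n)^2,
    unlist(lapply(seq_along(sig),
                  function(i) sig[[i]] / stress_factors[i])))))
  p <- p[p <= p_max]
  w <- rowSums(vapply(seq_along(materials), function(i) {
    thicknesses[i] *
      stats::approx(sig[[i]], eg, xout = p * stress_factors[i], rule = 2)$y
  }, numeric(length(p))))
  # strictly increasing w (drop ties from flat law regions)
  keep <- c(TRUE, diff(w) > 1e-12)
  w <- w[keep]; p <- p[keep]
  Phi <- .cumtrapz(w, p)
  nw <- length(w)
  slope_end <- (p[nw] - p[nw - 1]) / (w[nw] - w[nw - 1])
  list(w = w, p = p, Phi = Phi, wmax = w[nw], pmax = p[nw],
       Phimax = Phi[nw], barrier = max(slope_end, p[nw] / w[nw]) * 20)
}

# pressure and energy density at deflection d (vectorised); d <= 0 -> 0
.tab_eval <- function(tab, d) {
  p <- Phi <- numeric(length(d))
  pos <- d > 0
  if (any(pos)) {
    dp <- pmin(d[pos], tab$wmax)
    k <- pmax(findInterval(dp, tab$w), 1)
    k <- pmin(k, length(tab$w) - 1)
    dd <- dp - tab$w[k]
    sl <- (tab$p[k + 1] - tab$p[k]) / (tab$w[k + 1] - tab$w[k])
    p_in <- tab$p[k] + sl * dd
    Phi_in <- tab$Phi[k] + tab$p[k] * dd + 0.5 * sl * dd^2
    over <- d[pos] > tab$wmax
    if (any(over)) {
      ex <- d[pos][over] - tab$wmax
      p_in[over] <- tab$pmax + tab$barrier * ex
      Phi_in[over] <- tab$Phimax + tab$pmax * ex + 0.5 * tab$barrier * ex^2
    }
    p[pos] <- p_in
    Phi[pos] <- Phi_in
  }
  list(p = p, Phi = Phi)
}

# energy and gradient closure context
.make_ctx <- function(body, surface, g, stiffness_scale) {
  nd <- body$nodes
  n <- nrow(nd)
  m_tab <- .stack_table(surface$mattress$materials,
                        surface$mattress$thickness_mm, stiffness_scale)
  S <- rep(0, n)
  tab_id <- rep(1L, n)
  tabs <- list(m_tab)
  if (!is.null(surface$pillow)) {
    p_tab <- .stack_table(c(surface$pillow$materials,
                            surface$mattress$materials),
                          c(surface$pillow$thickness_mm,
                            surface$mattress$thickness_mm),
                          stiffness_scale,
                          stress_factors =
                            c(rep(1, length(surface$pillow$materials)),
                              rep(surface$pillow_spread,
                                  length(surface$mattress$materials))))
    tabs[[2]] <- p_tab
    on_pillow <- nd$x >= surface$pillow_extent_mm[1] &
      nd$x <= surface$pillow_extent_mm[2]
    tab_id[on_pillow] <- 2L
    S[on_pillow] <- surface$pillow$total_thickness_mm
  }
  list(x = nd$x, mass = nd$mass_kg, A = nd$area_mm2, S = S,
       tabs = tabs, tab_id = tab_id, g = g,
       joints = body$joints, rot = body$rotations, lig = body$ligaments,
       n = n)
}

.energy_grad <- function(y, ctx, want_grad = TRUE) {
  n <- ctx$n
  grad <- numeric(n)
  # gravity
  E <- ctx$g * sum(ctx$mass * y)
  if (want_grad) grad <- grad + ctx$g * ctx$mass
  # axial joints
  j <- ctx$joints
  if (nrow(j)) {
    dx <- ctx$x[j$to] - ctx$x[j$from]
    dy <- y[j$to] - y[j$from]
    L <- sqrt(dx^2 + dy^2)
    f <- j$k_ax * (L - j$L0)
    E <- E + sum(0.5 * f * (L - j$L0))
    if (want_grad) {
      gy <- f * dy / L
      grad <- grad + tapply2(j$to, gy, n) - tapply2(j$from, gy, n)
    }
  }
  # rotational joints
  r <- ctx$rot
  if (nrow(r)) {
    i <- r$node
    ux <- ctx$x[i] - ctx$x[i - 1]; uy <- y[i] - y[i - 1]
    vx <- ctx$x[i + 1] - ctx$x[i]; vy <- y[i + 1] - y[i]
    th <- atan2(vy, vx) - atan2(uy, ux)
    dth <- atan2(sin(th - r$theta0), cos(th - r$theta0))
    E <- E + sum(0.5 * r$k_rot * dth^2)
    if (want_grad) {
      mu <- ux / (ux^2 + uy^2)
      mv <- vx / (vx^2 + vy^2)
      kd <- r$k_rot * dth
      grad <- grad + tapply2(i - 1, kd * mu, n) +
        tapply2(i, kd * (-mu - mv), n) + tapply2(i + 1, kd * mv, n)
    }
  }
  # tension-only ligaments
  lg <- ctx$lig
  if (nrow(lg)) {
    dxl <- ctx$x[lg$to] - ctx$x[lg$from]
    dyl <- y[lg$to] - y[lg$from]
    Ll <- sqrt(dxl^2 + dyl^2)
    ext <- pmax(Ll - lg$L0, 0)
    E <- E + sum(0.5 * lg$k * ext^2)
    if (want_grad) {
      fl <- lg$k * ext * dyl / Ll
      grad <- grad + tapply2(lg$to, fl, n) - tapply2(lg$from, fl, n)
    }
  }
  # foundation (unilateral)
  d <- ctx$S - y
  for (tid in unique(ctx$tab_id)) {
    sel <- ctx$tab_id == tid
    ev <- .tab_eval(ctx$tabs[[tid]], d[sel])
    E <- E + sum(ctx$A[sel] * ev$Phi)
    if (want_grad) grad[sel] <- grad[sel] - ctx$A[sel] * ev$p
  }
  list(E = E, grad = grad)
}

# One full minimisation at a fixed foundation scale: chunked L-BFGS-B with
# analytic gradient, followed by damped-Newton residual polish when the
# energy stalls above the force tolerance.
.minimise_energy <- function(y, ctx, max_iter, tol_energy, tol_grad) {
  fn <- function(y) .energy_grad(y, ctx, want_grad = FALSE)$E
  gr <- function(y) .energy_grad(y, ctx)$grad
  eg <- .energy_grad(y, ctx)
  trace <- eg$E
  converged <- max(abs(eg$grad)) < tol_grad
  iter_used <- 0L
  chunk <- 250L
  while (!converged && iter_used < max_iter) {
    res <- stats::optim(y, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = 1e1,
                                       pgtol = tol_grad / 10))
    y <- res$par
    iter_used <- iter_used + chunk
    dE <- trace[length(trace)] - res$value
    if (res$value <= trace[length(trace)]) trace <- c(trace, res$value)
    gmax <- max(abs(gr(y)))
    if (gmax >= tol_grad) {
      # drive the residual down directly; cheap (n gradient evaluations per
      # Newton step) and essential for stiff configurations where the
      # quasi-Newton phase creeps
      pol <- .newton_polish(y, ctx, tol_grad)
      y <- pol$y
      gmax <- max(abs(pol$grad))
      E_pol <- fn(y)
      if (E_pol <= trace[length(trace)]) trace <- c(trace, E_pol)
    }
    if (gmax < tol_grad && dE < tol_energy * max(abs(res$value), 1)) {
      converged <- TRUE
    } else if (gmax < tol_grad && res$convergence == 0) {
      converged <- TRUE
    } else if (gmax >= tol_grad && res$convergence == 0 && dE <= 0) {
      break  # fully stalled; caller reports the diagnostic
    }
  }
  list(y = y, trace = trace, converged = converged)
}

# Damped-Newton polish on the gradient (residual force) once the quasi-Newton
# phase has flattened out: finite-difference Hessian of the analytic
# gradient, Levenberg damping, accepted on residual-norm decrease.  Near the
# minimum the energy itself changes below float resolution, so the residual
# norm is the only usable progress measure.
.newton_polish <- function(y, ctx, tol_grad, max_steps = 30) {
  g <- .energy_grad(y, ctx)$grad
  n <- length(y)
  for (step in seq_len(max_steps)) {
    gmax <- max(abs(g))
    if (gmax < tol_grad) break
    h <- 1e-6 * pmax(abs(y), 1)
    H <- matrix(0, n, n)
    for (k in seq_len(n)) {
      yk <- y
      yk[k] <- yk[k] + h[k]
      H[, k] <- (.energy_grad(yk, ctx)$grad - g) / h[k]
    }
    H <- (H + t(H)) / 2
    lambda <- 0
    improved <- FALSE
    for (try in 1:8) {
      d <- tryCatch(solve(H + diag(lambda, n), -g), error = function(e) NULL)
      if (!is.null(d)) {
        g_new <- .energy_grad(y + d, ctx)$grad
        if (max(abs(g_new)) < gmax) {
          y <- y + d
          g <- g_new
          improved <- TRUE
          break
        }
      }
      lambda <- if (lambda == 0) max(abs(diag(H))) * 1e-8 else lambda * 10
    }
    if (!improved) break
  }
  list(y = y, grad = g)
}

# sum values into an n-vector by index (fast aggregated scatter-add)
tapply2 <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Solve the supine body--support equilibrium
#'
#' Minimises the total potential energy of the body chain resting on the
#' support surface (see the package vignette for the model).  Deterministic:
#' the initial guess is the rest profile lowered until first contact, and no
#' randomness is involved.
#'
#' @param body a [build_default_body()] model.
#' @param surface a [support_surface()].
#' @param g gravitational acceleration (m/s^2).
#' @param max_iter maximum optimiser iterations before a diagnostic
#'   non-convergence error.
#' @param tol_energy convergence threshold on the relative energy decrease
#'   per iteration block.
#' @param tol_grad convergence threshold on the maximum nodal residual
#'   force (N).  For stiffness-scaled foundations the effective threshold
#'   is `tol_grad * sqrt(stiffness_scale)`: a foundation 1e6 times stiffer
#'   moves the attainable force resolution in double precision by the same
#'   factor.
#' @param stiffness_scale multiplier on the foundation law (e.g. `1e6` for
#'   a near-rigid foundation limit).
#' @return object of class `spinemat_equilibrium` with nodal deflections
#'   and contact pressures (kPa), per-joint axial forces (N) and moments
#'   (N mm), the deformed back-surface [spinal_curve], per-disc stress
#'   proxies, a non-increasing energy trace and a `converged` flag.
#' @export
solve_equilibrium <- function(body, surface, g = 9.81, max_iter = 5000,
                              tol_energy = 1e-8, tol_grad = 1e-6,
                              stiffness_scale = 1) {
  stopifnot(inherits(body, "body_model"), inherits(surface, "support_surface"))
  # continuation over foundation stiffness: very stiff foundations (rigid
  # limit) are solved through a deterministic ladder of intermediate scales,
  # each warm-starting the next; the reported energy trace is that of the
  # final (requested) scale
  scales <- stiffness_scale
  if (stiffness_scale > 10) {
    scales <- unique(c(1, 10^seq(1, log10(stiffness_scale), by = 1),
                       stiffness_scale))
  }
  tol_grad <- tol_grad * max(1, sqrt(stiffness_scale))
  ctx <- .make_ctx(body, surface, g, scales[1])
  y_rest <- body$nodes$y_rest
  # fixed initial guess: rest shape lowered (or raised) until first contact
  y <- y_rest - min(y_rest - ctx$S)
  for (sc in scales) {
    ctx <- .make_ctx(body, surface, g, sc)
    sol <- .minimise_energy(y, ctx, max_iter, tol_energy, tol_grad)
    y <- sol$y
  }
  if (!sol$converged) {
    stop("equilibrium solve did not converge within ", max_iter,
         " iterations (last max |residual| = ",
         format(max(abs(.energy_grad(y, ctx)$grad)), digits = 3),
         " N; energy trace: ",
         paste(format(utils::tail(sol$trace, 4), digits = 6),
               collapse = ", "), ")")
  }
  trace <- sol$trace
  converged <- sol$converged
  eg <- .energy_grad(y, ctx)
  d <- pmax(ctx$S - y, 0)
  p_Nmm2 <- numeric(ctx$n)
  for (tid in unique(ctx$tab_id)) {
    sel <- ctx$tab_id == tid
    p_Nmm2[sel] <- .tab_eval(ctx$tabs[[tid]], (ctx$S - y)[sel])$p
  }
  weight_N <- sum(ctx$mass) * g
  contact_N <- sum(p_Nmm2 * ctx$A)
  # joint forces and node moments
  j <- ctx$joints
  L <- sqrt((ctx$x[j$to] - ctx$x[j$from])^2 + (y[j$to] - y[j$from])^2)
  axial_N <- j$k_ax * (L - j$L0)
  r <- ctx$rot
  if (nrow(r)) {
    i <- r$node
    th <- atan2(y[i + 1] - y[i], ctx$x[i + 1] - ctx$x[i]) -
      atan2(y[i] - y[i - 1], ctx$x[i] - ctx$x[i - 1])
    moment_Nmm <- stats::setNames(
      r$k_rot * atan2(sin(th - r$theta0), cos(th - r$theta0)),
      body$nodes$name[i])
  } else {
    moment_Nmm <- numeric(0)
  }
  sp_n <- sum(body$nodes$group %in% c("head", "cervical", "thoracic",
                                      "lumbar", "sacrum"))
  res <- structure(list(
    body = body, surface = surface, g = g,
    y = y, deflection_mm = d, pressure_kPa = p_Nmm2 * 1e3,
    joint_axial_N = axial_N,
    node_moment_Nmm = moment_Nmm,
    curve = if (sp_n >= 4) .equilibrium_curve(body, y) else NULL,
    converged = converged, energy_trace = trace,
    weight_N = weight_N, contact_force_N = contact_N,
    balance_rel = abs(contact_N - weight_N) / weight_N,
    residual_N = eg$grad
  ), class = "spinemat_equilibrium")
  if (!is.null(body$discs)) res$disc_stress <- ivd_peak_stress(res)
  res
}

# Deformed back-surface proxy through the spine nodes, extended caudally
# towards the thigh so the curve spans the same fraction of the body as the
# measurement tape (the sacrum node sits at 82% of tape length); without the
# extension the arclength region partition would be misaligned.
.equilibrium_curve <- function(body, y) {
  sp <- which(body$nodes$group %in% c("head", "cervical", "thoracic",
                                      "lumbar", "sacrum"))
  xs <- body$nodes$x[sp]
  ys <- y[sp]
  i_th <- which(body$nodes$group == "thigh")[1]
  s_sac <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
  ext <- s_sac * (1 - 0.82) / 0.82  # tape continues past the sacrum
  u <- c(1, 2, 3) / 3
  dir <- c(body$nodes$x[i_th] - xs[length(xs)], y[i_th] - ys[length(ys)])
  dir <- dir / sqrt(sum(dir^2))
  xs <- c(xs, xs[length(xs)] + u * ext * dir[1])
  ys <- c(ys, ys[length(ys)] + u * ext * dir[2])
  s <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  # linear interpolation: added points lie on the node polyline, so the
  # tangent-line construction is determined by the nodes themselves (a
  # spline would overshoot at contact kinks and add extraction noise)
  s_new <- seq(0, max(s), by = 2)
  if (s_new[length(s_new)] < max(s)) s_new <- c(s_new, max(s))
  spinal_curve(stats::approx(s, xs, xout = s_new)$y,
               stats::approx(s, ys, xout = s_new)$y)
}

#' @export
print.spinemat_equilibrium <- function(x, ...) {
  cat("<spinemat_equilibrium> ",
      if (x$converged) "converged" else "NOT converged",
      "; weight ", format(x$weight_N, digits = 5), " N, contact force ",
      format(x$contact_force_N, digits = 5), " N (balance ",
      format(100 * x$balance_rel, digits = 2), "%)\n", sep = "")
  cat("  peak pressure ", format(max(x$pressure_kPa), digits = 4),
      " kPa; max deflection ", format(max(x$deflection_mm), digits = 4),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
summary.spinemat_equilibrium <- function(object, ...) {
  out <- list(
    converged = object$converged,
    weight_N = object$weight_N,
    balance_rel = object$balance_rel,
    region_peaks_kPa = contact_pressure_profile(object)$region_peaks_kPa,
    contact_area_cm2 = contact_area(object),
    disc_region_peaks_kPa = attr(object$disc_stress, "region_peaks_kPa"),
    spine_params = extract_spine_params(object$curve)
  )
  class(out) <- "summary.spinemat_equilibrium"
  out
}

#' @export
print.summary.spinemat_equilibrium <- function(x, ...) {
  cat("Supine equilibrium summary (", if (x$converged) "converged" else
    "NOT converged", ")\n", sep = "")
  cat(sprintf("  weight %.1f N, force balance error %.3g%%\n",
              x$weight_N, 100 * x$balance_rel))
  cat("  regional peak contact pressure (kPa):\n")
  print(round(x$region_peaks_kPa, 2))
  cat("  contact area (cm^2): pillow ", round(x$contact_area_cm2$pillow_cm2),
      ", mattress ", round(x$contact_area_cm2$mattress_cm2), "\n", sep = "")
  cat("  disc stress proxy peaks (kPa):\n")
  print(round(x$disc_region_peaks_kPa, 1))
  cat("  deformed-curve spine parameters:\n")
  print(x$spine_params)
  invisible(x)
}

#' @export
plot.spinemat_equilibrium <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  nd <- x$body$nodes
  graphics::plot(nd$x, x$y, type = "o", pch = 16, cex = 0.6,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = "deformed body chain")
  graphics::lines(nd$x, nd$y_rest - min(nd$y_rest), lty = 3)
  S <- rep(0, nrow(nd))
  if (!is.null(x$surface$pillow)) {
    on_p <- nd$x >= x$surface$pillow_extent_mm[1] &
      nd$x <= x$surface$pillow_extent_mm[2]
    S[on_p] <- x$surface$pillow$total_thickness_mm
  }
  graphics::lines(nd$x, S, col = "grey50")
  graphics::plot(nd$x, x$pressure_kPa, type = "h", lwd = 3,
                 xlab = "x (mm)", ylab = "contact pressure (kPa)",
                 main = "nodal contact pressure")
  invisible(x)
}

#' @export
residuals.spinemat_equilibrium <- function(object, ...) {
  stats::setNames(object$residual_N, object$body$nodes$name)
}
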