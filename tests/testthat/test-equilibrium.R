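# Energy-minimising equilibrium solver: limit cases, invariants, oracles.

# minimal hand-built body: a single point mass on one foundation column
point_body <- function(mass_kg = 10, area_mm2 = 1e4, x = 100, y_rest = 50) {
  structure(list(
    nodes = data.frame(name = "head", group = "head", x = x, y_rest = y_rest,
                       mass_kg = mass_kg, width_mm = 100, trib_mm = 100,
                       area_mm2 = area_mm2),
    joints = data.frame(from = integer(0), to = integer(0),
                        group = character(0), k_ax = numeric(0),
                        L0 = numeric(0)),
    rotations = data.frame(node = integer(0), k_rot = numeric(0),
                           theta0 = numeric(0)),
    ligaments = data.frame(from = integer(0), to = integer(0),
                           k = numeric(0), L0 = numeric(0)),
    discs = NULL, height_cm = NA, mass_kg = mass_kg),
    class = "body_model")
}

stiff_body <- function(height_cm = 176, mass_kg = 74) {
  st <- spinemat:::.default_stiffness()
  st$k_rot <- st$k_rot * 1e5
  st$k_ax <- st$k_ax * 10
  build_default_body(height_cm, mass_kg, stiffness = st)
}

test_that("zero gravity leaves the rest shape untouched with zero pressure", {
  b <- build_default_body()
  surf <- support_surface("MM", "pillow", library = test_lib())
  r <- solve_equilibrium(b, surf, g = 0)
  expect_true(r$converged)
  expect_equal(max(r$pressure_kPa), 0)
  # rest profile merely shifted to first contact
  shift <- r$y - b$nodes$y_rest
  expect_lt(diff(range(shift)), 1e-9)
})

test_that("a single point mass settles where load balances the column law", {
  lib <- test_lib()
  for (mass in c(5, 20, 60)) {
    b <- point_body(mass_kg = mass)
    r <- solve_equilibrium(b, support_surface("MM", NULL, library = lib))
    f <- foundation_law(lib$MM, 200)
    w_ref <- uniroot(function(w) {
      foundation_pressure(f, w) * 1e-3 * 1e4 - mass * 9.81
    }, c(0, 189), tol = 1e-9)$root
    expect_lt(abs(max(r$deflection_mm) - w_ref), 0.05)
    expect_lt(abs(r$contact_force_N - mass * 9.81), 1e-6)
  }
})

test_that("the rigid-foundation limit pins deflections and the rest shape", {
  lib <- test_lib()
  # a shape-holding (stiffened) body on a near-rigid mattress reproduces
  # its rest profile and lies flat
  sb <- stiff_body()
  rr <- solve_equilibrium(sb, support_surface("MM", NULL, library = lib),
                          stiffness_scale = 1e6)
  expect_lt(max(rr$deflection_mm), 0.5)
  rest <- sb$nodes$y_rest - min(sb$nodes$y_rest)
  expect_lt(max(abs(rr$y - rest)), 0.5)
  ti_rigid <- extract_spine_params(rr$curve)$TI_deg
  expect_lt(ti_rigid, 0.05)
  # the same body on the compliant soft mattress tilts more
  rs <- solve_equilibrium(sb, support_surface("SM", NULL, library = lib))
  expect_gt(extract_spine_params(rs$curve)$TI_deg, ti_rigid)
  # the default (draping) body still shows near-zero penetration
  rd <- solve_equilibrium(build_default_body(),
                          support_surface("MM", NULL, library = lib),
                          stiffness_scale = 1e6)
  expect_lt(max(rd$deflection_mm), 0.5)
})

test_that("converged solutions balance contact force against body weight", {
  lib <- test_lib()
  set.seed(19)
  for (k in 1:5) {
    b <- build_default_body(runif(1, 150, 200), runif(1, 45, 110))
    mat <- sample(c("SM", "MM", "HM"), 1)
    r <- solve_equilibrium(b, support_surface(mat, "pillow",
                                              pillow_extent_mm =
                                                fit_pillow_extent(b),
                                              library = lib))
    expect_true(r$converged)
    expect_lt(r$balance_rel, 0.005)
    expect_true(all(diff(r$energy_trace) <= 0))
    expect_true(all(r$pressure_kPa >= 0))
  }
})

test_that("identical inputs give bit-identical equilibria", {
  b <- build_default_body()
  surf <- support_surface("MM", "pillow", library = test_lib())
  r1 <- solve_equilibrium(b, surf)
  r2 <- solve_equilibrium(b, surf)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$energy_trace, r2$energy_trace)
})

test_that("a pointwise-softer mattress spreads load and eases the buttock", {
  lib <- test_lib()
  set.seed(23)
  for (k in 1:3) {
    b <- build_default_body(runif(1, 155, 195), runif(1, 50, 100))
    pe <- fit_pillow_extent(b)
    soft <- scaled_material(lib$MM, runif(1, 0.3, 0.8))
    rs <- solve_equilibrium(b, support_surface(soft, "pillow",
                                               pillow_extent_mm = pe,
                                               library = lib))
    rh <- solve_equilibrium(b, support_surface(lib$MM, "pillow",
                                               pillow_extent_mm = pe,
                                               library = lib))
    expect_gte(contact_area(rs)$total_cm2, contact_area(rh)$total_cm2)
    expect_lte(contact_pressure_profile(rs)$region_peaks_kPa["buttock"],
               contact_pressure_profile(rh)$region_peaks_kPa["buttock"])
  }
})

test_that("residuals expose the nodal force imbalance of the fit", {
  b <- build_default_body()
  r <- solve_equilibrium(b, support_surface("MM", "pillow",
                                            library = test_lib()))
  res <- residuals(r)
  expect_named(res, b$nodes$name)
  expect_lt(max(abs(res)), 1e-6)
})
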