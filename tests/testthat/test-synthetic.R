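# Synthetic profile generator, tape simulator and cohort generator.

test_that("degenerate all-zero parameters give a straight tape-length line", {
  crv <- make_profile(0, 0, 0, 0)
  expect_equal(curve_length(crv), 870)
  expect_true(all(abs(crv$y) < 1e-12))
  sp <- extract_spine_params(crv)
  expect_equal(c(sp$TI_deg, sp$HD_mm, sp$CLD_mm, sp$LLD_mm), rep(0, 4),
               tolerance = 1e-9)
})

test_that("a medium-mattress-like profile round-trips through extraction", {
  crv <- make_profile(3.64, 55.3, 69.9, 22.2)
  sp <- extract_spine_params(crv)
  expect_equal(sp$TI_deg, 3.64, tolerance = 0.2)
  expect_equal(sp$HD_mm, 55.3, tolerance = 1)
  expect_equal(sp$CLD_mm, 69.9, tolerance = 1)
  expect_equal(sp$LLD_mm, 22.2, tolerance = 1)
})

test_that("random feasible parameters round-trip within 1 mm / 0.2 degrees", {
  set.seed(15)
  for (p in random_feasible_params(25)) {
    sp <- extract_spine_params(make_profile(p["TI"], p["HD"], p["CLD"],
                                            p["LLD"]))
    expect_lt(abs(sp$TI_deg - p["TI"]), 0.2)
    expect_lt(abs(sp$HD_mm - p["HD"]), 1)
    expect_lt(abs(sp$CLD_mm - p["CLD"]), 1)
    expect_lt(abs(sp$LLD_mm - p["LLD"]), 1)
  }
})

test_that("unrealisable parameter combinations raise an infeasible-profile error", {
  expect_error(make_profile(0, 150, 40, 20), "infeasible")
  expect_false(profile_feasible(0, 150, 40, 20))
  expect_error(make_profile(-1, 50, 60, 20), "TI")
  expect_error(make_profile(5, -3, 60, 20), ">= 0")
})

test_that("a straight line samples into collinear 30 mm line elements", {
  line <- spinal_curve(seq(0, 870, by = 1), rep(0, 871))
  els <- sample_tape(line, 29, noise_mm = 0)
  expect_equal(nrow(els), 29)
  for (i in seq_len(29)) {
    expect_identical(classify_element(els[i, ]), "line")
    expect_equal(element_arclength(els[i, ]), 30, tolerance = 1e-9)
  }
})

test_that("tape sampling of a 200 mm circle reconstructs its diameter to <1%", {
  r <- 100
  th <- seq(0, 2 * pi * 0.9, length.out = 2000)
  circ <- spinal_curve(r * cos(th), r * sin(th))
  els <- sample_tape(circ, 29, noise_mm = 0)
  rec <- chain_elements(els)
  fit <- fit_circle(rec)
  expect_lt(abs(fit$diameter - 200) / 200, 0.01)
})

test_that("noise-free sample-then-chain is the identity within 0.2 mm Hausdorff", {
  # smooth cohort-scale profiles: a 30 mm element tape cannot resolve
  # curvature radii below its own element length, so the fidelity bound
  # applies to realistic back profiles, not extreme corner cases
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 21,
                                    noise_mm = 0), curves = FALSE)
  for (i in seq_len(3)) {
    p <- co$params[co$params$condition == "MM", ][i, ]
    crv <- make_profile(p$TI_deg, p$HD_mm, p$CLD_mm, p$LLD_mm)
    rec <- chain_elements(sample_tape(crv, 29, noise_mm = 0))
    expect_lt(oracle_hausdorff(rec$x, rec$y, crv$x, crv$y), 0.2)
  }
})

test_that("an SD-0 cohort reproduces the condition means exactly", {
  conds <- default_conditions()
  for (cn in names(conds)) {
    for (pn in names(conds[[cn]])) conds[[cn]][[pn]][2] <- 0
  }
  co <- generate_cohort(cohort_spec(n_participants = 4, conditions = conds,
                                    seed = 3, noise_mm = 0), curves = FALSE)
  for (cn in names(conds)) {
    sub <- co$params[co$params$condition == cn, ]
    for (pn in names(conds[[cn]])) {
      expect_equal(sub[[pn]], rep(conds[[cn]][[pn]][1], 4))
    }
  }
})

test_that("cohorts are deterministic given the seed", {
  a <- generate_cohort(cohort_spec(n_participants = 4, seed = 11), curves = TRUE)
  b <- generate_cohort(cohort_spec(n_participants = 4, seed = 11), curves = TRUE)
  expect_identical(a$params, b$params)
  expect_identical(a$curves[[2]][["MM"]]$elements,
                   b$curves[[2]][["MM"]]$elements)
  c2 <- generate_cohort(cohort_spec(n_participants = 4, seed = 12), curves = FALSE)
  expect_false(identical(a$params$HD_mm, c2$params$HD_mm))
})

test_that("large-cohort sample moments recover the specified distributions", {
  co <- generate_cohort(cohort_spec(n_participants = 2000, seed = 8),
                        curves = FALSE)
  sm <- co$params[co$params$condition == "SM", ]
  # soft-mattress head distance: mean 85.8, SD 21.5
  expect_lt(abs(mean(sm$HD_mm) - 85.8), 2 * 21.5 / sqrt(2000))
  expect_lt(abs(sd(sm$HD_mm) - 21.5), 1.5)
  mm <- co$params[co$params$condition == "MM", ]
  expect_lt(abs(mean(mm$CLD_mm) - 69.9), 2 * 6.8 / sqrt(2000))
  # all draws respect the physical bounds
  expect_true(all(co$params$HD_mm >= 0 & co$params$CLD_mm >= 0 &
                    co$params$LLD_mm >= 0))
  expect_true(all(co$params$TI_deg >= 0 & co$params$TI_deg < 45))
})

test_that("the participant random effect correlates a participant across conditions", {
  co <- generate_cohort(cohort_spec(n_participants = 400, seed = 5, rho = 0.5),
                        curves = FALSE)
  wide <- reshape(co$params[, c("participant", "condition", "HD_mm")],
                  idvar = "participant", timevar = "condition",
                  direction = "wide")
  r <- cor(wide$HD_mm.SM, wide$HD_mm.MM)
  expect_gt(r, 0.25)  # rho = 0.5 shared variance
})

test_that("cohorts write a manifest and per-cell tape files", {
  co <- generate_cohort(cohort_spec(n_participants = 2, seed = 2), curves = TRUE)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(man))
  m <- read.csv(man)
  expect_equal(nrow(m), 6)
  expect_true(all(c("participant", "condition", "TI_deg", "HD_mm",
                    "CLD_mm", "LLD_mm", "seed") %in% names(m)))
  tape <- file.path(dir, "participant_01", "SM", "tape.csv")
  expect_true(file.exists(tape))
  expect_equal(nrow(read_tape_csv(tape)), 29)
})
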