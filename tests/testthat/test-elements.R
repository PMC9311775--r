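# Tape arc/line elements: classification, circle fitting, arclength, CSV IO.

elem <- function(p1, pm, p2) {
  arc_elements(data.frame(element_id = 0L,
                          x_start = p1[1], y_start = p1[2],
                          x_mid = pm[1], y_mid = pm[2],
                          x_end = p2[1], y_end = p2[2]))
}

test_that("elements classify as line or arc by mid-point offset from the chord", {
  expect_identical(classify_element(elem(c(0, 0), c(1, 0), c(2, 0))), "line")
  expect_identical(classify_element(elem(c(0, 0), c(1, 1), c(2, 0))), "arc")
  # mid point 0.01 mm off the chord (verified by the point-line formula)
  e <- elem(c(0, 0), c(1, 0.01), c(2, 0))
  expect_equal(oracle_point_line_dist(c(1, 0.01), c(0, 0), c(2, 0)), 0.01)
  expect_identical(classify_element(e, tol_line = 0.05), "line")
  expect_identical(classify_element(e, tol_line = 0.005), "arc")
  expect_error(arc_elements(data.frame(element_id = 0, x_start = 1,
                                       y_start = 1, x_mid = 1, y_mid = 2,
                                       x_end = 1, y_end = 1)),
               "p_start equals p_end")
})

test_that("fit_arc recovers the circumscribed circle and traverses the mid point", {
  a <- fit_arc(elem(c(0, 0), c(1, 1), c(2, 0)))
  expect_equal(a$center, c(1, 0), tolerance = 1e-12)
  expect_equal(a$radius, 1, tolerance = 1e-12)
  # mirror case: the span traverses below the chord, opposite sweep sign
  b <- fit_arc(elem(c(0, 0), c(1, -1), c(2, 0)))
  expect_equal(b$center, c(1, 0), tolerance = 1e-12)
  expect_equal(b$radius, 1, tolerance = 1e-12)
  expect_true(sign(a$sweep) != sign(b$sweep))
  # the mid-sweep point must be the element's mid point
  mid_a <- a$center + a$radius *
    c(cos(a$theta_start + a$sweep / 2), sin(a$theta_start + a$sweep / 2))
  expect_equal(mid_a, c(1, 1), tolerance = 1e-9)
  expect_error(fit_arc(elem(c(0, 0), c(1, 0), c(2, 0))), "line")
})

test_that("fit_arc matches the perpendicular-bisector oracle on random points", {
  set.seed(101)
  for (k in 1:20) {
    pts <- matrix(runif(6, -50, 50), 3, 2)
    cr <- abs((pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
                (pts[2, 2] - pts[1, 2]) * (pts[3, 1] - pts[1, 1]))
    if (cr < 1) next  # skip near-collinear draws
    a <- fit_arc(elem(pts[1, ], pts[2, ], pts[3, ]))
    cen <- oracle_circumcenter(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(a$center, cen, tolerance = 1e-8)
    for (i in 1:3) {
      expect_equal(sqrt(sum((pts[i, ] - a$center)^2)), a$radius,
                   tolerance = 1e-9)
    }
  }
})

test_that("element arclength is the chord for lines and r|sweep| for arcs", {
  expect_equal(element_arclength(elem(c(0, 0), c(1, 0), c(2, 0))), 2)
  expect_equal(element_arclength(elem(c(0, 0), c(1, 1), c(2, 0))), pi,
               tolerance = 1e-12)
  # semicircle of radius 100 vs dense polyline oracle
  e <- elem(c(0, 0), c(100, 100), c(200, 0))
  th <- seq(pi, 0, length.out = 20001)
  poly <- sum(sqrt(diff(100 + 100 * cos(th))^2 + diff(100 * sin(th))^2))
  expect_equal(element_arclength(e), 100 * pi, tolerance = 1e-12)
  expect_equal(element_arclength(e), poly, tolerance = 1e-7)
})

test_that("tape CSV round-trips, warns on short tapes and errors on bad cells", {
  set.seed(7)
  crv <- make_profile(4, 60, 75, 25)
  els <- sample_tape(crv, 29, noise_mm = 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tape_csv(els, path)
  back <- read_tape_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(els), tolerance = 1e-12)

  short <- as.data.frame(els)[1:28, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(short, path2, row.names = FALSE)
  expect_warning(read_tape_csv(path2), "expected 29")
  expect_silent(read_tape_csv(path2, n_expected = 28))

  bad <- as.data.frame(els)
  bad$y_mid[13] <- NA
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path3, row.names = FALSE)
  expect_error(read_tape_csv(path3), "y_mid.*row 13")

  expect_error(read_tape_csv(path3, n_expected = NULL), "y_mid")
  nocol <- as.data.frame(els)[, -3]
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(nocol, path4, row.names = FALSE)
  expect_error(read_tape_csv(path4), "missing column")

  dup <- as.data.frame(els)
  dup$element_id[2] <- 0L
  expect_error(arc_elements(dup), "duplicate|ordered")
})
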