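# Paired contrasts, Pearson validation, pipeline orchestration.

sd0_conditions <- function() {
  conds <- default_conditions()
  for (cn in names(conds)) {
    for (pn in names(conds[[cn]])) conds[[cn]][[pn]][2] <- 0
  }
  conds
}

test_that("an SD-0 cohort reproduces the printed between-mattress differences", {
  co <- generate_cohort(cohort_spec(n_participants = 16,
                                    conditions = sd0_conditions(),
                                    seed = 1, noise_mm = 0), curves = FALSE)
  ct <- paired_contrasts(co$params)
  get <- function(par, pair) ct$mean_diff[ct$parameter == par & ct$pair == pair]
  expect_equal(get("HD_mm", "SM-MM"), 30.5, tolerance = 1e-9)
  expect_equal(get("CLD_mm", "SM-MM"), 26.7, tolerance = 1e-9)
  expect_equal(get("LLD_mm", "MM-HM"), 10.6, tolerance = 1e-9)
  expect_true(all(ct$p_adj >= ct$p_value))
  expect_equal(nrow(ct), 4 * choose(3, 2))
})

test_that("identical conditions give zero differences and p = 1", {
  conds <- sd0_conditions()[c("MM", "MM")]
  names(conds) <- c("A", "B")
  co <- generate_cohort(cohort_spec(n_participants = 5, conditions = conds,
                                    seed = 2, noise_mm = 0), curves = FALSE)
  ct <- paired_contrasts(co$params)
  expect_true(all(ct$mean_diff == 0))
  expect_true(all(ct$p_value == 1))
})

test_that("the paired t statistic equals the hand-computed mean/SE ratio", {
  co <- generate_cohort(cohort_spec(n_participants = 16, seed = 4),
                        curves = FALSE)
  ct <- paired_contrasts(co$params)
  wide <- reshape(co$params[, c("participant", "condition", "HD_mm")],
                  idvar = "participant", timevar = "condition",
                  direction = "wide")
  d <- wide$HD_mm.SM - wide$HD_mm.MM
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(ct$statistic[ct$parameter == "HD_mm" & ct$pair == "SM-MM"],
               t_ref, tolerance = 1e-12)
})

test_that("incomplete crossover tables are rejected with the missing cell named", {
  co <- generate_cohort(cohort_spec(n_participants = 4, seed = 6),
                        curves = FALSE)
  broken <- co$params[-2, ]  # drop participant 1's second condition
  expect_error(paired_contrasts(broken), "participant 1.*missing")
})

test_that("a single condition yields an empty contrast table without error", {
  co <- generate_cohort(cohort_spec(n_participants = 4,
                                    conditions = default_conditions()["MM"],
                                    seed = 3), curves = FALSE)
  ct <- paired_contrasts(co$params)
  expect_equal(nrow(ct), 0)
})

test_that("Pearson validation labels strong linear relationships", {
  x <- 1:10
  v <- validate_correlation(2 * x + 1, x)
  expect_equal(v$r, 1)
  expect_equal(v$strength, "strong")
  v2 <- validate_correlation(-x, x)
  expect_equal(v2$r, -1)
  expect_equal(v2$strength, "not strong")
  set.seed(31)
  a <- rnorm(50); b <- a + rnorm(50, sd = 0.5)
  r_ref <- cov(a, b) / sqrt(var(a) * var(b))
  expect_equal(validate_correlation(a, b)$r, r_ref, tolerance = 1e-12)
  expect_error(validate_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(validate_correlation(1:2, 1:2), "at least 3")
})

test_that("the validation sweep pools predictions against ground truth", {
  vs <- validation_sweep(n_per_condition = 2, seed = 9, library = test_lib())
  expect_equal(nrow(vs$table), 2 * 3 * 4)
  expect_true(is.finite(vs$r))
  expect_setequal(unique(vs$table$parameter),
                  c("TI_deg", "HD_mm", "CLD_mm", "LLD_mm"))
})

test_that("the pipeline runs end-to-end and writes a complete bundle", {
  dir <- withr::local_tempdir()
  rep <- run_pipeline(config = list(n_participants = 4), seed = 7,
                      out_dir = dir)
  expect_s3_class(rep, "spinemat_report")
  expect_true(all(file.exists(file.path(dir, c(
    "manifest.csv", "measured_params.csv", "contrasts.csv",
    "mechanics.json", "report.json")))))
  long <- read.csv(file.path(dir, "measured_params.csv"))
  expect_equal(nrow(long), 4 * 3 * 4)
  mech <- jsonlite::read_json(file.path(dir, "mechanics.json"))
  expect_setequal(names(mech), c("SM", "MM", "HM"))
  expect_true(all(vapply(mech, function(m) m$balance_rel < 0.005,
                         logical(1))))
})

test_that("an SD-0 pipeline report carries the exact difference arithmetic", {
  rep <- run_pipeline(config = list(n_participants = 3, noise_mm = 0,
                                    conditions = sd0_conditions()),
                      seed = 2)
  ct <- rep$contrasts
  expect_equal(ct$mean_diff[ct$parameter == "HD_mm" & ct$pair == "SM-MM"],
               30.5, tolerance = 1e-9)
  expect_equal(ct$mean_diff[ct$parameter == "CLD_mm" & ct$pair == "SM-MM"],
               26.7, tolerance = 1e-9)
  expect_equal(ct$mean_diff[ct$parameter == "LLD_mm" & ct$pair == "MM-HM"],
               10.6, tolerance = 1e-9)
})
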