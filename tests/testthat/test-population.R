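test_that("BSA formulas match direct evaluation and scale as power laws", {
  # oracle: direct evaluation of the published formulas
  expect_equal(compute_bsa(70, 170), 0.024265 * 70^0.5378 * 170^0.3964,
               tolerance = 1e-12)
  expect_equal(round(compute_bsa(70, 170), 3), 1.826)
  expect_equal(round(compute_bsa(70, 170, method = "dubois"), 3), 1.810)
  # doubling weight multiplies Haycock BSA by exactly 2^0.5378
  expect_equal(compute_bsa(40, 150) * 2^0.5378, compute_bsa(80, 150),
               tolerance = 1e-12)
  # strictly increasing in both arguments on a grid
  w <- seq(3, 90, length.out = 25); h <- seq(50, 190, length.out = 25)
  for (hh in c(60, 120, 180)) expect_true(all(diff(compute_bsa(w, hh)) > 0))
  for (ww in c(5, 30, 70)) expect_true(all(diff(compute_bsa(ww, h)) > 0))
  expect_error(compute_bsa(-1, 100), "weight")
  expect_error(compute_bsa(50, 0), "height")
})

test_that("healthy GFR follows the birth-to-1-year maturation curve", {
  expect_equal(gfr_for_age(0), 20)
  expect_equal(gfr_for_age(0.5), 70)       # piecewise-linear midpoint
  expect_equal(gfr_for_age(1), 120)
  expect_equal(gfr_for_age(10), 120)
  # plateau for all ages past maturation
  expect_true(all(gfr_for_age(seq(1, 80, by = 0.5)) == 120))
  expect_error(gfr_for_age(-1), "age")
})

test_that("stage-conditional GFR draws stay inside the stage band", {
  set.seed(42)
  for (st in c("mild", "moderate", "severe", "esrd")) {
    b <- stage_bands(); band <- b[b$stage == st, ]
    g <- replicate(200, gfr_for_age(10, st))
    expect_true(all(g >= band$gfr_min & g < band$gfr_max))
  }
})

test_that("sampled cohorts are seeded-deterministic and respect the spec", {
  spec <- population_spec(25, age_range = c(2, 16), ckd_stage = "severe", seed = 7)
  c1 <- sample_population(spec)
  c2 <- sample_population(spec)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))  # bitwise
  expect_equal(nrow(c1), 25)
  expect_true(all(c1$gfr >= 15 & c1$gfr < 30))
  expect_true(all(c1$age >= 2 & c1$age <= 16))
  expect_true(all(c1$weight > 0 & c1$fu_plasma > 0 & c1$fu_plasma <= 1))
  # BSA column consistent with the module's formula
  expect_equal(c1$bsa, compute_bsa(c1$weight, c1$height), tolerance = 1e-9)
  # severe overlay attached
  expect_true(all(c1$nonrenal_cl_fraction == 0.6))
})

test_that("healthy cohorts put mature subjects above the 90 threshold", {
  cohort <- sample_population(population_spec(200, age_range = c(1, 18), seed = 3))
  expect_true(all(cohort$gfr > 90))
  expect_true(all(cohort$ckd_stage == "healthy"))
})

test_that("reference-matched cohorts fix demographics and resample physiology", {
  ref <- list(id = "S1", age = 5.5, sex = "M", weight = NA, gfr = 61)
  spec <- population_spec(40, ckd_stage = "mild", reference_subject = ref, seed = 1)
  cohort <- sample_population(spec)
  expect_equal(nrow(cohort), 40)
  expect_true(all(cohort$age == 5.5))
  expect_true(all(cohort$sex == "M"))
  expect_equal(length(unique(cohort$weight)), 1)   # dose-relevant weight fixed
  expect_true(all(cohort$weight_imputed))          # imputation logged
  expect_true(all(cohort$gfr >= 60 & cohort$gfr < 90))
  expect_gt(length(unique(cohort$gfr)), 1)         # physiology resampled
})

test_that("sex ratio hits binomial bounds at n = 1000", {
  cohort <- sample_population(population_spec(1000, sex_ratio = 0.5, seed = 3))
  n_male <- sum(cohort$sex == "M")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)     # independent 99% bound
  expect_true(n_male >= bounds[1] && n_male <= bounds[2])
})

test_that("unsatisfiable or malformed specs are rejected", {
  expect_error(population_spec(0), "n")
  expect_error(population_spec(5, age_range = c(10, 2)), "age_range")
  expect_error(population_spec(5, sex_ratio = 1.5), "sex_ratio")
  expect_error(population_spec(5, reference_subject = list(weight = 10)),
               "age")
})

test_that("cohort CSV round-trip imputes height and GFR with provenance", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b"), age_years = c(7, 16), sex = c("M", "F"),
                       weight_kg = c(29.7, 55),
                       serum_creatinine_mg_dl = c(0.34, 1.0)),
            path, row.names = FALSE)
  cohort <- read_cohort(path)
  expect_true(all(cohort$height_imputed))
  expect_equal(cohort$height, height_for_age(c(7, 16), c("M", "F")))
  # GFR source hierarchy: maturation under 15, Jelliffe at 16
  expect_equal(cohort$gfr[1], 120)
  expect_equal(cohort$gfr[2], jelliffe_egfr(16, 1.0, "F"))
  out <- tempfile(fileext = ".csv")
  write_cohort(sample_population(population_spec(3, seed = 1)), out)
  expect_true(all(c("bsa_m2", "gfr", "ckd_stage") %in% names(read.csv(out))))
})
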