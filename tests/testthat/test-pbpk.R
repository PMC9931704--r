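test_that("compound parameters enforce clearance bookkeeping", {
  p <- compound_params()
  expect_equal(p$cl_renal_adult + p$cl_additional_adult, p$cl_iv_adult,
               tolerance = 1e-12)
  expect_error(compound_params(cl_iv_adult = 50), "bookkeeping")
  expect_error(compound_params(fa = 1.2), "fa")
})

test_that("clearance scaling reproduces hand-evaluated reference cases", {
  p <- compound_params()
  # healthy adult at the reference point recovers the adult decomposition
  adult <- scale_clearances(list(weight = 70, gfr = 120, nonrenal_cl_fraction = 1), p)
  expect_equal(unname(adult["cl_renal"]), 22.2, tolerance = 1e-12)
  expect_equal(unname(adult["cl_nonrenal"]), 27.3, tolerance = 1e-12)
  expect_equal(sum(adult), 49.5, tolerance = 1e-12)
  # severe CKD adult, GFR 20: arithmetic per the stated rules
  sev <- scale_clearances(list(weight = 70, gfr = 20, nonrenal_cl_fraction = 0.6), p)
  expect_equal(unname(sev["cl_nonrenal"]), 27.3 * 0.6, tolerance = 1e-12)    # 16.38
  expect_equal(unname(sev["cl_renal"]), 22.2 * 20 / 120, tolerance = 1e-12)  # 3.70
  # healthy 27-kg child: hand-evaluated allometric power law
  child <- scale_clearances(list(weight = 27, gfr = 120, nonrenal_cl_fraction = 1), p)
  expect_equal(unname(child["cl_nonrenal"]), 27.3 * (27 / 70)^0.75, tolerance = 1e-12)
  expect_equal(round(unname(child["cl_nonrenal"]), 2), 13.36)
  # missing overlay treated as healthy, with a warning
  expect_warning(scale_clearances(list(weight = 70, gfr = 120), p), "overlay")
  # per-kg non-renal clearance decreases with weight (exponent < 1)
  w <- c(5, 10, 20, 40, 70)
  perkg <- sapply(w, function(wi)
    scale_clearances(list(weight = wi, gfr = 120, nonrenal_cl_fraction = 1), p)["cl_nonrenal"] / wi)
  expect_true(all(diff(perkg) < 0))
})

test_that("the ODE profile matches the closed-form one-compartment solution", {
  p <- compound_params(central_fraction = 1, vss_per_kg = 1, ka = 1.2)
  subj <- healthy_adult()
  t <- seq(0, 24, by = 0.25)
  prof <- simulate_profile(subj, p, dose_regimen(amount_mg = 25, sampling_times = t))
  k <- 49.5 / 70
  expect_equal(prof$conc, one_cmt_oral_conc(t, 25, p$fa, 1.2, 70, k),
               tolerance = 1e-6)
})

test_that("simulation is linear in dose and null at dose zero", {
  subj <- healthy_child()
  t <- seq(0, 24, by = 0.25)
  p <- compound_params()
  prof0 <- simulate_profile(subj, p, dose_regimen(amount_mg = 0, sampling_times = t))
  expect_true(all(prof0$conc == 0))
  prof1 <- simulate_profile(subj, p, dose_regimen(amount_mg = 10, sampling_times = t))
  prof2 <- simulate_profile(subj, p, dose_regimen(amount_mg = 20, sampling_times = t))
  expect_equal(auc_trapezoid(prof2) / auc_trapezoid(prof1), 2, tolerance = 1e-6)
  expect_equal(max(prof2$conc) / max(prof1$conc), 2, tolerance = 1e-6)
})

test_that("oral clearance from the simulated curve recovers CL/fa", {
  subj <- healthy_adult()
  p <- compound_params()
  prof <- simulate_profile(subj, p, dose_regimen(amount_mg = 25,
                                                 sampling_times = seq(0, 48, by = 0.1)))
  r <- nca(prof, clf_on = "auc_0_inf")
  expect_equal(r$cl_f, 49.5 / p$fa, tolerance = 0.02)
})

test_that("mass eliminated over the full curve equals the absorbed dose", {
  subj <- healthy_adult()
  p <- compound_params()
  prof <- simulate_profile(subj, p, dose_regimen(amount_mg = 25,
                                                 sampling_times = seq(0, 72, by = 0.05)))
  r <- nca(prof, clf_on = "auc_0_inf")
  # eliminated mass = CL * AUCinf (AUC in mg*h/L after unit conversion)
  cl_total <- sum(scale_clearances(subj, p))
  eliminated_mg <- cl_total * r$auc_0_inf / 1000
  expect_equal(eliminated_mg, p$fa * 25, tolerance = 0.005)
})

test_that("steady-state accumulation matches the one-compartment closed form", {
  # reduced limit: single disposition compartment, near-bolus absorption
  p <- compound_params(central_fraction = 1, vss_per_kg = 1, ka = 200)
  subj <- healthy_adult()
  k <- 49.5 / 70; tau <- 8
  grid <- sort(unique(c(seq(0, 0.05, by = 5e-4), seq(0.05, tau, by = 0.01))))
  reg <- dose_regimen(amount_mg = 25, interval = tau, sampling_times = grid)
  ss <- simulate_to_steady_state(subj, p, reg, tol = 1e-6)
  first <- simulate_profile(subj, p, dose_regimen(amount_mg = 25, sampling_times = grid))
  ratio <- auc_trapezoid(ss) / auc_trapezoid(first)
  expect_equal(ratio, 1 / (1 - exp(-k * tau)), tolerance = 0.005)
  # steady-state interval AUC equals fa*D/CL exactly for a linear model
  expect_equal(auc_trapezoid(ss), 1000 * p$fa * 25 / (70 * k), tolerance = 0.005)
  # and the first interval matches the finite-ka closed form
  expect_equal(auc_trapezoid(first), one_cmt_oral_auc_tau(25, p$fa, 200, 70, k, tau),
               tolerance = 0.005)
})

test_that("a dosing interval much longer than the half-life shows no accumulation", {
  subj <- healthy_adult()
  p <- compound_params()
  grid <- seq(0, 72, by = 0.1)
  reg <- dose_regimen(amount_mg = 25, interval = 72, sampling_times = grid)
  ss <- suppressWarnings(simulate_to_steady_state(subj, p, reg))
  single <- simulate_profile(subj, p, dose_regimen(amount_mg = 25, sampling_times = grid))
  r <- nca(single, clf_on = "auc_0_inf")
  expect_equal(auc_trapezoid(ss), r$auc_0_inf, tolerance = 0.01)
})

test_that("exposure rises and oral clearance falls with CKD severity", {
  p <- compound_params()
  t <- seq(0, 24, by = 0.25)
  base <- healthy_child()
  auc_by_stage <- sapply(c("healthy", "mild", "severe"), function(st) {
    ov <- ckd_overlay(st)
    subj <- base
    subj$gfr <- if (st == "healthy") 120 else
      mean(unlist(stage_bands()[stage_bands()$stage == st, c("gfr_min", "gfr_max")]))
    subj$nonrenal_cl_fraction <- ov$nonrenal_cl_fraction
    subj$gastric_emptying_multiplier <- ov$gastric_emptying_multiplier
    auc_trapezoid(simulate_profile(subj, p, dose_regimen(amount_mg_per_kg = 1,
                                                         sampling_times = t)))
  })
  expect_true(auc_by_stage["healthy"] < auc_by_stage["mild"])
  expect_true(auc_by_stage["mild"] < auc_by_stage["severe"])
  clf <- clf_by_stage(age = 8, weight = 28)
  expect_true(clf["healthy"] > clf["mild"] && clf["mild"] > clf["severe"])
})

test_that("steady state in CKD exceeds the same subject's healthy exposure", {
  p <- compound_params()
  grid <- seq(0, 8, by = 0.1)
  reg <- dose_regimen(amount_mg_per_kg = 1, interval = 8, sampling_times = grid)
  base <- healthy_child()
  sick <- base; sick$gfr <- 20; sick$nonrenal_cl_fraction <- 0.6
  auc_h <- auc_trapezoid(simulate_to_steady_state(base, p, reg))
  auc_s <- auc_trapezoid(simulate_to_steady_state(sick, p, reg))
  expect_gt(auc_s, auc_h)
})

test_that("regimen validation rejects malformed dosing", {
  expect_error(dose_regimen(), "exactly one")
  expect_error(dose_regimen(amount_mg = 10, amount_mg_per_kg = 1), "exactly one")
  expect_error(dose_regimen(amount_mg = 10, n_doses = 3), "interval")
  expect_error(dose_regimen(amount_mg = 10, sampling_times = c(0, 0, 1)),
               "sampling_times")
  expect_error(simulate_to_steady_state(healthy_adult(), compound_params(),
                                        dose_regimen(amount_mg = 10)), "interval")
})
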