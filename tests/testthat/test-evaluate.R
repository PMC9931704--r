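test_that("fold error is predicted/observed and reproduces printed ratios", {
  expect_equal(round(fold_error(221.90, 523.00), 2), 2.36)
  expect_equal(round(fold_error(371, 636.97), 2), 1.72)
  for (x in c(0.1, 1, 350)) expect_equal(fold_error(x, x), 1)
  # reciprocal identity
  for (o in c(2, 7)) for (p in c(0.5, 3))
    expect_equal(fold_error(o, p) * fold_error(p, o), 1, tolerance = 1e-12)
  expect_error(fold_error(0, 1), "observed")
})

test_that("printed AUC and Cmax ratios reproduce to 2 dp outside quarantine", {
  tab <- load_fixture("table2")
  quar <- load_fixture("table2_quarantine")
  auc_ok <- !quarantined(quar, tab$id, "auc_ratio")
  cmax_ok <- !quarantined(quar, tab$id, "cmax_ratio")
  expect_equal(round(fold_error(tab$auc_obs[auc_ok], tab$auc_pred[auc_ok]), 2),
               tab$auc_ratio[auc_ok])
  expect_equal(round(fold_error(tab$cmax_obs[cmax_ok], tab$cmax_pred[cmax_ok]), 2),
               tab$cmax_ratio[cmax_ok])
  expect_equal(sum(cmax_ok), 14)        # every Cmax ratio is consistent
  expect_equal(sum(auc_ok), 13)         # one AUC ratio cell is quarantined
})

test_that("AFE is the geometric mean with its algebraic identities", {
  expect_equal(afe(c(2, 0.5)), 1)
  for (r in c(0.3, 1, 2.7)) expect_equal(afe(r), r)
  x <- c(0.4, 1.3, 2.2, 0.9)
  # permutation invariance and the reciprocal identity
  expect_equal(afe(x), afe(rev(x)), tolerance = 1e-12)
  expect_equal(afe(x) * afe(1 / x), 1, tolerance = 1e-12)
  # log-AFE additivity under concatenation of equal-sized sets
  y <- c(1.5, 0.8, 2.0, 1.1)
  expect_equal(afe(c(x, y)), sqrt(afe(x) * afe(y)), tolerance = 1e-12)
  # independent oracle: geometric mean as prod^(1/n)
  expect_equal(afe(x), prod(x)^(1 / length(x)), tolerance = 1e-12)
  expect_error(afe(numeric(0)), "non-empty")
  expect_error(afe(c(1, -1)), "ratios")
})

test_that("recomputed aggregates of the printed ratios take their known values", {
  tab <- load_fixture("table2")
  # oracle: direct arithmetic on the 14 printed AUC ratios
  expect_equal(round(afe(tab$auc_ratio), 2), 1.07)
  expect_equal(round(mean(tab$auc_ratio), 2), 1.21)
  expect_equal(round(mean(tab$cmax_ratio), 2), 1.28)
  m <- mean_ratio_ci(tab$auc_ratio)
  expect_equal(m$mean, mean(tab$auc_ratio), tolerance = 1e-12)
  expect_equal(m$ci,
               mean(tab$auc_ratio) + c(-1, 1) * qt(0.975, 13) *
                 sd(tab$auc_ratio) / sqrt(14),
               tolerance = 1e-12)
})

test_that("mean-ratio confidence intervals behave at the degenerate limits", {
  z <- mean_ratio_ci(rep(1, 4))
  expect_equal(z$mean, 1)
  expect_equal(z$ci, c(1, 1))
  s <- mean_ratio_ci(c(0.5, 1.5))
  expect_equal(s$mean, 1)
  expect_equal(s$ci[1] + s$ci[2], 2, tolerance = 1e-12)  # symmetric about 1
  g <- mean_ratio_ci(c(0.5, 2), log_scale = TRUE)
  expect_equal(g$mean, 1, tolerance = 1e-12)             # geometric mean
  expect_error(mean_ratio_ci(1), "insufficient")
})

test_that("two-fold counting is inclusive and matches the printed-table counts", {
  b <- twofold_check(c(0.5, 2.0))
  expect_true(all(b$within))                              # boundary inclusion
  expect_true(twofold_check(2.36, hi = 2.4)$within)
  tab <- load_fixture("table2")
  tf_auc <- twofold_check(tab$auc_ratio)
  expect_equal(tf_auc$n_within, 10)                       # 0.43, 2.06, 2.30, 2.36 fall outside
  expect_equal(twofold_check(tab$auc_ratio, lo = 1 / 2.4, hi = 2.4)$n_within, 14)
  expect_equal(twofold_check(tab$cmax_ratio)$n_within, 12)
})

test_that("population summaries collapse for identical profiles and are seeded-reproducible", {
  t <- seq(0, 12, by = 0.5)
  prof <- data.frame(time = t, conc = one_cmt_oral_conc(t, 10, 0.7, 1.5, 30, 0.4))
  s <- population_summary(list(prof, prof, prof))
  for (col in c("mean", "min", "max", "p5", "p95"))
    expect_equal(s[[col]], prof$conc)
  # two profiles: documented type-7 behaviour, p5 = lo + 0.05 * (hi - lo)
  prof2 <- prof; prof2$conc <- prof$conc * 2
  s2 <- population_summary(list(prof, prof2))
  expect_equal(s2$p5, prof$conc + 0.05 * prof$conc, tolerance = 1e-12)
  expect_equal(s2$min, prof$conc)
  # mismatched grids are an alignment error
  prof3 <- prof; prof3$time <- prof3$time + 0.1
  expect_error(population_summary(list(prof, prof3)), "common time grid")
  # seeded simulations give bitwise-identical summaries
  mk <- function() {
    cohort <- sample_population(population_spec(10, ckd_stage = "mild", seed = 11))
    profs <- lapply(seq_len(10), function(i)
      simulate_profile(as.list(cohort[i, ]), compound_params(),
                       dose_regimen(amount_mg_per_kg = 1, sampling_times = t)))
    population_summary(profs)
  }
  expect_identical(serialize(mk(), NULL), serialize(mk(), NULL))
})

test_that("prediction-interval coverage behaves at the limits and widens monotonically", {
  t <- seq(0, 12, by = 0.5)
  set.seed(9)
  profs <- lapply(1:50, function(i)
    data.frame(time = t, conc = one_cmt_oral_conc(t, 10, 0.7, 1.5, 30, 0.4) *
                 exp(rnorm(1, 0, 0.2))))
  s <- population_summary(profs)
  med <- data.frame(time = t, conc = s$mean)
  expect_equal(pi_coverage(med, s), 1)                     # central curve inside
  far <- data.frame(time = t, conc = s$max * 10 + 1)
  expect_equal(pi_coverage(far, s), 0)                     # far above the band
  # widening the band never lowers coverage
  obs <- profs[[7]]
  expect_gte(pi_coverage(obs, s, lower = "min", upper = "max"),
             pi_coverage(obs, s))
  expect_error(pi_coverage(data.frame(time = numeric(0), conc = numeric(0)), s),
               "empty")
  expect_error(pi_coverage(data.frame(time = 99, conc = 1), s), "outside")
})

test_that("the evaluation report assembles all metrics coherently", {
  tab <- load_fixture("table2")
  ev <- evaluate_pk(tab$auc_obs, tab$auc_pred, parameter = "auc_0_t")
  expect_s3_class(ev, "pk_evaluation")
  expect_equal(ev$n, 14)
  expect_equal(ev$per_obs$ratio, tab$auc_pred / tab$auc_obs, tolerance = 1e-12)
  expect_equal(ev$afe, afe(tab$auc_pred / tab$auc_obs), tolerance = 1e-12)
  expect_true(ev$ci95[1] <= ev$mean_ratio && ev$mean_ratio <= ev$ci95[2])
  expect_output(print(ev), "AFE")
})
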