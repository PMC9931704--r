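# Closed-form one-compartment oral model: independent oracle for the ODE
# implementation. All arguments in mg, L, 1/h; concentration in ng/ml.
one_cmt_oral_conc <- function(t, dose_mg, fa, ka, v, k) {
  stopifnot(abs(ka - k) > 1e-9)
  1000 * (fa * dose_mg * ka) / (v * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

# interval AUC (ng*h/ml) of the one-compartment oral model over [0, tau]
one_cmt_oral_auc_tau <- function(dose_mg, fa, ka, v, k, tau) {
  1000 * (fa * dose_mg * ka) / (v * (ka - k)) *
    ((1 - exp(-k * tau)) / k - (1 - exp(-ka * tau)) / ka)
}

healthy_adult <- function(id = "A") {
  list(id = id, age = 30, sex = "M", weight = 70, gfr = 120,
       hematocrit = 0.43, fu_plasma = 0.70, nonrenal_cl_fraction = 1,
       gastric_emptying_multiplier = 1, kp_scalar = 1)
}

healthy_child <- function(id = "C", age = 8, weight = 28) {
  list(id = id, age = age, sex = "M", weight = weight, gfr = 120,
       hematocrit = 0.37, fu_plasma = 0.70, nonrenal_cl_fraction = 1,
       gastric_emptying_multiplier = 1, kp_scalar = 1)
}

# cells excluded from a parity assertion, as (id, column) pairs
quarantined <- function(quar, ids, column) {
  paste(ids, column) %in% paste(quar$id, quar$column)
}
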