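#' Captopril compound parameters
#'
#' Drug-dependent parameters of the reduced disposition model. The adult
#' clearance decomposition is captopril's reference set: total systemic
#' clearance 49.5 L/h of which 22.2 L/h is renal; the remaining
#' "additional" (non-renal) 27.3 L/h is allometrically scaled to body
#' weight with exponent 0.75 and carries no enzyme ontogeny. Renal
#' clearance scales with allometry and with normalized GFR relative to the
#' 120 ml/min/1.73 m^2 adult reference. Absorption/distribution defaults
#' (fa, ka, Vss, fu) are literature conventions for captopril and fully
#' overridable.
#'
#' @param name compound label
#' @param fa fraction absorbed (0-1]
#' @param ka first-order absorption rate, 1/h
#' @param lag absorption lag, h
#' @param vss_per_kg steady-state distribution volume, L/kg
#' @param kp_scalar global tissue-partition multiplier on Vss
#' @param cl_iv_adult adult total systemic clearance, L/h
#' @param cl_renal_adult adult renal clearance, L/h
#' @param cl_additional_adult adult additional (non-renal) clearance, L/h;
#'   must satisfy \code{cl_iv_adult = cl_renal_adult + cl_additional_adult}
#' @param fu_plasma unbound fraction in plasma (0-1]
#' @param reference_weight adult reference weight, kg
#' @param reference_gfr adult reference GFR, ml/min/1.73 m^2
#' @param allometric_exponent clearance allometry exponent
#' @param central_fraction fraction of Vss assigned to the central
#'   compartment (1 collapses the model to one disposition compartment)
#' @param cl_distribution_adult inter-compartmental clearance at the adult
#'   reference weight, L/h (allometrically scaled); ignored when
#'   \code{central_fraction = 1}
#' @return an object of class \code{compound_params}
#' @examples
#' p <- compound_params()
#' p$cl_renal_adult + p$cl_additional_adult   # 49.5
#' @export
compound_params <- function(name = "captopril",
                            fa = 0.65, ka = 1.5, lag = 0,
                            vss_per_kg = 0.8, kp_scalar = 1,
                            cl_iv_adult = 49.5, cl_renal_adult = 22.2,
                            cl_additional_adult = 27.3,
                            fu_plasma = 0.70,
                            reference_weight = 70, reference_gfr = 120,
                            allometric_exponent = 0.75,
                            central_fraction = 0.5,
                            cl_distribution_adult = 10) {
  for (nm in c("fa", "ka", "vss_per_kg", "kp_scalar", "cl_iv_adult",
               "cl_renal_adult", "cl_additional_adult", "fu_plasma",
               "reference_weight", "reference_gfr", "central_fraction"))
    .check_positive(get(nm), nm)
  .check_positive(lag, "lag", strict = FALSE)
  if (fa > 1 || fu_plasma > 1 || central_fraction > 1)
    stop("fa, fu_plasma and central_fraction must lie in (0, 1]", call. = FALSE)
  if (abs(cl_iv_adult - (cl_renal_adult + cl_additional_adult)) > 1e-9)
    stop(sprintf("clearance bookkeeping violated: cl_renal_adult + cl_additional_adult = %.10g != cl_iv_adult = %.10g",
                 cl_renal_adult + cl_additional_adult, cl_iv_adult), call. = FALSE)
  structure(list(name = name, fa = fa, ka = ka, lag = lag,
                 vss_per_kg = vss_per_kg, kp_scalar = kp_scalar,
                 cl_iv_adult = cl_iv_adult, cl_renal_adult = cl_renal_adult,
                 cl_additional_adult = cl_additional_adult,
                 fu_plasma = fu_plasma, reference_weight = reference_weight,
                 reference_gfr = reference_gfr,
                 allometric_exponent = allometric_exponent,
                 central_fraction = central_fraction,
                 cl_distribution_adult = cl_distribution_adult),
            class = "compound_params")
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params> %s\n", x$name))
  cat(sprintf("  absorption: fa %.2f, ka %.2f 1/h, lag %.2f h\n", x$fa, x$ka, x$lag))
  cat(sprintf("  distribution: Vss %.2f L/kg x Kp %.2f, central fraction %.2f\n",
              x$vss_per_kg, x$kp_scalar, x$central_fraction))
  cat(sprintf("  adult clearance: total %.1f = renal %.1f + additional %.1f L/h (exponent %.2f)\n",
              x$cl_iv_adult, x$cl_renal_adult, x$cl_additional_adult, x$allometric_exponent))
  invisible(x)
}

#' Dosing regimen
#'
#' Oral dosing: exactly one of \code{amount_mg} (absolute) or
#' \code{amount_mg_per_kg} (weight-based, resolved against the subject at
#' simulation time) must be given. \code{interval} and \code{n_doses}
#' describe repeated dosing; a missing interval means a single dose.
#'
#' @param amount_mg dose in mg
#' @param amount_mg_per_kg dose in mg/kg
#' @param interval dosing interval tau, h
#' @param n_doses number of doses administered
#' @param sampling_times strictly increasing, non-negative sampling times
#'   (h), relative to the first dose (or to the final-interval start for
#'   steady-state output)
#' @return an object of class \code{dose_regimen}
#' @export
dose_regimen <- function(amount_mg = NULL, amount_mg_per_kg = NULL,
                         interval = NULL, n_doses = 1L,
                         sampling_times = seq(0, 24, by = 0.5)) {
  if (is.null(amount_mg) == is.null(amount_mg_per_kg))
    stop("give exactly one of `amount_mg` or `amount_mg_per_kg`", call. = FALSE)
  amt <- if (is.null(amount_mg)) amount_mg_per_kg else amount_mg
  .check_positive(amt, "dose amount", strict = FALSE)   # 0 allowed (null-dose checks)
  if (!is.null(interval)) .check_positive(interval, "interval")
  if (n_doses > 1 && is.null(interval))
    stop("`interval` required when n_doses > 1", call. = FALSE)
  if (any(sampling_times < 0) || any(diff(sampling_times) <= 0))
    stop("`sampling_times` must be non-negative and strictly increasing", call. = FALSE)
  structure(list(amount_mg = amount_mg, amount_mg_per_kg = amount_mg_per_kg,
                 interval = interval, n_doses = as.integer(n_doses),
                 sampling_times = as.numeric(sampling_times)),
            class = "dose_regimen")
}

# resolve a regimen's dose in mg against a subject
resolve_dose_mg <- function(regimen, subject) {
  if (!is.null(regimen$amount_mg)) return(regimen$amount_mg)
  w <- subject$weight
  if (is.null(w) || is.na(w)) stop("mg/kg dose needs a subject weight", call. = FALSE)
  regimen$amount_mg_per_kg * w
}

#' Scale adult clearances to a subject
#'
#' \deqn{CL_{nonrenal} = CL_{add,adult} \cdot (W/70)^{0.75} \cdot f_{stage}}
#' \deqn{CL_{renal} = CL_{R,adult} \cdot (W/70)^{0.75} \cdot GFR/120}
#' where \eqn{f_{stage}} is the fraction of healthy non-renal clearance
#' retained under the subject's CKD overlay (1 healthy, 0.8 mild, 0.7
#' moderate, 0.6 severe). A subject without an overlay is treated as
#' healthy with a warning.
#'
#' @param subject named list / one-row data frame with \code{weight},
#'   \code{gfr} and (optionally) \code{nonrenal_cl_fraction}
#' @param params a \code{\link{compound_params}}
#' @return named numeric: \code{cl_renal}, \code{cl_nonrenal} (L/h)
#' @examples
#' adult <- list(weight = 70, gfr = 120, nonrenal_cl_fraction = 1)
#' scale_clearances(adult, compound_params())   # 22.2, 27.3
#' @export
scale_clearances <- function(subject, params = compound_params()) {
  s <- as.list(subject)
  .check_positive(s$weight, "weight")
  .check_positive(s$gfr, "gfr", strict = FALSE)
  frac <- s$nonrenal_cl_fraction
  if (is.null(frac) || is.na(frac)) {
    warning("subject has no disease overlay; treating as healthy (nonrenal_cl_fraction = 1)")
    frac <- 1
  }
  allo <- (s$weight / params$reference_weight)^params$allometric_exponent
  c(cl_renal = params$cl_renal_adult * allo * s$gfr / params$reference_gfr,
    cl_nonrenal = params$cl_additional_adult * allo * frac)
}

# per-subject ODE constants for the reduced model (mg and L internally)
.pk_constants <- function(subject, params) {
  s <- as.list(subject)
  cl <- scale_clearances(s, params)
  kp <- params$kp_scalar * (if (!is.null(s$kp_scalar) && !is.na(s$kp_scalar)) s$kp_scalar else 1)
  vss <- params$vss_per_kg * kp * s$weight
  fc <- params$central_fraction
  one_cmt <- fc >= 1 - 1e-12
  v1 <- vss * fc
  v2 <- if (one_cmt) 0 else vss * (1 - fc)
  gem <- if (!is.null(s$gastric_emptying_multiplier) && !is.na(s$gastric_emptying_multiplier))
    s$gastric_emptying_multiplier else 1
  allo <- (s$weight / params$reference_weight)^params$allometric_exponent
  list(ka = params$ka / gem, lag = params$lag * gem, fa = params$fa,
       cl = sum(cl), cl_renal = cl[["cl_renal"]], cl_nonrenal = cl[["cl_nonrenal"]],
       q = if (one_cmt) 0 else params$cl_distribution_adult * allo,
       v1 = v1, v2 = v2, one_cmt = one_cmt)
}

.pk_ode <- function(t, y, p) {
  absorb <- p$ka * y[1]
  dgut <- -absorb
  if (p$one_cmt) {
    dc <- absorb - (p$cl / p$v1) * y[2]
    dp <- 0
  } else {
    dc <- absorb - (p$cl / p$v1) * y[2] - (p$q / p$v1) * y[2] + (p$q / p$v2) * y[3]
    dp <- (p$q / p$v1) * y[2] - (p$q / p$v2) * y[3]
  }
  delim <- (p$cl / p$v1) * y[2]
  list(c(dgut, dc, dp, delim))
}

# integrate the model over `times` (h) with doses (mg) at `dose_times`;
# returns the deSolve matrix with columns gut/central/peripheral/eliminated
.integrate_pk <- function(k, dose_mg, dose_times, times,
                          y0 = c(gut = 0, central = 0, peripheral = 0, eliminated = 0),
                          rtol = 1e-8, atol = 1e-12) {
  dose_times <- dose_times + k$lag
  times <- sort(unique(c(times, dose_times[dose_times <= max(times)])))
  ev <- NULL
  if (dose_mg > 0 && length(dose_times)) {
    at_start <- abs(dose_times - times[1]) < 1e-12
    if (any(at_start)) y0["gut"] <- y0["gut"] + k$fa * dose_mg * sum(at_start)
    rest <- dose_times[!at_start & dose_times <= max(times)]
    if (length(rest))
      ev <- data.frame(var = "gut", time = rest, value = k$fa * dose_mg, method = "add")
  }
  out <- deSolve::lsoda(y0, times, .pk_ode, k, rtol = rtol, atol = atol,
                        events = if (is.null(ev)) NULL else list(data = ev))
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed to converge (istate ",
         attr(out, "istate")[1], ") at t ~ ", max(out[, "time"]), call. = FALSE)
  neg <- min(out[, "central"])
  if (neg < -1e-6) stop("negative central amount beyond tolerance: ", neg, call. = FALSE)
  out
}

# package a simulated profile
.as_profile <- function(times, conc, subject_id, dose_mg, steady_state = FALSE) {
  structure(data.frame(time = times, conc = pmax(conc, 0)),
            subject_id = subject_id, dose_mg = dose_mg,
            steady_state = steady_state,
            class = c("pk_profile", "data.frame"))
}

#' Simulate a concentration-time profile
#'
#' Integrates the reduced captopril model for one subject and regimen:
#' first-order absorption from a gut depot (bioavailable fraction
#' \code{fa}, rate \code{ka}, optional lag) into a central compartment of
#' volume \code{central_fraction * vss_per_kg * kp_scalar * weight},
#' exchanging with a peripheral compartment, with linear elimination at
#' the subject's scaled total clearance (\code{\link{scale_clearances}}).
#' Repeated doses are administered every \code{interval} h. Concentrations
#' are blood/plasma ng/ml at \code{sampling_times} measured from the first
#' dose. The ODE system runs in mg and L; 1 mg/L = 1000 ng/ml at the
#' output boundary.
#'
#' @param subject named list / one-row data frame (weight, gfr, overlay
#'   fields as produced by \code{\link{sample_population}} /
#'   \code{\link{apply_ckd}})
#' @param params \code{\link{compound_params}}
#' @param regimen \code{\link{dose_regimen}}
#' @param rtol,atol solver tolerances (mg scale)
#' @return a \code{pk_profile}: data.frame (time, conc) with attributes
#'   \code{subject_id}, \code{dose_mg} (total mg in the simulated course),
#'   \code{steady_state}
#' @examples
#' adult <- list(id = "A", weight = 70, gfr = 120, nonrenal_cl_fraction = 1)
#' prof <- simulate_profile(adult, compound_params(),
#'                          dose_regimen(amount_mg = 25))
#' head(prof)
#' @export
simulate_profile <- function(subject, params = compound_params(),
                             regimen, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(regimen, "dose_regimen"))
  s <- as.list(subject)
  dose <- resolve_dose_mg(regimen, s)
  k <- .pk_constants(s, params)
  st <- regimen$sampling_times
  if (dose == 0)
    return(.as_profile(st, rep(0, length(st)), s$id %||% "subject", 0))
  dose_times <- if (regimen$n_doses > 1)
    (seq_len(regimen$n_doses) - 1) * regimen$interval else 0
  times <- sort(unique(c(0, st)))
  out <- .integrate_pk(k, dose, dose_times, times, rtol = rtol, atol = atol)
  conc <- approx(out[, "time"], out[, "central"] / k$v1 * 1000, xout = st)$y
  .as_profile(st, conc, s$id %||% "subject", dose * length(dose_times))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate repeated dosing to steady state
#'
#' Doses every \code{regimen$interval} h until the within-interval AUC
#' changes by less than \code{tol} (relative) between consecutive doses,
#' or until \code{max_days} of dosing; warns if not converged. Returns the
#' final-interval profile with times relative to the interval start,
#' flagged \code{steady_state}.
#'
#' @inheritParams simulate_profile
#' @param tol relative interval-AUC change declaring steady state
#' @param max_days cap on simulated dosing duration, days
#' @return a \code{pk_profile} for the final interval; attribute
#'   \code{dose_mg} is the per-interval dose, \code{n_doses_to_ss} records
#'   the number of doses simulated
#' @examples
#' adult <- list(id = "A", weight = 70, gfr = 120, nonrenal_cl_fraction = 1)
#' reg <- dose_regimen(amount_mg = 25, interval = 8,
#'                     sampling_times = seq(0, 8, 0.25))
#' ss <- simulate_to_steady_state(adult, compound_params(), reg)
#' attr(ss, "steady_state")
#' @export
simulate_to_steady_state <- function(subject, params = compound_params(),
                                     regimen, tol = 0.001, max_days = 90,
                                     rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (is.null(regimen$interval)) stop("steady state needs `regimen$interval`", call. = FALSE)
  s <- as.list(subject)
  dose <- resolve_dose_mg(regimen, s)
  tau <- regimen$interval
  st <- regimen$sampling_times
  if (any(st > tau)) stop("sampling_times must lie within one dosing interval", call. = FALSE)
  k <- .pk_constants(s, params)
  if (dose == 0)
    return(.as_profile(st, rep(0, length(st)), s$id %||% "subject", 0, TRUE))

  grid <- sort(unique(c(seq(0, tau, length.out = 201), st)))
  y <- c(gut = 0, central = 0, peripheral = 0, eliminated = 0)
  auc_prev <- NA_real_
  max_doses <- ceiling(max_days * 24 / tau)
  converged <- FALSE
  for (i in seq_len(max_doses)) {
    out <- .integrate_pk(k, dose, 0, grid, y0 = y, rtol = rtol, atol = atol)
    conc <- out[, "central"] / k$v1 * 1000
    auc <- auc_trapezoid(out[, "time"], conc)
    if (!is.na(auc_prev) && auc_prev > 0 && abs(auc - auc_prev) / auc_prev < tol) {
      converged <- TRUE
      break
    }
    auc_prev <- auc
    y <- out[nrow(out), c("gut", "central", "peripheral", "eliminated")]
  }
  if (!converged)
    warning(sprintf("steady state not reached within %d days (last interval-AUC change %.3g); returning last interval",
                    max_days, abs(auc - auc_prev) / auc_prev))
  prof <- .as_profile(st, approx(out[, "time"], conc, xout = st)$y,
                      s$id %||% "subject", dose, TRUE)
  attr(prof, "n_doses_to_ss") <- i
  prof
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile> subject %s, dose %.4g mg%s, %d samples over %.4g h, Cmax %.4g ng/ml\n",
              attr(x, "subject_id"), attr(x, "dose_mg"),
              if (isTRUE(attr(x, "steady_state"))) " (steady state)" else "",
              nrow(x), max(x$time), max(x$conc)))
  invisible(x)
}

#' @export
plot.pk_profile <- function(x, log = "", ...) {
  plot(x$time, x$conc, type = "l", xlab = "Time (h)",
       ylab = "Concentration (ng/ml)", log = log, ...)
  invisible(x)
}
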