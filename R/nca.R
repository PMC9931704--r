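#' Trapezoidal AUC
#'
#' Linear trapezoidal rule over \code{[times[1], t_end]} (the package
#' default, matching the dose/AUC = CL/F identities of the reference PK
#' tables); log-down trapezoids (log interpolation on descending segments)
#' available via \code{method = "linear-log"}.
#'
#' @param times sampling times, h; strictly increasing, length >= 2.
#'   A \code{pk_profile} may be passed here, in which case \code{conc} is
#'   taken from it.
#' @param conc concentrations, ng/ml (>= 0)
#' @param t_end upper limit, h; defaults to the last time; must not exceed
#'   it (partial last intervals are interpolated linearly)
#' @param method \code{"linear"} or \code{"linear-log"}
#' @return AUC in ng*h/ml
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 100, 50))   # 125
#' @export
auc_trapezoid <- function(times, conc = NULL, t_end = NULL,
                          method = c("linear", "linear-log")) {
  method <- match.arg(method)
  if (inherits(times, "pk_profile")) { conc <- times$conc; times <- times$time }
  if (length(times) < 2) stop("insufficient data: need at least 2 points", call. = FALSE)
  if (length(conc) != length(times)) stop("times and conc lengths differ", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (is.null(t_end)) t_end <- times[length(times)]
  if (t_end > times[length(times)] + 1e-12) stop("t_end exceeds the last sampling time", call. = FALSE)
  keep <- times <= t_end + 1e-12
  t <- times[keep]; c_ <- conc[keep]
  if (t[length(t)] < t_end) {           # partial last interval
    c_end <- approx(times, conc, xout = t_end)$y
    t <- c(t, t_end); c_ <- c(c_, c_end)
  }
  dt <- diff(t); c1 <- c_[-length(c_)]; c2 <- c_[-1]
  seg <- if (method == "linear") dt * (c1 + c2) / 2 else {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    ifelse(logdown, dt * (c1 - c2) / log(c1 / c2), dt * (c1 + c2) / 2)
  }
  sum(seg)
}

#' Apparent oral clearance from dose and AUC
#'
#' \deqn{CL/F = \frac{Dose \cdot 10^6}{AUC \cdot 1000}}
#' with dose in mg (ng after the 1e6 factor), AUC in ng*h/ml, giving
#' CL/F in L/h. With a mg/kg dose the identical arithmetic yields L/h/kg.
#'
#' @param dose_mg dose, mg (or mg/kg for the per-kg variant) (> 0)
#' @param auc exposure, ng*h/ml (> 0)
#' @return clearance in L/h (or L/h/kg)
#' @examples
#' cl_f(12.5, 189.40)    # 66.00 L/h
#' cl_f(0.8, 1126.50)    # 0.71 L/h/kg for a 0.8 mg/kg dose
#' @export
cl_f <- function(dose_mg, auc) {
  .check_positive(dose_mg, "dose_mg")
  .check_positive(auc, "auc")
  dose_mg * 1e6 / auc / 1000
}

#' Terminal log-linear slope
#'
#' Unweighted least-squares fit of log(concentration) on the terminal
#' descending tail: every candidate set of the last \code{j >= min_points}
#' points after Tmax (positive concentrations only) is fitted and the one
#' with the highest adjusted R-squared is kept. Returns \code{NULL} when
#' no valid descending tail exists or the best slope is non-negative.
#'
#' @param times,conc profile vectors
#' @param min_points minimum points in the fit (>= 3)
#' @return list(lambda_z, intercept, n_points, adj_r2) or NULL
#' @export
lambda_z <- function(times, conc, min_points = 3) {
  if (inherits(times, "pk_profile")) { conc <- times$conc; times <- times$time }
  i_max <- which.max(conc)
  idx <- which(seq_along(times) > i_max & conc > 0)
  if (length(idx) < min_points) return(NULL)
  best <- NULL
  for (j in seq(min_points, length(idx))) {
    use <- tail(idx, j)
    x <- times[use]; y <- log(conc[use])
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
    if (sxx <= 0) next
    slope <- sxy / sxx
    if (!is.finite(slope) || slope >= 0) next
    ssr <- sum((y - my - slope * (x - mx))^2)
    sst <- sum((y - my)^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 1
    adj <- 1 - (1 - r2) * (j - 1) / (j - 2)
    if (is.null(best) || adj > best$adj_r2 + 1e-8)
      best <- list(lambda_z = -slope, intercept = my - slope * mx,
                   n_points = j, adj_r2 = adj)
  }
  best
}

#' Non-compartmental analysis of one profile
#'
#' Extracts Cmax and Tmax (ties broken to the earliest time), AUC from
#' zero to the last sample by the linear trapezoidal rule, AUC to
#' infinity by adding \code{Clast / lambda_z} when a terminal slope can be
#' fitted (\code{\link{lambda_z}}), and apparent oral clearance. CL/F
#' uses AUC(0-t) by default for parity with reported observed-data
#' conventions; set \code{clf_on = "auc_0_inf"} to use the extrapolated
#' exposure.
#'
#' @param profile a \code{pk_profile} or data.frame with \code{time},
#'   \code{conc}
#' @param dose_mg administered dose in the evaluated interval, mg; taken
#'   from the profile attribute when omitted
#' @param weight optional body weight, kg, for the per-kg clearance
#' @param clf_on \code{"auc_0_t"} (default) or \code{"auc_0_inf"}
#' @param auc_method passed to \code{\link{auc_trapezoid}}
#' @return an object of class \code{nca_result}: cmax, tmax, auc_0_t,
#'   auc_0_inf (NA when no terminal phase), lambda_z, cl_f, cl_f_per_kg
#' @examples
#' prof <- data.frame(time = 0:6, conc = c(0, 80, 100, 70, 45, 28, 17))
#' nca(prof, dose_mg = 25)
#' @export
nca <- function(profile, dose_mg = NULL, weight = NULL,
                clf_on = c("auc_0_t", "auc_0_inf"),
                auc_method = "linear") {
  clf_on <- match.arg(clf_on)
  t <- profile$time; c_ <- profile$conc
  if (is.null(dose_mg)) dose_mg <- attr(profile, "dose_mg")
  if (is.null(dose_mg)) stop("`dose_mg` is required", call. = FALSE)
  i_max <- which.max(c_)                       # first max on ties
  auc_t <- auc_trapezoid(t, c_, method = auc_method)
  lz <- lambda_z(t, c_)
  auc_inf <- NA_real_
  if (is.null(lz)) {
    warning("no descending terminal phase; auc_0_inf omitted")
  } else {
    c_last <- c_[length(c_)]
    auc_inf <- auc_t + c_last / lz$lambda_z
  }
  auc_for_cl <- if (clf_on == "auc_0_t") auc_t else auc_inf
  clf <- if (!is.na(auc_for_cl) && auc_for_cl > 0 && dose_mg > 0)
    cl_f(dose_mg, auc_for_cl) else NA_real_
  structure(list(cmax = c_[i_max], tmax = t[i_max],
                 auc_0_t = auc_t, auc_0_inf = auc_inf,
                 lambda_z = if (is.null(lz)) NA_real_ else lz$lambda_z,
                 cl_f = clf,
                 cl_f_per_kg = if (!is.null(weight) && !is.na(clf)) clf / weight else NA_real_,
                 dose_mg = dose_mg, clf_on = clf_on),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> Cmax %.4g ng/ml at %.3g h | AUC0-t %.5g ng*h/ml | AUC0-inf %s | CL/F %s L/h\n",
              x$cmax, x$tmax, x$auc_0_t,
              if (is.na(x$auc_0_inf)) "NA" else sprintf("%.5g", x$auc_0_inf),
              if (is.na(x$cl_f)) "NA" else sprintf("%.4g", x$cl_f)))
  invisible(x)
}

#' NCA across a list of profiles
#'
#' @param profiles list of \code{pk_profile}s
#' @param doses_mg per-profile doses; defaults to each profile's attribute
#' @param weights optional per-profile weights, kg
#' @return data.frame with one row per profile (id, cmax, tmax, auc_0_t,
#'   auc_0_inf, lambda_z, cl_f, cl_f_per_kg)
#' @export
nca_table <- function(profiles, doses_mg = NULL, weights = NULL) {
  res <- lapply(seq_along(profiles), function(i) {
    r <- suppressWarnings(nca(profiles[[i]],
             dose_mg = if (is.null(doses_mg)) NULL else doses_mg[i],
             weight = if (is.null(weights)) NULL else weights[i]))
    data.frame(id = attr(profiles[[i]], "subject_id") %||% as.character(i),
               cmax = r$cmax, tmax = r$tmax, auc_0_t = r$auc_0_t,
               auc_0_inf = r$auc_0_inf, lambda_z = r$lambda_z,
               cl_f = r$cl_f, cl_f_per_kg = r$cl_f_per_kg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
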