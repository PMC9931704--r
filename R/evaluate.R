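#' Fold error (predicted/observed ratio)
#'
#' The per-observation accuracy ratio used throughout model evaluation:
#' \deqn{fold\;error = \frac{predicted}{observed}}
#'
#' @param observed,predicted positive values; vectorized
#' @return predicted/observed
#' @examples
#' fold_error(221.90, 523.00)   # 2.36
#' @export
fold_error <- function(observed, predicted) {
  .check_positive(observed, "observed")
  .check_positive(predicted, "predicted")
  predicted / observed
}

#' Average fold error
#'
#' \deqn{AFE = 10^{\sum \log_{10}(fold\;error) / N}}
#' i.e. the geometric mean of the fold errors; values near 1 indicate no
#' systematic over- or under-prediction.
#'
#' @param ratios positive fold errors, N >= 1
#' @return the AFE (dimensionless)
#' @examples
#' afe(c(2, 0.5))   # 1
#' @export
afe <- function(ratios) {
  if (length(ratios) < 1) stop("`ratios` must be non-empty", call. = FALSE)
  .check_positive(ratios, "ratios")
  10^(mean(log10(ratios)))
}

#' Mean ratio with t-based confidence interval
#'
#' Arithmetic mean of the fold errors with a normal-theory interval
#' \eqn{mean \pm t_{1-\alpha/2, N-1} \, sd/\sqrt{N}} on the raw ratio
#' scale; \code{log_scale = TRUE} computes the interval on log10 ratios
#' and back-transforms (geometric mean and CI).
#'
#' @param ratios positive fold errors, N >= 2
#' @param level confidence level (default 0.95)
#' @param log_scale construct the interval on the log scale
#' @return list(mean, ci = c(lo, hi), n, level)
#' @export
mean_ratio_ci <- function(ratios, level = 0.95, log_scale = FALSE) {
  .check_positive(ratios, "ratios")
  n <- length(ratios)
  if (n < 2) stop("insufficient data: need at least 2 ratios", call. = FALSE)
  x <- if (log_scale) log10(ratios) else ratios
  m <- mean(x)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(x) / sqrt(n)
  ci <- c(m - half, m + half)
  if (log_scale) { m <- 10^m; ci <- 10^ci }
  list(mean = m, ci = ci, n = n, level = level)
}

#' Two-fold (or k-fold) acceptance check
#'
#' Flags each ratio as inside the closed acceptance band \code{[lo, hi]}
#' (default two-fold, [0.5, 2]) and reports the within-band fraction.
#'
#' @param ratios positive fold errors
#' @param lo,hi band edges, inclusive
#' @return list(within = logical flags, fraction_within, n_within, n)
#' @examples
#' twofold_check(c(0.5, 2.0, 2.36))$fraction_within
#' twofold_check(2.36, hi = 2.4)$within
#' @export
twofold_check <- function(ratios, lo = 0.5, hi = 2.0) {
  .check_positive(ratios, "ratios")
  within <- ratios >= lo & ratios <= hi
  list(within = within, fraction_within = mean(within),
       n_within = sum(within), n = length(within), lo = lo, hi = hi)
}

#' Summarise a virtual population's profiles
#'
#' Per-timepoint mean, minimum, maximum and 5th/95th percentiles of
#' simulated concentrations across subjects. Percentiles use linear
#' interpolation between order statistics (\code{stats::quantile} type 7),
#' so small-n bands are reproducible. All profiles must share one time
#' grid.
#'
#' @param profiles list of \code{pk_profile}s (or data.frames with
#'   \code{time}, \code{conc}) on a common grid, length >= 2
#' @return object of class \code{pk_popsummary}: data.frame time, mean,
#'   min, max, p5, p95; attribute \code{n_profiles}
#' @export
population_summary <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  t0 <- profiles[[1]]$time
  for (p in profiles)
    if (length(p$time) != length(t0) || any(abs(p$time - t0) > 1e-9))
      stop("profiles are not on a common time grid", call. = FALSE)
  cmat <- sapply(profiles, function(p) p$conc)
  out <- data.frame(time = t0,
                    mean = apply(cmat, 1, mean),
                    min = apply(cmat, 1, min),
                    max = apply(cmat, 1, max),
                    p5 = apply(cmat, 1, quantile, probs = 0.05, type = 7, names = FALSE),
                    p95 = apply(cmat, 1, quantile, probs = 0.95, type = 7, names = FALSE))
  structure(out, n_profiles = length(profiles),
            class = c("pk_popsummary", "data.frame"))
}

#' Prediction-interval coverage
#'
#' Fraction of observed (time, concentration) points lying inside the
#' simulated 5th-95th percentile band (the 90% prediction interval). Band
#' edges are linearly interpolated at the observation times, which must
#' fall inside the simulated grid.
#'
#' @param observed a \code{pk_profile} / data.frame with \code{time},
#'   \code{conc}; non-empty
#' @param summary a \code{\link{population_summary}}
#' @param lower,upper band columns to use (defaults p5/p95)
#' @return coverage fraction in [0, 1]
#' @export
pi_coverage <- function(observed, summary, lower = "p5", upper = "p95") {
  if (is.null(observed$time) || length(observed$time) == 0)
    stop("empty observation set", call. = FALSE)
  if (min(observed$time) < min(summary$time) - 1e-9 ||
      max(observed$time) > max(summary$time) + 1e-9)
    stop("observed times fall outside the simulated grid", call. = FALSE)
  lo <- approx(summary$time, summary[[lower]], xout = observed$time)$y
  hi <- approx(summary$time, summary[[upper]], xout = observed$time)$y
  mean(observed$conc >= lo & observed$conc <= hi)
}

#' Evaluate predicted against observed PK parameters
#'
#' Builds the full evaluation report: per-observation fold errors,
#' arithmetic mean ratio with 95% CI, average fold error, and the
#' two-fold acceptance fraction. Optionally a prediction-interval
#' coverage (from \code{\link{pi_coverage}}) can be attached.
#'
#' @param observed,predicted positive parameter values, equal length
#' @param parameter label(s) for the parameter column (recycled)
#' @param twofold c(lo, hi) acceptance band
#' @param level CI level
#' @param pi_coverage optional coverage fraction to carry in the report
#' @return object of class \code{pk_evaluation}: list with \code{per_obs}
#'   data frame (parameter, observed, predicted, ratio, within_twofold),
#'   \code{mean_ratio}, \code{ci95}, \code{afe}, \code{n},
#'   \code{frac_within_twofold}, \code{pi_coverage}
#' @examples
#' ev <- evaluate_pk(c(100, 200), c(120, 150), parameter = "auc")
#' ev$afe
#' @export
evaluate_pk <- function(observed, predicted, parameter = "parameter",
                        twofold = c(0.5, 2), level = 0.95,
                        pi_coverage = NA_real_) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ", call. = FALSE)
  r <- fold_error(observed, predicted)
  tf <- twofold_check(r, twofold[1], twofold[2])
  ci <- if (length(r) >= 2) mean_ratio_ci(r, level) else list(mean = mean(r), ci = c(NA, NA))
  structure(list(
    per_obs = data.frame(parameter = rep_len(parameter, length(r)),
                         observed = observed, predicted = predicted,
                         ratio = r, within_twofold = tf$within,
                         stringsAsFactors = FALSE),
    mean_ratio = ci$mean, ci95 = ci$ci, afe = afe(r), n = length(r),
    frac_within_twofold = tf$fraction_within, pi_coverage = pi_coverage),
    class = "pk_evaluation")
}

#' @export
print.pk_evaluation <- function(x, ...) {
  cat(sprintf("<pk_evaluation> n = %d\n", x$n))
  cat(sprintf("  mean ratio (pred/obs): %.3f (95%% CI %.3f - %.3f)\n",
              x$mean_ratio, x$ci95[1], x$ci95[2]))
  cat(sprintf("  AFE: %.3f | within two-fold: %.0f%%\n",
              x$afe, 100 * x$frac_within_twofold))
  if (!is.na(x$pi_coverage))
    cat(sprintf("  90%% prediction-interval coverage: %.0f%%\n", 100 * x$pi_coverage))
  invisible(x)
}

#' @export
summary.pk_evaluation <- function(object, ...) {
  print(object)
  invisible(object$per_obs)
}

#' @export
plot.pk_popsummary <- function(x, observed = NULL, log = "", ...) {
  plot(x$time, x$mean, type = "n", ylim = range(c(x$min, x$max, observed$conc)),
       xlab = "Time (h)", ylab = "Concentration (ng/ml)", log = log, ...)
  polygon(c(x$time, rev(x$time)), c(x$p5, rev(x$p95)),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(x$time, x$mean, lwd = 2, col = "steelblue4")
  lines(x$time, x$min, lty = 3); lines(x$time, x$max, lty = 3)
  if (!is.null(observed)) points(observed$time, observed$conc, pch = 16)
  legend("topright", bty = "n", lwd = c(2, NA, 1), lty = c(1, NA, 3),
         pch = c(NA, 16, NA), col = c("steelblue4", "black", "black"),
         legend = c("mean (5th-95th band)", "observed", "min/max"))
  invisible(x)
}
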