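#' Load a packaged reference fixture
#'
#' The two pediatric reference tables ship with the package as plain CSV:
#' \describe{
#'   \item{\code{table1}}{demographics of the 14 pediatric subjects (6
#'     renal-failure subjects dosed in mg/kg at steady state; 8
#'     renal-scarring subjects with single mg doses), with age, weight
#'     (where reported), sex, serum creatinine and the eGFR printed in the
#'     source (treated as given data; the printed creatinine-based formula
#'     does not reproduce the pediatric values).}
#'   \item{\code{table2}}{observed and predicted AUC(0-t), Cmax and CL/F
#'     per subject with the printed pred/obs ratios; doses and clearance
#'     units resolved per the source footnotes (mg/kg and L/h/kg for the
#'     renal-failure study).}
#'   \item{\code{table2_quarantine}}{printed cells that are internally
#'     inconsistent (dose/AUC vs printed CL/F, or printed ratio vs
#'     recomputed pred/obs), retained verbatim, tagged and never silently
#'     corrected.}
#' }
#'
#' @param name \code{"table1"}, \code{"table2"} or
#'   \code{"table2_quarantine"}
#' @return a data.frame
#' @examples
#' nrow(load_fixture("table1"))    # 14
#' @export
load_fixture <- function(name = c("table1", "table2", "table2_quarantine")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_demographics.csv",
    table2 = "table2_pk_parameters.csv",
    table2_quarantine = "table2_quarantine.csv")
  path <- system.file("extdata", file, package = "capkd", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Specify a synthetic observed study
#'
#' Defines a virtual "clinical study" with known ground truth: subjects
#' sampled from the population model, concentration profiles simulated
#' from the disposition model, and multiplicative log-normal residual
#' error applied to produce the observed data.
#'
#' @param n_subjects number of subjects
#' @param age_range ages, years
#' @param ckd_stages named proportions of disease stages, summing to 1,
#'   e.g. \code{c(healthy = 0.5, severe = 0.5)}
#' @param dose_mg_per_kg,dose_mg dose rule (exactly one)
#' @param interval,n_doses repeated-dosing description (single dose when
#'   interval is NULL)
#' @param sampling_times observation times, h
#' @param residual_sd log-scale SD of the multiplicative residual error
#'   (0 = noise-free)
#' @param true_params the generating \code{\link{compound_params}}
#' @param seed RNG seed
#' @return object of class \code{synthetic_study_spec}
#' @export
synthetic_study_spec <- function(n_subjects = 20, age_range = c(2, 18),
                                 ckd_stages = c(healthy = 1),
                                 dose_mg_per_kg = 1, dose_mg = NULL,
                                 interval = NULL, n_doses = 1L,
                                 sampling_times = seq(0, 12, by = 0.5),
                                 residual_sd = 0.2,
                                 true_params = compound_params(),
                                 seed = 1L) {
  if (abs(sum(ckd_stages) - 1) > 1e-9)
    stop("`ckd_stages` proportions must sum to 1", call. = FALSE)
  if (any(residual_sd < 0)) stop("`residual_sd` must be >= 0", call. = FALSE)
  if (is.null(dose_mg) == is.null(dose_mg_per_kg))
    stop("give exactly one of `dose_mg` or `dose_mg_per_kg`", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 ckd_stages = ckd_stages, dose_mg_per_kg = dose_mg_per_kg,
                 dose_mg = dose_mg, interval = interval,
                 n_doses = as.integer(n_doses),
                 sampling_times = sampling_times, residual_sd = residual_sd,
                 true_params = true_params, seed = seed),
            class = "synthetic_study_spec")
}

#' Generate a synthetic observed study
#'
#' Samples subjects, simulates the noise-free truth per subject, applies
#' i.i.d. multiplicative log-normal residual error (mean-one, log-scale
#' SD \code{residual_sd}) to produce the observed profiles, and returns
#' the noise-free NCA truth for recovery testing. Fully deterministic
#' under the spec's seed.
#'
#' @param spec a \code{\link{synthetic_study_spec}}
#' @return list with \code{subjects} (a \code{pk_cohort}),
#'   \code{profiles} (observed, noisy), \code{true_profiles} (noise-free),
#'   \code{true_nca} (per-subject NCA of the noise-free profiles, incl.
#'   the true model CL/F = dose/AUCinf), \code{doses_mg}, \code{spec}
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  stages <- names(spec$ckd_stages)
  n_per <- floor(spec$ckd_stages * n)
  rem <- n - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1

  subjects <- NULL
  for (i in seq_along(stages)) {
    if (n_per[i] == 0) next
    sp <- population_spec(n_per[i], age_range = spec$age_range,
                          ckd_stage = stages[i], seed = NULL)
    subjects <- rbind(subjects, as.data.frame(sample_population(sp)))
  }
  subjects$id <- sprintf("SYN%03d", seq_len(nrow(subjects)))
  class(subjects) <- c("pk_cohort", "data.frame")

  profiles <- true_profiles <- vector("list", n)
  doses <- numeric(n)
  for (i in seq_len(n)) {
    subj <- as.list(subjects[i, ])
    reg <- dose_regimen(amount_mg = spec$dose_mg,
                        amount_mg_per_kg = spec$dose_mg_per_kg,
                        interval = spec$interval, n_doses = spec$n_doses,
                        sampling_times = spec$sampling_times)
    truth <- simulate_profile(subj, spec$true_params, reg)
    # mean-one multiplicative log-normal error, so observed concentrations
    # (and hence trapezoidal AUCs) are unbiased for the noise-free truth
    eps <- if (spec$residual_sd > 0)
      exp(rnorm(nrow(truth), -spec$residual_sd^2 / 2, spec$residual_sd))
    else rep(1, nrow(truth))
    obs <- truth
    obs$conc <- truth$conc * eps
    true_profiles[[i]] <- truth
    profiles[[i]] <- obs
    doses[i] <- attr(truth, "dose_mg")
  }
  true_nca <- nca_table(true_profiles, doses_mg = doses, weights = subjects$weight)
  list(subjects = subjects, profiles = profiles, true_profiles = true_profiles,
       true_nca = true_nca, doses_mg = doses, spec = spec)
}

#' Write a synthetic study to a directory
#'
#' Materialises \code{\link{generate_study}} output as the CSV set a
#' downstream analysis would read (subjects.csv, doses.csv, profiles.csv,
#' truth.csv) plus a manifest.json recording the seed and spec.
#'
#' @param study result of \code{\link{generate_study}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(study$subjects, file.path(dir, "subjects.csv"))
  write.csv(data.frame(id = study$subjects$id, dose_mg = study$doses_mg),
            file.path(dir, "doses.csv"), row.names = FALSE)
  prof <- do.call(rbind, lapply(seq_along(study$profiles), function(i)
    data.frame(subject_id = study$subjects$id[i],
               time_h = study$profiles[[i]]$time,
               conc_ng_ml = study$profiles[[i]]$conc,
               dose_mg = study$doses_mg[i],
               steady_state = isTRUE(attr(study$profiles[[i]], "steady_state")))))
  write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  write.csv(study$true_nca, file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- study$spec
  manifest <- list(seed = sp$seed, n_subjects = sp$n_subjects,
                   age_range = sp$age_range, ckd_stages = as.list(sp$ckd_stages),
                   dose_mg = sp$dose_mg, dose_mg_per_kg = sp$dose_mg_per_kg,
                   interval = sp$interval, n_doses = sp$n_doses,
                   residual_sd = sp$residual_sd,
                   package_version = as.character(utils::packageVersion("capkd")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read / write profile CSVs
#'
#' Long-format profile exchange: columns subject_id, time_h, conc_ng_ml,
#' dose_mg, steady_state.
#'
#' @param path CSV path
#' @return \code{read_profiles}: a named list of \code{pk_profile}s
#' @export
read_profiles <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(need %in% names(d)))
    stop("profile CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  out <- lapply(split(d, d$subject_id), function(g) {
    g <- g[order(g$time_h), ]
    .as_profile(g$time_h, g$conc_ng_ml, g$subject_id[1],
                if ("dose_mg" %in% names(g)) g$dose_mg[1] else NA_real_,
                if ("steady_state" %in% names(g)) isTRUE(g$steady_state[1]) else FALSE)
  })
  out[unique(d$subject_id)]
}
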