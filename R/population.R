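#' Body surface area from weight and height
#'
#' Haycock power-law BSA, the pediatric standard:
#' \deqn{BSA = 0.024265 \, W^{0.5378} \, H^{0.3964}}
#' with weight \eqn{W} in kg and height \eqn{H} in cm. The DuBois-DuBois
#' formula (\eqn{0.007184\,W^{0.425}\,H^{0.725}}) is available via
#' \code{method = "dubois"}.
#'
#' @param weight body weight, kg (> 0); vectorized
#' @param height body height, cm (> 0); vectorized
#' @param method \code{"haycock"} (default) or \code{"dubois"}
#' @return body surface area in m^2
#' @examples
#' compute_bsa(70, 170)            # adult reference, ~1.83 m2
#' compute_bsa(29.7, 121.5)        # 7-year-old
#' @export
compute_bsa <- function(weight, height, method = c("haycock", "dubois")) {
  method <- match.arg(method)
  .check_positive(weight, "weight")
  .check_positive(height, "height")
  switch(method,
    haycock = 0.024265 * weight^0.5378 * height^0.3964,
    dubois  = 0.007184 * weight^0.425  * height^0.725)
}

#' Median height for age
#'
#' Piecewise-linear approximation to median stature, used only to impute a
#' height for BSA when a dataset omits it: 50 cm at birth, 75 cm at 1 year,
#' 6 cm/year through age 12, then a linear adolescent phase reaching the
#' adult median (175 cm male, 163 cm female) at 18 years.
#'
#' @param age years (>= 0); vectorized
#' @param sex "M" or "F"; recycled
#' @return height in cm
#' @export
height_for_age <- function(age, sex = "M") {
  .check_positive(age, "age", strict = FALSE)
  sex <- rep_len(toupper(as.character(sex)), length(age))
  adult <- ifelse(sex == "F", 163, 175)
  h12 <- 75 + 6 * 11                                    # 141 cm at age 12
  h <- ifelse(age < 1, 50 + 25 * age,
       ifelse(age < 12, 75 + 6 * (age - 1),
       ifelse(age < 18, h12 + (adult - h12) * (age - 12) / 6, adult)))
  unname(h)
}

#' Median weight for age
#'
#' Piecewise-linear approximation to median pediatric weight (APLS-style):
#' 4.5 kg at birth rising to 10.5 kg at 1 year, \code{2.5*age + 8} kg from
#' 1 to 10 years, then linear to the adult median (70 kg male, 60 kg
#' female) at 18 years. Used when a subject table gives no weight.
#'
#' @inheritParams height_for_age
#' @return weight in kg
#' @export
weight_for_age <- function(age, sex = "M") {
  .check_positive(age, "age", strict = FALSE)
  sex <- rep_len(toupper(as.character(sex)), length(age))
  adult <- ifelse(sex == "F", 60, 70)
  w10 <- 2.5 * 10 + 8                                   # 33 kg at age 10
  w <- ifelse(age < 1, 4.5 + 6 * age,
       ifelse(age < 10, 2.5 * age + 8,
       ifelse(age < 18, w10 + (adult - w10) * (age - 10) / 8, adult)))
  unname(w)
}

#' GFR for age and CKD stage
#'
#' Healthy glomerular filtration rate follows a two-point maturation curve:
#' 20 ml/min/1.73 m^2 at birth rising piecewise-linearly to the adult level
#' of 120 ml/min/1.73 m^2 by age 1 year, constant thereafter. For a CKD
#' stage the value is drawn uniformly within the stage's GFR band (seeded
#' by the caller's RNG state).
#'
#' @param age years (>= 0); vectorized
#' @param ckd_stage one of \code{"healthy"}, \code{"mild"},
#'   \code{"moderate"}, \code{"severe"}, \code{"esrd"}
#' @return normalized GFR, ml/min/1.73 m^2
#' @examples
#' gfr_for_age(0)        # 20
#' gfr_for_age(10)       # 120
#' set.seed(1); gfr_for_age(10, "severe")   # uniform in [15, 30)
#' @export
gfr_for_age <- function(age, ckd_stage = "healthy") {
  .check_positive(age, "age", strict = FALSE)
  ckd_stage <- match.arg(ckd_stage, c("healthy", "mild", "moderate", "severe", "esrd"))
  if (ckd_stage == "healthy")
    return(unname(ifelse(age < 1, 20 + 100 * age, 120)))
  b <- stage_bands()
  band <- b[b$stage == ckd_stage, ]
  runif(length(age), band$gfr_min, band$gfr_max)
}

#' Specify a virtual population
#'
#' Collects the knobs of \code{\link{sample_population}}. When
#' \code{reference_subject} is given (a named list or one-row data frame
#' with at least \code{age} and \code{sex}; optionally \code{weight},
#' \code{height}, \code{gfr}, \code{serum_creatinine}, \code{id}), every
#' virtual subject keeps its age, sex and dose-relevant weight, and only
#' physiological covariates (GFR, hematocrit, unbound fraction) are
#' resampled.
#'
#' @param n number of virtual subjects (>= 1)
#' @param age_range [min, max] age in years (used when no reference subject)
#' @param sex_ratio fraction male, in [0, 1]
#' @param ckd_stage target disease stage for the cohort
#' @param reference_subject optional subject to match (see Details)
#' @param seed RNG seed for reproducibility
#' @param cv coefficients of variation for sampled covariates (log-normal
#'   for weight/height/GFR, normal for hematocrit and unbound fraction)
#' @param hematocrit,fu_plasma healthy central values; hematocrit 0.37 and
#'   captopril unbound fraction 0.70 by default (literature conventions)
#' @return an object of class \code{population_spec}
#' @export
population_spec <- function(n, age_range = c(1, 18), sex_ratio = 0.5,
                            ckd_stage = "healthy", reference_subject = NULL,
                            seed = NULL,
                            cv = list(weight = 0.15, height = 0.04, gfr = 0.10,
                                      hematocrit = 0.05, fu = 0.05),
                            hematocrit = 0.37, fu_plasma = 0.70) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  if (length(age_range) != 2 || age_range[1] > age_range[2] || age_range[1] < 0)
    stop("`age_range` must be [min, max] with 0 <= min <= max", call. = FALSE)
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("`sex_ratio` must lie in [0, 1]", call. = FALSE)
  ckd_stage <- match.arg(ckd_stage, c("healthy", "mild", "moderate", "severe", "esrd"))
  if (!is.null(reference_subject)) {
    reference_subject <- as.list(reference_subject)
    if (is.null(reference_subject$age) || is.null(reference_subject$sex))
      stop("`reference_subject` needs at least `age` and `sex`", call. = FALSE)
  }
  structure(list(n = as.integer(n), age_range = age_range, sex_ratio = sex_ratio,
                 ckd_stage = ckd_stage, reference_subject = reference_subject,
                 seed = seed, cv = cv, hematocrit = hematocrit,
                 fu_plasma = fu_plasma),
            class = "population_spec")
}

# healthy GFR sample: maturation median with log-normal spread, kept inside
# the healthy band (> 90) once maturation is complete (age >= 1); infants
# keep the raw maturation draw since staging bands do not apply pre-maturation
.sample_healthy_gfr <- function(age, center = NULL, cv = 0.10) {
  med <- if (is.null(center)) gfr_for_age(age) else rep_len(center, length(age))
  g <- med * rlnorm(length(age), 0, cv)
  mature <- age >= 1
  bad <- mature & g <= 90
  while (any(bad)) {                      # resample into the healthy band
    g[bad] <- med[bad] * rlnorm(sum(bad), 0, cv)
    bad <- mature & g <= 90
  }
  g
}

#' Sample a virtual cohort
#'
#' Draws \code{spec$n} virtual subjects. Ages are uniform over
#' \code{age_range} (or fixed to the reference subject's age), sex is
#' Bernoulli(\code{sex_ratio}) (or fixed), weight and height come from
#' median-for-age growth approximations with log-normal spread (or are
#' fixed to the reference values; a missing reference weight/height is
#' imputed from age and flagged in \code{weight_imputed}/
#' \code{height_imputed}). GFR is sampled per the cohort's CKD stage:
#' healthy around the maturation curve (truncated above 90 once mature),
#' diseased uniformly within the stage band. Identical spec and seed give
#' an identical cohort.
#'
#' @param spec a \code{\link{population_spec}}
#' @return a \code{data.frame} of class \code{pk_cohort}; one row per
#'   subject with columns id, age, sex, weight, height, height_imputed,
#'   weight_imputed, bsa, serum_creatinine, gfr, ckd_stage, hematocrit,
#'   fu_plasma, nonrenal_cl_fraction, fu_multiplier, hematocrit_delta,
#'   gastric_emptying_multiplier, kp_scalar, seed
#' @examples
#' cohort <- sample_population(population_spec(5, ckd_stage = "severe", seed = 1))
#' cohort$gfr                               # all within [15, 30)
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n; ref <- spec$reference_subject; cv <- spec$cv

  if (is.null(ref)) {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- ifelse(runif(n) < spec$sex_ratio, "M", "F")
    weight <- weight_for_age(age, sex) * rlnorm(n, 0, cv$weight)
    height <- height_for_age(age, sex) * rlnorm(n, 0, cv$height)
    weight_imputed <- height_imputed <- rep(TRUE, n)
    scr <- rep(NA_real_, n)
    gfr_center <- NULL
    id <- sprintf("VS%04d", seq_len(n))
  } else {
    age <- rep_len(as.numeric(ref$age), n)
    sex <- rep_len(as.character(ref$sex), n)
    w_ref <- if (!is.null(ref$weight) && !is.na(ref$weight)) as.numeric(ref$weight) else NA_real_
    h_ref <- if (!is.null(ref$height) && !is.na(ref$height)) as.numeric(ref$height) else NA_real_
    weight_imputed <- rep(is.na(w_ref), n)
    height_imputed <- rep(is.na(h_ref), n)
    weight <- rep_len(if (is.na(w_ref)) weight_for_age(age[1], sex[1]) else w_ref, n)
    height <- rep_len(if (is.na(h_ref)) height_for_age(age[1], sex[1]) else h_ref, n)
    scr <- rep_len(if (!is.null(ref$serum_creatinine)) as.numeric(ref$serum_creatinine) else NA_real_, n)
    gfr_center <- if (!is.null(ref$gfr) && !is.na(ref$gfr)) as.numeric(ref$gfr) else NULL
    base_id <- if (!is.null(ref$id)) as.character(ref$id) else "REF"
    id <- sprintf("%s-%04d", base_id, seq_len(n))
  }

  stage <- spec$ckd_stage
  gfr <- if (stage == "healthy") {
    .sample_healthy_gfr(age, center = gfr_center, cv = cv$gfr)
  } else {
    b <- stage_bands(); band <- b[b$stage == stage, ]
    if (band$gfr_min >= band$gfr_max) stop("empty GFR band for stage ", stage, call. = FALSE)
    runif(n, band$gfr_min, band$gfr_max)
  }

  hct <- pmin(pmax(rnorm(n, spec$hematocrit, spec$hematocrit * cv$hematocrit), 0.15), 0.6)
  fu <- pmin(pmax(rnorm(n, spec$fu_plasma, spec$fu_plasma * cv$fu), 0.05), 1)
  overlay <- ckd_overlay(stage)
  hct <- pmin(pmax(hct + overlay$hematocrit_delta, 0.1), 0.6)
  fu <- pmin(fu * overlay$fu_multiplier, 1)

  cohort <- data.frame(
    id = id, age = age, sex = sex, weight = weight, height = height,
    weight_imputed = weight_imputed, height_imputed = height_imputed,
    bsa = compute_bsa(weight, height), serum_creatinine = scr, gfr = gfr,
    ckd_stage = stage, hematocrit = hct, fu_plasma = fu,
    nonrenal_cl_fraction = overlay$nonrenal_cl_fraction,
    fu_multiplier = overlay$fu_multiplier,
    hematocrit_delta = overlay$hematocrit_delta,
    gastric_emptying_multiplier = overlay$gastric_emptying_multiplier,
    kp_scalar = overlay$kp_scalar,
    seed = if (is.null(spec$seed)) NA_integer_ else spec$seed,
    stringsAsFactors = FALSE)
  class(cohort) <- c("pk_cohort", "data.frame")
  cohort
}

#' Read / write a cohort table
#'
#' CSV round-trip for cohorts. On read, missing height is imputed from age
#' and sex (flagged in \code{height_imputed}); missing GFR is filled from
#' serum creatinine (Jelliffe, age >= 15) or the age-maturation curve
#' (under 15), mirroring the BSA-based-under-15 convention; missing CKD
#' stage is derived from GFR.
#'
#' @param path CSV file; columns id, age_years, sex, weight_kg and
#'   optionally height_cm, serum_creatinine_mg_dl, gfr, ckd_stage
#' @return a \code{pk_cohort} data frame
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age_years", "sex", "weight_kg")
  if (!all(need %in% names(d)))
    stop("cohort CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  height <- if ("height_cm" %in% names(d)) d$height_cm else rep(NA_real_, nrow(d))
  height_imputed <- is.na(height)
  height[height_imputed] <- height_for_age(d$age_years[height_imputed], d$sex[height_imputed])
  scr <- if ("serum_creatinine_mg_dl" %in% names(d)) d$serum_creatinine_mg_dl else rep(NA_real_, nrow(d))
  gfr <- if ("gfr" %in% names(d)) d$gfr else rep(NA_real_, nrow(d))
  fill <- is.na(gfr)
  gfr[fill] <- ifelse(d$age_years[fill] >= 15 & !is.na(scr[fill]),
                      jelliffe_egfr(d$age_years[fill], scr[fill], d$sex[fill]),
                      gfr_for_age(d$age_years[fill]))
  stage <- if ("ckd_stage" %in% names(d)) d$ckd_stage else stage_from_gfr(gfr)
  stage[is.na(stage)] <- stage_from_gfr(gfr[is.na(stage)])
  cohort <- data.frame(
    id = as.character(d$id), age = d$age_years, sex = d$sex, weight = d$weight_kg,
    height = height, weight_imputed = FALSE, height_imputed = height_imputed,
    bsa = compute_bsa(d$weight_kg, height), serum_creatinine = scr, gfr = gfr,
    ckd_stage = stage, stringsAsFactors = FALSE)
  class(cohort) <- c("pk_cohort", "data.frame")
  cohort
}

#' @rdname read_cohort
#' @param cohort a \code{pk_cohort}
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(id = cohort$id, age_years = cohort$age, sex = cohort$sex,
                    weight_kg = cohort$weight, height_cm = cohort$height,
                    height_imputed = cohort$height_imputed,
                    bsa_m2 = cohort$bsa,
                    serum_creatinine_mg_dl = cohort$serum_creatinine,
                    gfr = cohort$gfr, ckd_stage = cohort$ckd_stage,
                    hematocrit = cohort$hematocrit, fu_plasma = cohort$fu_plasma,
                    seed = cohort$seed)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d subjects, stage %s, ages %.1f-%.1f y\n",
              nrow(x), paste(unique(x$ckd_stage), collapse = "/"),
              min(x$age), max(x$age)))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more subjects\n")
  invisible(x)
}
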