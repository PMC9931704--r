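#' CKD staging bands
#'
#' GFR bands (ml/min/1.73 m^2) classifying kidney function: healthy
#' > 90, mild 60-90, moderate 30-60, severe 15-30, end-stage renal
#' disease < 15. A shared boundary value is classified into the more
#' severe band (see \code{\link{stage_from_gfr}}), so every non-negative
#' GFR belongs to exactly one stage. The numeric columns here give the
#' sampling range of each band.
#'
#' @return a data.frame with columns stage, gfr_min, gfr_max
#' @export
stage_bands <- function() {
  data.frame(stage = c("healthy", "mild", "moderate", "severe", "esrd"),
             gfr_min = c(90, 60, 30, 15, 0),
             gfr_max = c(Inf, 90, 60, 30, 15),
             stringsAsFactors = FALSE)
}

#' Export the staging table as JSON
#' @param path file to write; \code{NULL} returns the JSON string
#' @export
stage_bands_json <- function(path = NULL) {
  j <- jsonlite::toJSON(stage_bands(), dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

#' CKD stage from GFR
#'
#' @param gfr normalized GFR, ml/min/1.73 m^2 (>= 0); vectorized
#' @return character vector of stages. Healthy requires \code{gfr > 90};
#'   a boundary value belongs to the more severe band (90 is mild, 60 is
#'   moderate, 30 and 15 are severe), so the stages partition [0, Inf):
#'   esrd [0,15), severe [15,30], moderate (30,60], mild (60,90],
#'   healthy (90, Inf)
#' @examples
#' stage_from_gfr(c(61, 20, 90, 91))   # mild severe mild healthy
#' @export
stage_from_gfr <- function(gfr) {
  .check_positive(gfr, "gfr", strict = FALSE)
  out <- character(length(gfr))
  out[gfr > 90]              <- "healthy"
  out[gfr > 60 & gfr <= 90]  <- "mild"
  out[gfr > 30 & gfr <= 60]  <- "moderate"
  out[gfr >= 15 & gfr <= 30] <- "severe"
  out[gfr < 15]              <- "esrd"
  out
}

#' Jelliffe estimated GFR
#'
#' Creatinine-based eGFR:
#' \deqn{eGFR = \frac{98 - 0.8\,(age - 20)}{S_{cr}}}
#' multiplied by 0.9 for females, clamped at zero. Intended for subjects
#' 15 years and older; under 15 the age-maturation curve
#' (\code{\link{gfr_for_age}}) is the GFR source (see
#' \code{\link{gfr_for_subject}}).
#'
#' @param age years (>= 0)
#' @param serum_creatinine mg/dl (> 0)
#' @param sex "M" or "F"
#' @return eGFR, ml/min/1.73 m^2
#' @examples
#' jelliffe_egfr(20, 1.0, "M")   # 98
#' jelliffe_egfr(25, 1.0, "F")   # 84.6
#' @export
jelliffe_egfr <- function(age, serum_creatinine, sex = "M") {
  .check_positive(age, "age", strict = FALSE)
  .check_positive(serum_creatinine, "serum_creatinine")
  sex <- rep_len(toupper(as.character(sex)), length(age))
  g <- (98 - 0.8 * (age - 20)) / serum_creatinine
  g <- ifelse(sex == "F", 0.9 * g, g)
  pmax(g, 0)
}

#' GFR for a subject, by the age-dependent source hierarchy
#'
#' Under 15 years GFR comes from the BSA-based maturation convention
#' (\code{\link{gfr_for_age}}); at 15 years and above from serum
#' creatinine via \code{\link{jelliffe_egfr}} (falling back to the
#' maturation curve when creatinine is missing).
#'
#' @inheritParams jelliffe_egfr
#' @export
gfr_for_subject <- function(age, serum_creatinine = NA, sex = "M") {
  if (age >= 15 && !is.na(serum_creatinine))
    jelliffe_egfr(age, serum_creatinine, sex)
  else
    gfr_for_age(age)
}

#' Disease overlay for a CKD stage
#'
#' Pathophysiological multipliers applied to a healthy subject when CKD is
#' imposed. Non-renal clearance is retained at 100% (healthy), 80% (mild),
#' 70% (moderate; interpolated between the stated mild and severe values)
#' and 60% (severe). The remaining knobs (unbound-fraction multiplier,
#' hematocrit shift, gastric-emptying multiplier, Kp scalar) default to
#' mild literature-convention changes and are fully overridable through
#' \code{config}.
#'
#' @param stage CKD stage
#' @param config optional named list of per-stage overrides, e.g.
#'   \code{list(severe = list(nonrenal_cl_fraction = 0.5))}
#' @return an object of class \code{ckd_overlay}: nonrenal_cl_fraction,
#'   fu_multiplier, hematocrit_delta, gastric_emptying_multiplier,
#'   kp_scalar
#' @examples
#' ckd_overlay("mild")$nonrenal_cl_fraction     # 0.8
#' ckd_overlay("severe")$nonrenal_cl_fraction   # 0.6
#' @export
ckd_overlay <- function(stage = "healthy", config = NULL) {
  stage <- match.arg(stage, c("healthy", "mild", "moderate", "severe", "esrd"))
  defaults <- list(
    healthy  = list(nonrenal_cl_fraction = 1.0, fu_multiplier = 1.00,
                    hematocrit_delta = 0.00, gastric_emptying_multiplier = 1.00,
                    kp_scalar = 1),
    mild     = list(nonrenal_cl_fraction = 0.8, fu_multiplier = 1.02,
                    hematocrit_delta = -0.02, gastric_emptying_multiplier = 1.10,
                    kp_scalar = 1),
    moderate = list(nonrenal_cl_fraction = 0.7, fu_multiplier = 1.05,
                    hematocrit_delta = -0.05, gastric_emptying_multiplier = 1.25,
                    kp_scalar = 1),
    severe   = list(nonrenal_cl_fraction = 0.6, fu_multiplier = 1.10,
                    hematocrit_delta = -0.08, gastric_emptying_multiplier = 1.50,
                    kp_scalar = 1),
    esrd     = list(nonrenal_cl_fraction = 0.5, fu_multiplier = 1.15,
                    hematocrit_delta = -0.10, gastric_emptying_multiplier = 1.75,
                    kp_scalar = 1))
  ov <- defaults[[stage]]
  if (!is.null(config) && !is.null(config[[stage]]))
    ov[names(config[[stage]])] <- config[[stage]]
  if (ov$nonrenal_cl_fraction <= 0 || ov$nonrenal_cl_fraction > 1)
    stop("nonrenal_cl_fraction must lie in (0, 1]", call. = FALSE)
  structure(c(ov, list(stage = stage)), class = "ckd_overlay")
}

#' Impose a CKD stage on a healthy subject
#'
#' Returns a copy of \code{subject} with GFR resampled uniformly into the
#' requested stage band (healthy stage keeps the subject's own GFR), the
#' disease overlay fields attached, and hematocrit / unbound fraction
#' adjusted per the overlay. The input subject is not modified. The
#' simulated disease states are healthy, mild, moderate and severe;
#' end-stage renal disease is rejected (dialysis is out of scope).
#'
#' @param subject named list or one-row data frame with healthy baseline
#'   physiology (fields: gfr, hematocrit, fu_plasma, ...)
#' @param stage target stage
#' @param config overlay overrides, see \code{\link{ckd_overlay}}
#' @return the diseased subject (same representation as input)
#' @export
apply_ckd <- function(subject, stage, config = NULL) {
  stage <- match.arg(stage, c("healthy", "mild", "moderate", "severe", "esrd"))
  if (stage == "esrd")
    stop("unsupported stage: end-stage renal disease (dialysis) is not modelled",
         call. = FALSE)
  is_df <- is.data.frame(subject)
  s <- as.list(subject)
  ov <- ckd_overlay(stage, config)
  if (stage != "healthy") {
    b <- stage_bands(); band <- b[b$stage == stage, ]
    s$gfr <- runif(length(s$gfr), band$gfr_min, band$gfr_max)
  }
  if (!is.null(s$hematocrit)) s$hematocrit <- pmax(s$hematocrit + ov$hematocrit_delta, 0.1)
  if (!is.null(s$fu_plasma))  s$fu_plasma  <- pmin(s$fu_plasma * ov$fu_multiplier, 1)
  s$ckd_stage <- stage
  s$nonrenal_cl_fraction <- ov$nonrenal_cl_fraction
  s$fu_multiplier <- ov$fu_multiplier
  s$hematocrit_delta <- ov$hematocrit_delta
  s$gastric_emptying_multiplier <- ov$gastric_emptying_multiplier
  s$kp_scalar <- ov$kp_scalar
  if (is_df) as.data.frame(s, stringsAsFactors = FALSE) else s
}
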