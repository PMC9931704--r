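#' Pipeline configuration
#'
#' Collects every knob of \code{\link{run_pipeline}} with validated
#' defaults. Unknown keys are rejected. A configuration can also be read
#' from JSON or YAML with \code{\link{read_config}}; keys there mirror the
#' arguments (\code{compound:}, \code{disease:}, \code{n_virtual:} ...).
#'
#' @param compound a \code{\link{compound_params}} or named list of
#'   overrides to the captopril defaults
#' @param disease per-stage overlay overrides (see \code{\link{ckd_overlay}})
#' @param n_virtual virtual subjects per reference subject (100 mirrors
#'   the evaluation convention)
#' @param ss_interval dosing interval for steady-state regimens, h (q8h
#'   pediatric captopril practice)
#' @param ss_sampling_times sampling grid within a steady-state interval, h
#' @param single_sampling_times sampling grid for single-dose regimens, h
#' @param seed base RNG seed; subject-level seeds are derived from it
#' @param out_dir optional directory for intermediate CSVs and the manifest
#' @return object of class \code{pipeline_config}
#' @export
pipeline_config <- function(compound = compound_params(), disease = NULL,
                            n_virtual = 100, ss_interval = 8,
                            ss_sampling_times = seq(0.25, 8, by = 0.25),
                            single_sampling_times = seq(0.25, 24, by = 0.25),
                            seed = 1L, out_dir = NULL) {
  if (!inherits(compound, "compound_params"))
    compound <- do.call(compound_params, as.list(compound))
  .check_positive(n_virtual, "n_virtual")
  .check_positive(ss_interval, "ss_interval")
  structure(list(compound = compound, disease = disease,
                 n_virtual = as.integer(n_virtual), ss_interval = ss_interval,
                 ss_sampling_times = ss_sampling_times,
                 single_sampling_times = single_sampling_times,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file ending in .json, .yaml or .yml
#' @return a \code{\link{pipeline_config}}
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml", call. = FALSE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, cfg)
}

# reference subject (one table1 row) -> virtual cohort + per-subject NCA
.predict_for_reference <- function(row, config, seed) {
  stage <- stage_from_gfr(row$egfr)
  weight <- row$weight_kg
  w_imputed <- is.na(weight)
  if (w_imputed) weight <- weight_for_age(row$age_years, row$sex)
  ref <- list(id = row$id, age = row$age_years, sex = row$sex,
              weight = weight, gfr = row$egfr,
              serum_creatinine = row$serum_creatinine_mg_dl)
  spec <- population_spec(config$n_virtual, ckd_stage = stage,
                          reference_subject = ref, seed = seed)
  cohort <- sample_population(spec)
  # overlay overrides from the disease config (stage fractions etc.)
  if (!is.null(config$disease)) {
    ov <- ckd_overlay(stage, config$disease)
    cohort$nonrenal_cl_fraction <- ov$nonrenal_cl_fraction
    cohort$gastric_emptying_multiplier <- ov$gastric_emptying_multiplier
    cohort$kp_scalar <- ov$kp_scalar
  }
  ss <- identical(row$regimen, "steady_state")
  reg <- if (ss) {
    dose_regimen(amount_mg_per_kg = row$dose, interval = config$ss_interval,
                 sampling_times = config$ss_sampling_times)
  } else if (identical(row$dose_unit, "mg_per_kg")) {
    dose_regimen(amount_mg_per_kg = row$dose,
                 sampling_times = config$single_sampling_times)
  } else {
    dose_regimen(amount_mg = row$dose,
                 sampling_times = config$single_sampling_times)
  }
  profiles <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    subj <- as.list(cohort[i, ])
    profiles[[i]] <- if (ss)
      simulate_to_steady_state(subj, config$compound, reg)
    else
      simulate_profile(subj, config$compound, reg)
  }
  doses <- vapply(profiles, function(p) attr(p, "dose_mg"), numeric(1))
  tab <- nca_table(profiles, doses_mg = doses, weights = cohort$weight)
  list(id = row$id, stage = stage, weight_imputed = w_imputed,
       cohort = cohort, profiles = profiles, nca = tab,
       summary = population_summary(profiles),
       pred = c(auc = mean(tab$auc_0_t), cmax = mean(tab$cmax),
                clf = mean(tab$cl_f), clf_per_kg = mean(tab$cl_f_per_kg)))
}

#' Run the end-to-end prediction pipeline
#'
#' For each reference subject (by default the packaged demographics
#' table): stage the kidney disease from the reported eGFR, build a
#' virtual cohort matched on age/sex/weight with the stage's disease
#' overlay, simulate the reported regimen (steady-state mg/kg q8h for the
#' renal-failure study, single oral doses for the renal-scarring study),
#' run NCA per virtual subject, average to population-predicted AUC(0-t),
#' Cmax and CL/F, and evaluate against the observed parameter table with
#' fold-error / AFE / two-fold metrics. Reruns with the same config are
#' deterministic.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param subjects demographics table (default packaged \code{table1})
#' @param observed observed parameter table (default packaged
#'   \code{table2}); set NULL to skip evaluation
#' @return object of class \code{capkd_pipeline}: \code{predictions}
#'   (per-subject predicted vs observed data frame), \code{evaluations}
#'   (list of \code{pk_evaluation} by parameter), \code{per_reference}
#'   (cohort/profiles/NCA/summary per reference subject), \code{config}
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_virtual = 10, seed = 1))
#' res$evaluations$auc
#' }
#' @export
run_pipeline <- function(config = pipeline_config(),
                         subjects = load_fixture("table1"),
                         observed = load_fixture("table2")) {
  stopifnot(inherits(config, "pipeline_config"))
  per_ref <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    row <- as.list(subjects[i, ])
    per_ref[[i]] <- .predict_for_reference(row, config,
                                           seed = config$seed + 1000L * i)
  }
  names(per_ref) <- subjects$id
  pred <- do.call(rbind, lapply(per_ref, function(r)
    data.frame(id = r$id, stage = r$stage,
               auc_pred = r$pred[["auc"]], cmax_pred = r$pred[["cmax"]],
               clf_pred = r$pred[["clf"]], clf_per_kg_pred = r$pred[["clf_per_kg"]],
               stringsAsFactors = FALSE)))
  rownames(pred) <- NULL

  evaluations <- NULL
  if (!is.null(observed)) {
    m <- match(observed$id, pred$id)
    if (anyNA(m)) stop("observed table has ids absent from the subject table: ",
                       paste(observed$id[is.na(m)], collapse = ", "), call. = FALSE)
    obs_clf_unit_kg <- observed$dose_unit == "mg_per_kg"
    clf_pred_matched <- ifelse(obs_clf_unit_kg,
                               pred$clf_per_kg_pred[m], pred$clf_pred[m])
    evaluations <- list(
      auc = evaluate_pk(observed$auc_obs, pred$auc_pred[m], parameter = "auc_0_t"),
      cmax = evaluate_pk(observed$cmax_obs, pred$cmax_pred[m], parameter = "cmax"),
      clf = evaluate_pk(observed$clf_obs, clf_pred_matched, parameter = "cl_f"))
    pred <- cbind(pred[m, ],
                  auc_obs = observed$auc_obs, cmax_obs = observed$cmax_obs,
                  clf_obs = observed$clf_obs,
                  auc_ratio = evaluations$auc$per_obs$ratio,
                  cmax_ratio = evaluations$cmax$per_obs$ratio,
                  clf_ratio = evaluations$clf$per_obs$ratio)
    rownames(pred) <- NULL
  }

  out <- structure(list(predictions = pred, evaluations = evaluations,
                        per_reference = per_ref, config = config),
                   class = "capkd_pipeline")
  if (!is.null(config$out_dir)) .write_pipeline_artifacts(out, config$out_dir)
  out
}

.write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$predictions, file.path(dir, "predictions.csv"), row.names = FALSE)
  nca_all <- do.call(rbind, lapply(names(res$per_reference), function(nm) {
    x <- res$per_reference[[nm]]$nca; x$reference <- nm; x
  }))
  write.csv(nca_all, file.path(dir, "virtual_nca.csv"), row.names = FALSE)
  if (!is.null(res$evaluations)) {
    rep <- do.call(rbind, lapply(names(res$evaluations), function(p) {
      e <- res$evaluations[[p]]
      data.frame(parameter = p, n = e$n, mean_ratio = e$mean_ratio,
                 ci_lo = e$ci95[1], ci_hi = e$ci95[2], afe = e$afe,
                 frac_within_twofold = e$frac_within_twofold)
    }))
    write.csv(rep, file.path(dir, "evaluation_report.csv"), row.names = FALSE)
    jsonlite::write_json(rep, file.path(dir, "evaluation_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(seed = res$config$seed, n_virtual = res$config$n_virtual,
                   ss_interval = res$config$ss_interval,
                   compound = unclass(res$config$compound),
                   package_version = as.character(utils::packageVersion("capkd")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.capkd_pipeline <- function(x, ...) {
  cat(sprintf("<capkd_pipeline> %d reference subjects x %d virtual subjects each\n",
              length(x$per_reference), x$config$n_virtual))
  if (!is.null(x$evaluations)) for (p in names(x$evaluations)) {
    e <- x$evaluations[[p]]
    cat(sprintf("  %-5s mean ratio %.2f (95%% CI %.2f-%.2f), AFE %.2f, %2.0f%% within two-fold\n",
                p, e$mean_ratio, e$ci95[1], e$ci95[2], e$afe,
                100 * e$frac_within_twofold))
  }
  invisible(x)
}

#' Predicted CL/F by CKD stage for a fixed subject
#'
#' Deterministic stage comparison on one subject: the disease overlay of
#' each stage is applied with the stage's representative GFR (healthy:
#' 120; otherwise the band midpoint), a single oral dose is simulated and
#' per-kg oral clearance extracted by NCA. Used to check that predicted
#' CL/F declines monotonically with CKD severity.
#'
#' @param age,weight,sex subject description (weight imputed from age
#'   when NULL)
#' @param stages stages to compare, in order
#' @param params \code{\link{compound_params}}
#' @param dose_mg_per_kg simulated dose
#' @param sampling_times simulation grid, h
#' @return named numeric vector of CL/F in L/h/kg per stage
#' @export
clf_by_stage <- function(age = 8, weight = NULL, sex = "M",
                         stages = c("healthy", "mild", "severe"),
                         params = compound_params(), dose_mg_per_kg = 1,
                         sampling_times = seq(0.25, 24, by = 0.25)) {
  if (is.null(weight)) weight <- weight_for_age(age, sex)
  b <- stage_bands()
  out <- setNames(numeric(length(stages)), stages)
  for (st in stages) {
    ov <- ckd_overlay(st)
    gfr <- if (st == "healthy") 120 else {
      band <- b[b$stage == st, ]; (band$gfr_min + band$gfr_max) / 2
    }
    subj <- list(id = st, age = age, sex = sex, weight = weight, gfr = gfr,
                 nonrenal_cl_fraction = ov$nonrenal_cl_fraction,
                 gastric_emptying_multiplier = ov$gastric_emptying_multiplier,
                 kp_scalar = ov$kp_scalar)
    prof <- simulate_profile(subj, params,
                             dose_regimen(amount_mg_per_kg = dose_mg_per_kg,
                                          sampling_times = sampling_times))
    r <- suppressWarnings(nca(prof, weight = weight))
    out[st] <- r$cl_f_per_kg
  }
  out
}
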