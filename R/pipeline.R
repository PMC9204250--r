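# Pipeline orchestration: the three checkpoints of the screening workflow.
#
#   run_simulate()      cohort CSVs + ground-truth JSON
#   run_fit()           preprocessing -> mixtures -> cross-validated EBM
#                       -> model JSON
#   run_stage_analyze() stage trial baselines -> stratify -> primary and
#                       secondary outcome analyses -> result CSVs
#
# Each step reads/writes plain files so runs are resumable and auditable;
# every run writes a manifest (config, seeds, versions) sufficient to
# reproduce it exactly.

#' Default pipeline configuration
#'
#' A nested list mirroring the feature-spec, trial-design, model and analysis
#' settings, with every seed explicit. Saved to and loaded from YAML
#' losslessly by [write_config()] / [load_config()].
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(
    features = lapply(ad_cognitive_battery(), spec_to_list),
    reference = list(n_cn = 229, n_ad = 181, n_mci = 400,
                     stage_geom_p = 0.5, covariate_effects = TRUE,
                     apoe4_rate = 0.47),
    trial = list(
      n_per_arm = list(placebo = 259, vitaminE = 257, donepezil = 253),
      visit_interval = 6, trial_length = 36,
      dropout_rate_per_visit = 0.05,
      baseline_hazard = 0.004, stage_log_hazard_slope = 0.15,
      late_weight = 0.16,
      hr = list(list(arm = "donepezil", subgroup = "Late-stage", hr = 0.55),
                list(arm = "donepezil", subgroup = "Others", hr = 1),
                list(arm = "vitaminE", subgroup = "Late-stage", hr = 1),
                list(arm = "vitaminE", subgroup = "Others", hr = 1))
    ),
    preprocessing = list(adjust = TRUE,
                         covariates = c("age", "education"),
                         reference_label = "CN"),
    ebm = list(folds = 5, repeats = 10, n_startpoints = 10, n_iter = 10000,
               include_unlabeled = TRUE),
    stratification = list(threshold = 8),
    analysis = list(placebo_label = "placebo",
                    arms = c("donepezil", "vitaminE"),
                    covariates = c("age", "mmse", "apoe4"),
                    secondary_arm = "donepezil",
                    visits = seq(6, 36, by = 6)),
    seeds = list(simulate = 42, fit = 42)
  )
}

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    if (nm %in% names(base) && is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' User settings are merged over [default_config()], so a config file only
#' needs the fields it changes; all defaults (including seeds) are
#' materialized in the returned list.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Full configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  if (length(cfg$features) < 2) {
    stop("invalid config: 'features' needs at least 2 entries")
  }
  for (f in cfg$features) {
    tryCatch(list_to_spec(f), error = function(e) {
      stop("invalid config: features entry '", f$name %||% "?", "': ",
           conditionMessage(e))
    })
  }
  tr <- cfg$trial
  if (tr$trial_length %% tr$visit_interval != 0) {
    stop("invalid config: trial.visit_interval must divide trial.trial_length")
  }
  if (tr$dropout_rate_per_visit < 0 || tr$dropout_rate_per_visit >= 1) {
    stop("invalid config: trial.dropout_rate_per_visit must be in [0, 1)")
  }
  for (h in tr$hr) {
    if (h$hr <= 0) stop("invalid config: trial.hr entries must be positive")
  }
  if (cfg$ebm$folds < 2) stop("invalid config: ebm.folds must be >= 2")
  invisible(cfg)
}

config_specs <- function(cfg) {
  lapply(cfg$features, function(f) {
    f[vapply(f, is.null, logical(1))] <- NA_real_
    list_to_spec(f)
  })
}

config_hr <- function(cfg) {
  tibble::tibble(
    arm = vapply(cfg$trial$hr, `[[`, character(1), "arm"),
    subgroup = vapply(cfg$trial$hr, `[[`, character(1), "subgroup"),
    hr = vapply(cfg$trial$hr, function(h) as.numeric(h$hr), numeric(1))
  )
}

config_design <- function(cfg) {
  trial_design(
    n_per_arm = unlist(cfg$trial$n_per_arm),
    visit_interval = cfg$trial$visit_interval,
    trial_length = cfg$trial$trial_length,
    dropout_rate_per_visit = cfg$trial$dropout_rate_per_visit,
    baseline_hazard = cfg$trial$baseline_hazard,
    stage_log_hazard_slope = cfg$trial$stage_log_hazard_slope
  )
}

write_manifest <- function(out_dir, step, cfg, extra = list()) {
  manifest <- c(list(
    step = step,
    config = cfg,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("stagescreen")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ), extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

log_msg <- function(...) message("[stagescreen] ", ...)

#' Simulate reference and trial cohorts to disk
#'
#' Generates the synthetic reference cohort and trial cohort under the
#' configuration and writes `reference.csv`, `trial.csv`,
#' `ground_truth_reference.json`, `ground_truth_trial.json` and a manifest to
#' `out_dir`.
#'
#' @param config Config list (from [load_config()]) or path to a YAML file;
#'   `NULL` for defaults.
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides `seeds$simulate` from the config when given.
#' @return Invisibly, a list with the two cohorts and truths.
#' @export
run_simulate <- function(config = NULL, out_dir = ".", seed = NULL) {
  cfg <- if (is.character(config)) load_config(config)
  else validate_config(merge_config(default_config(), config))
  if (!is.null(seed)) cfg$seeds$simulate <- seed
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    log_msg("created output directory ", out_dir)
  }
  specs <- config_specs(cfg)
  rc <- cfg$reference
  ref <- generate_reference_cohort(
    specs, n_cn = rc$n_cn, n_ad = rc$n_ad, n_mci = rc$n_mci,
    seed = cfg$seeds$simulate, stage_geom_p = rc$stage_geom_p,
    covariate_effects = rc$covariate_effects, apoe4_rate = rc$apoe4_rate)
  trial <- generate_trial_cohort(
    specs, ref$truth$true_sequence, design = config_design(cfg),
    hr_config = config_hr(cfg), seed = cfg$seeds$simulate + 1L,
    late_threshold = cfg$stratification$threshold,
    late_weight = cfg$trial$late_weight)
  write_cohort_csv(ref$cohort, file.path(out_dir, "reference.csv"))
  write_cohort_csv(trial$cohort, file.path(out_dir, "trial.csv"))
  write_truth_json(ref$truth,
                   file.path(out_dir, "ground_truth_reference.json"))
  write_truth_json(trial$truth, file.path(out_dir, "ground_truth_trial.json"))
  write_manifest(out_dir, "simulate", cfg,
                 list(n_reference = nrow(ref$cohort),
                      n_trial = nrow(trial$cohort)))
  log_msg("simulated ", nrow(ref$cohort), " reference and ",
          nrow(trial$cohort), " trial subjects into ", out_dir)
  invisible(list(reference = ref, trial = trial, config = cfg))
}

#' Fit the reference event-based model and serialize it
#'
#' Complete-case filtering on the model features, covariate adjustment
#' fitted on the reference-label group, cross-validated KDE-EBM fit, and
#' JSON serialization of the result.
#'
#' @param reference Reference cohort: a data frame or a CSV path.
#' @param config Config list or YAML path; `NULL` for defaults.
#' @param out_model Path of the model JSON to write (`NULL` to skip).
#' @param seed Overrides `seeds$fit` when given.
#' @return The `ebm_fit`, invisibly.
#' @export
run_fit <- function(reference, config = NULL, out_model = "model.json",
                    seed = NULL) {
  cfg <- if (is.character(config)) load_config(config)
  else validate_config(merge_config(default_config(), config))
  if (!is.null(seed)) cfg$seeds$fit <- seed
  cohort <- if (is.character(reference)) read_cohort_csv(reference)
  else tibble::as_tibble(reference)
  specs <- config_specs(cfg)
  feats <- spec_names(specs)
  absent <- setdiff(c(feats, "diagnosis"), names(cohort))
  if (length(absent)) {
    stop("reference cohort is missing columns: ",
         paste(absent, collapse = ", "))
  }
  cohort <- complete_case_filter(cohort, feats, quiet = TRUE)
  adjustment <- NULL
  if (isTRUE(cfg$preprocessing$adjust)) {
    adjustment <- fit_covariate_adjustment(
      cohort, feats, covariates = cfg$preprocessing$covariates,
      reference_label = cfg$preprocessing$reference_label)
    cohort <- apply_covariate_adjustment(adjustment, cohort)
  }
  fit <- cross_validated_fit(
    cohort, specs, folds = cfg$ebm$folds, repeats = cfg$ebm$repeats,
    seed = cfg$seeds$fit, n_startpoints = cfg$ebm$n_startpoints,
    n_iter = cfg$ebm$n_iter, include_unlabeled = cfg$ebm$include_unlabeled,
    adjustment = adjustment)
  if (!is.null(out_model)) {
    write_model_json(fit, out_model)
    log_msg("model written to ", out_model)
  }
  invisible(fit)
}

#' Stage, stratify and analyze a trial cohort
#'
#' Stages the trial baselines with a reference-trained model (applying the
#' model's covariate adjustment), stratifies at the stage threshold, runs the
#' primary (Kaplan-Meier + Cox + Hochberg) and secondary (per-visit
#' Mann-Whitney + Hochberg) analyses, and writes `stages.csv`, `groups.csv`,
#' a `results/` directory (`primary.csv`, `secondary.csv`,
#' `km_<stratum>_<arm>.csv`, `positional_density.csv`) and a manifest.
#'
#' @param model An `ebm_fit` or path to a model JSON.
#' @param trial Trial cohort data frame or CSV path.
#' @param threshold Stage threshold (strictly-greater rule); defaults to the
#'   config value.
#' @param out_dir Output directory.
#' @param config Config list or YAML path; `NULL` for defaults.
#' @return Invisibly: list(stages, labeling, primary, secondary).
#' @export
run_stage_analyze <- function(model, trial, threshold = NULL, out_dir = ".",
                              config = NULL) {
  cfg <- if (is.character(config)) load_config(config)
  else validate_config(merge_config(default_config(), config))
  threshold <- threshold %||% cfg$stratification$threshold
  fit <- if (is.character(model)) read_model_json(model) else model
  stopifnot(inherits(fit, "ebm_fit"))
  cohort <- if (is.character(trial)) read_cohort_csv(trial)
  else tibble::as_tibble(trial)
  if (!dir.exists(file.path(out_dir, "results"))) {
    dir.create(file.path(out_dir, "results"), recursive = TRUE)
  }
  stages <- stage_cohort(cohort, fit)
  labeling <- stratify_by_stage(stages, threshold = threshold)
  primary <- primary_outcome_analysis(
    cohort, labeling, arms = intersect(cfg$analysis$arms, cohort$arm),
    covariates = cfg$analysis$covariates,
    placebo_label = cfg$analysis$placebo_label)
  secondary <- secondary_outcome_analysis(
    cohort, labeling, treatment_arm = cfg$analysis$secondary_arm,
    placebo_label = cfg$analysis$placebo_label,
    visits = cfg$analysis$visits)

  stages_out <- tibble::tibble(
    subject_id = stages$subject_id,
    stage = stages$stage,
    stage_posterior = vapply(stages$stage_posterior, function(p) {
      jsonlite::toJSON(p, digits = NA)
    }, character(1))
  )
  readr::write_csv(stages_out, file.path(out_dir, "stages.csv"))
  readr::write_csv(labeling[, c("subject_id", "subgroup")],
                   file.path(out_dir, "groups.csv"))
  readr::write_csv(primary$cox, file.path(out_dir, "results", "primary.csv"))
  readr::write_csv(secondary, file.path(out_dir, "results", "secondary.csv"))
  for (st in unique(primary$km$stratum)) {
    for (a in unique(primary$km$arm[primary$km$stratum == st])) {
      km <- primary$km[primary$km$stratum == st & primary$km$arm == a,
                       c("time", "at_risk", "survival", "ci_low", "ci_high")]
      readr::write_csv(km, file.path(out_dir, "results",
                                     sprintf("km_%s_%s.csv",
                                             gsub("[^A-Za-z0-9]", "", st), a)))
    }
  }
  write_positional_density_csv(
    fit$positional_density,
    file.path(out_dir, "results", "positional_density.csv"))
  write_manifest(out_dir, "stage_analyze", cfg,
                 list(threshold = threshold,
                      subgroup_counts = as.list(attr(labeling, "counts"))))
  log_msg("staged ", nrow(stages), " subjects; subgroups: ",
          paste(names(attr(labeling, "counts")), attr(labeling, "counts"),
                sep = "=", collapse = ", "))
  invisible(list(stages = stages, labeling = labeling,
                 primary = primary, secondary = secondary))
}
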