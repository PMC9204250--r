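# Synthetic reference and trial cohorts with known ground truth.
#
# The generator follows the cumulative-event view of disease progression: a
# subject at stage k has experienced the first k events of a fixed sequence,
# so features at sequence positions <= k are drawn from their abnormal
# distribution and the rest from their normal distribution, then clipped to
# instrument bounds (producing realistic floor/ceiling pile-up).

run_with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# sample with replacement without the 1:x surprise of sample()
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# truncated geometric over 0..k_max, mass decaying from the `from` end
rtrunc_geom <- function(n, p, k_max, from = c("low", "high")) {
  from <- match.arg(from)
  probs <- (1 - p)^(0:k_max)
  draws <- sample(0:k_max, n, replace = TRUE, prob = probs / sum(probs))
  if (from == "high") k_max - draws else draws
}

clip_bounds <- function(x, lo, hi) {
  if (!is.na(lo)) x <- pmax(x, lo)
  if (!is.na(hi)) x <- pmin(x, hi)
  x
}

draw_demographics <- function(n, apoe4_rate) {
  age <- rnorm(n, 73, 7.3)
  education <- rnorm(n, 14.6, 3.1)
  # truncate positive by redraw-free reflection at a small floor
  education <- pmax(education, 1)
  age <- pmax(age, 40)
  tibble::tibble(
    age = age,
    education = education,
    sex = ifelse(runif(n) < 0.46, "female", "male"),
    apoe4 = rbinom(n, 1, apoe4_rate)
  )
}

# feature draws for subjects with known stages under a fixed event sequence
draw_feature_matrix <- function(specs, sequence, stage, demo,
                                covariate_effects = TRUE) {
  n <- length(stage)
  k <- length(specs)
  pos <- match(spec_names(specs), sequence)  # sequence position of each feature
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, spec_names(specs)))
  for (i in seq_len(k)) {
    s <- specs[[i]]
    abnormal <- pos[i] <= stage
    x <- ifelse(abnormal,
                rnorm(n, s$abnormal_mean, s$abnormal_sd),
                rnorm(n, s$normal_mean, s$normal_sd))
    if (covariate_effects) {
      x <- x + s$age_coef * (demo$age - 73) + s$edu_coef * (demo$education - 14.6)
    }
    out[, i] <- clip_bounds(x, s$lower_bound, s$upper_bound)
  }
  out
}

new_sim_truth <- function(true_sequence, true_stage, feature_specs, seed,
                          true_hr_by_subgroup = NULL) {
  structure(
    list(true_sequence = true_sequence,
         true_stage = true_stage,
         true_hr_by_subgroup = true_hr_by_subgroup,
         feature_specs = feature_specs,
         seed = seed),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", length(x$true_sequence), "events,",
      length(x$true_stage), "subjects, seed", x$seed, "\n")
  cat("  sequence:", paste(x$true_sequence, collapse = " > "), "\n")
  invisible(x)
}

#' Generate a synthetic reference (observational) cohort
#'
#' Draws a uniformly random true event sequence, assigns each subject a true
#' stage according to their diagnosis (controls concentrated at low stages,
#' dementia cases at high stages, MCI spread over the full range), and
#' generates feature values from the per-feature normal/abnormal
#' distributions, clipped to instrument bounds. Demographics (age, education,
#' sex, APOE-e4) are drawn independently; optional linear age/education
#' effects are added to the features so that covariate adjustment has work
#' to do. Identical arguments and seed give identical output.
#'
#' @param specs List of [feature_spec()] objects (at least two).
#' @param n_cn,n_ad,n_mci Group sizes; defaults follow a typical reference
#'   cohort of 229 controls, 181 dementia cases and 400 MCI.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param stage_geom_p Decay parameter of the truncated-geometric stage
#'   distributions used for the CN (from stage 0) and AD (from stage K) groups.
#' @param covariate_effects If `TRUE`, add each spec's linear age/education
#'   effect to the generated values.
#' @param apoe4_rate Carrier probability.
#' @param true_sequence Optional fixed event sequence (permutation of the
#'   feature names); when `NULL` a uniformly random sequence is drawn. Fixing
#'   it allows generating held-out subjects under the same ground truth.
#' @return A list with `cohort` (tibble: subject_id, diagnosis, age,
#'   education, sex, apoe4, one column per feature) and `truth`
#'   (a `sim_truth` with the sequence and per-subject stages).
#' @export
generate_reference_cohort <- function(specs, n_cn = 229, n_ad = 181,
                                      n_mci = 400, seed = 1,
                                      stage_geom_p = 0.5,
                                      covariate_effects = TRUE,
                                      apoe4_rate = 0.47,
                                      true_sequence = NULL) {
  specs <- as_spec_list(specs)
  k <- length(specs)
  if (k < 2) stop("invalid model: need at least 2 features (events)")
  stopifnot(n_cn >= 0, n_ad >= 0, n_mci >= 0)
  if (!is.null(true_sequence) &&
      !setequal(true_sequence, spec_names(specs))) {
    stop("true_sequence must be a permutation of the feature names")
  }
  run_with_seed(seed, {
    sequence <- true_sequence %||% sample(spec_names(specs))
    stage <- c(
      rtrunc_geom(n_cn, stage_geom_p, k, "low"),
      rtrunc_geom(n_ad, stage_geom_p, k, "high"),
      sample(0:k, n_mci, replace = TRUE)
    )
    diagnosis <- rep(c("CN", "AD", "MCI"), c(n_cn, n_ad, n_mci))
    n <- length(stage)
    demo <- draw_demographics(n, apoe4_rate)
    feats <- draw_feature_matrix(specs, sequence, stage, demo,
                                 covariate_effects)
    cohort <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("REF_%04d", seq_len(n)),
                     diagnosis = diagnosis),
      demo,
      tibble::as_tibble(feats)
    )
    truth <- new_sim_truth(sequence,
                           setNames(stage, cohort$subject_id),
                           specs, seed)
    list(cohort = cohort, truth = truth)
  })
}

#' Describe a randomized trial design
#'
#' @param n_per_arm Named counts per arm; defaults follow a three-arm
#'   MCI trial (259 placebo, 257 vitamin E, 253 donepezil).
#' @param visit_interval Months between visits; must divide `trial_length`.
#' @param trial_length Trial duration in months.
#' @param dropout_rate_per_visit Probability of dropping out at each
#'   follow-up visit (censoring at the last attended visit, never before the
#'   first follow-up).
#' @param baseline_hazard Conversion hazard (events/month) at stage 0.
#' @param stage_log_hazard_slope Increase in log-hazard per model stage. The
#'   defaults give roughly 45% three-year conversion for untreated late-stage
#'   subjects and about 13% at stage 0.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_per_arm = c(placebo = 259, vitaminE = 257,
                                       donepezil = 253),
                         visit_interval = 6, trial_length = 36,
                         dropout_rate_per_visit = 0.05,
                         baseline_hazard = 0.004,
                         stage_log_hazard_slope = 0.15) {
  if (is.null(names(n_per_arm)) || any(!nzchar(names(n_per_arm)))) {
    stop("n_per_arm must be a named vector of arm sizes")
  }
  if (any(n_per_arm <= 0)) stop("all arm counts must be positive")
  if (trial_length %% visit_interval != 0) {
    stop("visit_interval must divide trial_length")
  }
  if (dropout_rate_per_visit < 0 || dropout_rate_per_visit >= 1) {
    stop("dropout_rate_per_visit must be in [0, 1)")
  }
  if (baseline_hazard < 0) stop("baseline_hazard must be non-negative")
  structure(
    list(n_per_arm = n_per_arm, visit_interval = visit_interval,
         trial_length = trial_length,
         dropout_rate_per_visit = dropout_rate_per_visit,
         baseline_hazard = baseline_hazard,
         stage_log_hazard_slope = stage_log_hazard_slope),
    class = "trial_design"
  )
}

#' Default treatment-effect configuration
#'
#' Hazard ratios by arm and stage subgroup. The default encodes a
#' late-stage-only donepezil effect (HR 0.55) with no effect elsewhere,
#' the configuration whose wash-out under pooled analysis the screening
#' pipeline is designed to detect.
#'
#' @param late_hr Hazard ratio for donepezil in the Late-stage subgroup.
#' @return A tibble with columns arm, subgroup, hr.
#' @export
default_hr_config <- function(late_hr = 0.55) {
  tibble::tibble(
    arm = c("donepezil", "donepezil", "vitaminE", "vitaminE"),
    subgroup = c("Late-stage", "Others", "Late-stage", "Others"),
    hr = c(late_hr, 1, 1, 1)
  )
}

hr_lookup <- function(hr_config, arm, subgroup) {
  out <- rep(1, length(arm))  # placebo / unlisted combinations
  for (r in seq_len(nrow(hr_config))) {
    hit <- arm == hr_config$arm[r] & subgroup == hr_config$subgroup[r]
    out[hit] <- hr_config$hr[r]
  }
  out
}

#' Generate a synthetic randomized trial cohort
#'
#' Baseline stages are drawn from a bimodal mixture (an early/middle
#' component and a late minority, default weight 0.16); baseline features
#' come from the same event-sequence generative model as the reference
#' cohort. Conversion times are exponential with log-hazard
#' `log(baseline_hazard) + slope * stage + log(HR[arm, subgroup])`, censored
#' administratively at the trial end and by per-visit dropout. A
#' 13-item cognitive battery score (0-85, higher = worse) is recorded at
#' every attended visit: baseline increasing with stage, linear per-month
#' decline steepening with stage, attenuated in treated subgroups, plus
#' Gaussian noise.
#'
#' @param specs List of [feature_spec()]s.
#' @param true_sequence Event sequence (permutation of spec names) the
#'   baseline features are generated under; typically from the reference
#'   cohort's ground truth.
#' @param design A [trial_design()].
#' @param hr_config Tibble (arm, subgroup, hr) as from [default_hr_config()].
#' @param seed Integer seed.
#' @param late_threshold Stages strictly above this are "Late-stage".
#' @param late_weight Mixture weight of the late-stage component.
#' @param cog_effect_multiplier Multiplier on the cognitive decline slope for
#'   (arm, subgroup) combinations; tibble (arm, subgroup, mult). Default
#'   halves the slope for donepezil in the Late-stage subgroup.
#' @return A list with `cohort` (baseline row per subject plus arm,
#'   time_months, converted, and adas13_m0..m36 visit columns) and `truth`.
#' @export
generate_trial_cohort <- function(specs, true_sequence, design = trial_design(),
                                  hr_config = default_hr_config(), seed = 1,
                                  late_threshold = 8, late_weight = 0.16,
                                  cog_effect_multiplier = NULL) {
  specs <- as_spec_list(specs)
  k <- length(specs)
  if (k < 2) stop("invalid model: need at least 2 features (events)")
  if (!setequal(true_sequence, spec_names(specs))) {
    stop("true_sequence must be a permutation of the feature names")
  }
  if (any(hr_config$hr <= 0)) stop("all hazard ratios must be positive")
  if (!all(hr_config$arm %in% names(design$n_per_arm))) {
    bad <- setdiff(hr_config$arm, names(design$n_per_arm))
    stop("unknown arm label in hr_config: ", paste(bad, collapse = ", "))
  }
  if (late_threshold < 0 || late_threshold > k) {
    stop("late_threshold must be in [0, K]")
  }
  if (is.null(cog_effect_multiplier)) {
    cog_effect_multiplier <- tibble::tibble(
      arm = "donepezil", subgroup = "Late-stage", hr = 0.5)
  }
  run_with_seed(seed, {
    arms <- rep(names(design$n_per_arm), design$n_per_arm)
    n <- length(arms)
    late <- runif(n) < late_weight
    stage <- ifelse(late,
                    resample(seq(late_threshold + 1, k), n),
                    resample(seq(0, late_threshold), n))
    subgroup_true <- ifelse(stage > late_threshold, "Late-stage", "Others")
    demo <- draw_demographics(n, apoe4_rate = 0.55)
    feats <- draw_feature_matrix(specs, true_sequence, stage, demo, TRUE)

    hr <- hr_lookup(hr_config, arms, subgroup_true)
    lambda <- design$baseline_hazard *
      exp(design$stage_log_hazard_slope * stage) * hr
    conv_time <- ifelse(lambda > 0, rexp(n, pmax(lambda, 1e-300)), Inf)

    n_visits <- design$trial_length / design$visit_interval
    # dropout: geometric over follow-up visits, never before the first one
    attended <- rep(n_visits, n)
    if (design$dropout_rate_per_visit > 0) {
      extra <- rgeom(n, design$dropout_rate_per_visit)  # visits beyond the 1st
      attended <- pmin(1 + extra, n_visits)
    }
    censor_time <- pmin(attended * design$visit_interval, design$trial_length)
    converted <- as.integer(conv_time <= censor_time)
    time_months <- pmin(conv_time, censor_time)

    # cognitive outcome trajectory (higher = worse), clipped to [0, 85]
    mult <- hr_lookup(cog_effect_multiplier, arms, subgroup_true)
    adas0 <- 14 + 0.75 * stage + rnorm(n, 0, 4.5)
    slope <- (0.04 + 0.010 * stage) * mult
    months <- seq(0, design$trial_length, by = design$visit_interval)
    adas <- sapply(months, function(m) {
      v <- clip_bounds(adas0 + slope * m + rnorm(n, 0, 2), 0, 85)
      v[m > censor_time] <- NA_real_   # not observed after dropout
      v
    })
    colnames(adas) <- sprintf("adas13_m%d", months)

    cohort <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("TRIAL_%04d", seq_len(n)),
                     diagnosis = "MCI"),
      demo,
      tibble::as_tibble(feats),
      tibble::tibble(arm = arms, time_months = time_months,
                     converted = converted),
      tibble::as_tibble(adas)
    )
    hr_map <- setNames(hr_config$hr,
                       paste(hr_config$arm, hr_config$subgroup, sep = ":"))
    truth <- new_sim_truth(true_sequence,
                           setNames(stage, cohort$subject_id),
                           specs, seed, true_hr_by_subgroup = hr_map)
    list(cohort = cohort, truth = truth)
  })
}
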