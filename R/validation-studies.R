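# Simulation studies that quantify how well the pipeline recovers known
# ground truth: the event sequence, per-subject stages, and subgroup
# treatment effects. These are the package's own validation experiments,
# runnable at configurable size.

# minimal full-data fit (mixtures + greedy ML sequence) used by the studies
quick_ebm_fit <- function(cohort, specs, seed, n_startpoints = 10,
                          include_unlabeled = TRUE, adjustment = NULL) {
  models <- fit_cohort_mixtures(cohort, specs,
                                include_unlabeled = include_unlabeled)
  lik <- build_likelihood_matrix(cohort, models)
  ml <- greedy_ascent(lik, n_startpoints = n_startpoints, seed = seed)
  structure(
    list(models = models, ml_sequence = ml$sequence,
         ml_log_lik = ml$log_lik, positional_density = NULL,
         specs = specs, adjustment = adjustment,
         meta = list(folds = 0, repeats = 0, seed = seed,
                     n_startpoints = n_startpoints, n_iter = 0, n_sets = 0,
                     include_unlabeled = include_unlabeled)),
    class = "ebm_fit"
  )
}

#' Sequence-recovery study
#'
#' For each seed, simulates a reference cohort under a random true sequence,
#' fits the mixtures on the full data, finds the maximum-likelihood sequence
#' by greedy ascent, and records the normalized Kendall tau distance to the
#' truth.
#'
#' @param n_seeds Number of independent simulated cohorts.
#' @param k Number of events.
#' @param separation Normal/abnormal class separation in SD units.
#' @param n_cn,n_ad,n_mci Cohort composition.
#' @param seed Base seed; cohort i uses `seed + i`.
#' @param n_startpoints Greedy restarts.
#' @return Tibble: seed, kendall_tau, recovered (tau <= `tau_ok`).
#' @param tau_ok Recovery threshold on the normalized Kendall tau distance.
#' @export
evaluate_sequence_recovery <- function(n_seeds = 10, k = 10, separation = 2,
                                       n_cn = 229, n_ad = 181, n_mci = 400,
                                       seed = 1, n_startpoints = 10,
                                       tau_ok = 0.1) {
  specs <- simulation_battery(k, separation)
  rows <- lapply(seq_len(n_seeds), function(i) {
    sim <- generate_reference_cohort(specs, n_cn, n_ad, n_mci,
                                     seed = seed + i)
    fit <- quick_ebm_fit(sim$cohort, specs, seed = seed + i,
                         n_startpoints = n_startpoints)
    tau <- kendall_tau_distance(fit$ml_sequence, sim$truth$true_sequence)
    tibble::tibble(seed = seed + i, kendall_tau = tau,
                   recovered = tau <= tau_ok)
  })
  dplyr::bind_rows(rows)
}

#' Staging-accuracy study
#'
#' Fits the model on one simulated reference cohort, then stages held-out
#' subjects drawn from the same population (same diagnosis mix and
#' stage-given-diagnosis distributions, same ground-truth sequence) and
#' compares assigned to true stages.
#'
#' @param n_holdout Held-out subjects.
#' @param k,separation,seed As in [evaluate_sequence_recovery()].
#' @param n_cn,n_ad,n_mci Training cohort composition; the holdout keeps
#'   these proportions.
#' @return List: `per_subject` tibble (true_stage, stage) and `summary`
#'   one-row tibble (exact_accuracy, within_one_accuracy, n).
#' @export
evaluate_staging_accuracy <- function(n_holdout = 500, k = 10,
                                      separation = 3, n_cn = 229,
                                      n_ad = 181, n_mci = 400, seed = 1) {
  specs <- simulation_battery(k, separation)
  train <- generate_reference_cohort(specs, n_cn, n_ad, n_mci, seed = seed)
  fit <- quick_ebm_fit(train$cohort, specs, seed = seed)
  n_total <- n_cn + n_ad + n_mci
  h_cn <- round(n_holdout * n_cn / n_total)
  h_ad <- round(n_holdout * n_ad / n_total)
  holdout <- generate_reference_cohort(
    specs, n_cn = h_cn, n_ad = h_ad, n_mci = n_holdout - h_cn - h_ad,
    seed = seed + 10000L, true_sequence = train$truth$true_sequence)
  staged <- stage_cohort(holdout$cohort, fit, adjust = FALSE)
  per_subject <- tibble::tibble(
    true_stage = unname(holdout$truth$true_stage[staged$subject_id]),
    stage = staged$stage
  )
  summary <- tibble::tibble(
    exact_accuracy = mean(per_subject$stage == per_subject$true_stage),
    within_one_accuracy = mean(abs(per_subject$stage -
                                     per_subject$true_stage) <= 1),
    n = n_holdout
  )
  list(per_subject = per_subject, summary = summary)
}

#' Screening-power study: wash-out of a subgroup treatment effect
#'
#' The full screening pipeline under a configured late-stage-only treatment
#' effect: a reference model is trained once on a simulated cohort, then for
#' each replicate a fresh trial is simulated (true donepezil hazard ratio
#' `late_hr` in the late-stage subgroup, 1 elsewhere), staged at baseline
#' with the reference model, stratified, and analyzed with Cox models per
#' stratum. Records the estimated hazard ratios in the All / Others /
#' Late-stage strata, whether they order as Late < All < Others (the wash-out
#' signature), and whether the late-stage Wald CI covers the truth.
#'
#' @param n_replicates Number of simulated trials.
#' @param late_hr True donepezil hazard ratio in the late-stage subgroup.
#' @param seed Base seed.
#' @param design Trial design (defaults to [trial_design()]).
#' @param threshold Stage threshold for stratification.
#' @param use_true_stages Stratify on the generator's true stages instead of
#'   model stages (isolates the survival analysis from staging error).
#' @return List: `per_replicate` tibble and `summary` one-row tibble
#'   (ordering_fraction, coverage, median HRs).
#' @export
evaluate_screening_power <- function(n_replicates = 100, late_hr = 0.55,
                                     seed = 1, design = trial_design(),
                                     threshold = 8,
                                     use_true_stages = FALSE) {
  specs <- ad_cognitive_battery()
  ref <- generate_reference_cohort(specs, seed = seed)
  adjustment <- fit_covariate_adjustment(ref$cohort, spec_names(specs))
  adjusted <- apply_covariate_adjustment(adjustment, ref$cohort)
  fit <- quick_ebm_fit(adjusted, specs, seed = seed, adjustment = adjustment)
  hr_config <- default_hr_config(late_hr)

  rows <- lapply(seq_len(n_replicates), function(i) {
    trial <- generate_trial_cohort(specs, ref$truth$true_sequence,
                                   design = design, hr_config = hr_config,
                                   seed = seed + 1000L + i,
                                   late_threshold = threshold)
    if (use_true_stages) {
      stages <- tibble::tibble(
        subject_id = trial$cohort$subject_id,
        stage = unname(trial$truth$true_stage[trial$cohort$subject_id]))
    } else {
      stages <- stage_cohort(trial$cohort, fit)
    }
    labeling <- stratify_by_stage(stages, threshold = threshold)
    primary <- primary_outcome_analysis(trial$cohort, labeling,
                                        arms = "donepezil")
    cx <- primary$cox
    hr_of <- function(st) cx$hr[cx$stratum == st]
    lo <- cx$ci_low[cx$stratum == "Late-stage"]
    hi <- cx$ci_high[cx$stratum == "Late-stage"]
    tibble::tibble(
      replicate = i,
      hr_all = hr_of("All"), hr_others = hr_of("Others"),
      hr_late = hr_of("Late-stage"),
      washout_order = !anyNA(c(hr_of("Late-stage"), hr_of("All"),
                               hr_of("Others"))) &&
        hr_of("Late-stage") < hr_of("All") && hr_of("All") < hr_of("Others"),
      late_ci_covers = !is.na(lo) && lo <= late_hr && late_hr <= hi,
      staging_agreement = if (use_true_stages) 1 else {
        truth_label <- ifelse(trial$truth$true_stage[stages$subject_id] >
                                threshold, "Late-stage", "Others")
        mean(truth_label == labeling$subgroup)
      }
    )
  })
  per_replicate <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    ordering_fraction = mean(per_replicate$washout_order),
    coverage = mean(per_replicate$late_ci_covers),
    median_hr_all = median(per_replicate$hr_all, na.rm = TRUE),
    median_hr_others = median(per_replicate$hr_others, na.rm = TRUE),
    median_hr_late = median(per_replicate$hr_late, na.rm = TRUE),
    mean_staging_agreement = mean(per_replicate$staging_agreement),
    n_replicates = n_replicates
  )
  list(per_replicate = per_replicate, summary = summary)
}
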