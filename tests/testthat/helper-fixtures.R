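# Shared fixture: a synthetic trial with ground-truth subgroup labels.
make_labeled_trial <- function(seed, late_hr = 0.55, n_scale = 1,
                               cog_mult = NULL) {
  specs <- simulation_battery(10, 3)
  seqn <- vapply(specs, `[[`, character(1), "name")
  design <- trial_design(n_per_arm = round(
    c(placebo = 259, vitaminE = 257, donepezil = 253) * n_scale))
  trial <- generate_trial_cohort(specs, seqn, design = design,
                                 hr_config = default_hr_config(late_hr),
                                 seed = seed,
                                 cog_effect_multiplier = cog_mult)
  lab <- stratify_by_stage(
    tibble::tibble(subject_id = trial$cohort$subject_id,
                   stage = unname(trial$truth$true_stage)), 8)
  list(trial = trial$cohort, lab = lab)
}
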