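# Synthetic cohort generators: composition, determinism, bounds, and
# consistency of the configured ground truth.

test_that("reference cohort has the documented composition and schema", {
  sim <- generate_reference_cohort(ad_cognitive_battery(), seed = 7)
  expect_equal(nrow(sim$cohort), 810)
  expect_equal(as.integer(table(sim$cohort$diagnosis)[c("CN", "AD", "MCI")]),
               c(229, 181, 400))
  expect_true(all(c("subject_id", "diagnosis", "age", "education", "sex",
                    "apoe4", "mmse", "dsst") %in% names(sim$cohort)))
  expect_setequal(sim$truth$true_sequence,
                  vapply(ad_cognitive_battery(), `[[`, character(1), "name"))
  expect_true(all(sim$truth$true_stage >= 0 & sim$truth$true_stage <= 10))
})

test_that("generation is deterministic in the seed and respects bounds", {
  specs <- ad_cognitive_battery()
  a <- generate_reference_cohort(specs, 50, 50, 50, seed = 11)
  b <- generate_reference_cohort(specs, 50, 50, 50, seed = 11)
  c <- generate_reference_cohort(specs, 50, 50, 50, seed = 12)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$true_sequence, b$truth$true_sequence)
  expect_false(identical(a$cohort, c$cohort))
  for (s in specs) {
    x <- a$cohort[[s$name]]
    if (!is.na(s$lower_bound)) expect_true(all(x >= s$lower_bound))
    if (!is.na(s$upper_bound)) expect_true(all(x <= s$upper_bound))
  }
})

test_that("diagnosis groups land where the stage model says they should", {
  sim <- generate_reference_cohort(simulation_battery(8, 2), seed = 3)
  st <- sim$truth$true_stage
  dx <- sim$cohort$diagnosis
  expect_lt(mean(st[dx == "CN"]), mean(st[dx == "MCI"]))
  expect_lt(mean(st[dx == "MCI"]), mean(st[dx == "AD"]))
})

test_that("with no class separation CN and AD histograms are indistinguishable", {
  specs <- list(
    feature_spec("flat_a", disease_direction = +1, normal_mean = 0,
                 normal_sd = 1, abnormal_mean = 1e-9, abnormal_sd = 1),
    feature_spec("flat_b", disease_direction = +1, normal_mean = 0,
                 normal_sd = 1, abnormal_mean = 1e-9, abnormal_sd = 1)
  )
  sim <- generate_reference_cohort(specs, n_cn = 200, n_ad = 200, n_mci = 0,
                                   seed = 5)
  ks <- ks.test(sim$cohort$flat_a[sim$cohort$diagnosis == "CN"],
                sim$cohort$flat_a[sim$cohort$diagnosis == "AD"])
  expect_gt(ks$p.value, 0.01)
})

test_that("a subject's stage fixes which features are abnormal", {
  specs <- simulation_battery(4, 4)
  sequence <- vapply(specs, `[[`, character(1), "name")
  demo <- tibble::tibble(age = rep(73, 400), education = rep(14.6, 400))
  set.seed(21)
  feats <- stagescreen:::draw_feature_matrix(specs, sequence,
                                             stage = rep(2L, 400), demo)
  midpoints <- vapply(specs, function(s) {
    (s$normal_mean + s$abnormal_mean) / 2
  }, numeric(1))
  dirs <- vapply(specs, `[[`, integer(1), "disease_direction")
  abnormal_side <- sweep(sweep(feats, 2, midpoints), 2, dirs, `*`) > 0
  expect_gt(mean(abnormal_side[, 1] & abnormal_side[, 2]), 0.95)
  # features past the stage stay normal: crossing the 2-SD midpoint is rare
  expect_lt(mean(abnormal_side[, 3]), 0.08)
  expect_lt(mean(abnormal_side[, 4]), 0.08)
})

test_that("trial cohort reproduces the configured arm sizes", {
  specs <- ad_cognitive_battery()
  ref <- generate_reference_cohort(specs, 30, 30, 0, seed = 1)
  trial <- generate_trial_cohort(specs, ref$truth$true_sequence, seed = 2)
  expect_equal(nrow(trial$cohort), 769)
  counts <- table(trial$cohort$arm)
  expect_equal(as.integer(counts[c("placebo", "vitaminE", "donepezil")]),
               c(259, 257, 253))
})

test_that("no hazard and no dropout means everyone is censored at trial end", {
  specs <- simulation_battery(10, 2)
  seqn <- vapply(specs, `[[`, character(1), "name")
  design <- trial_design(n_per_arm = c(placebo = 40, donepezil = 40),
                         dropout_rate_per_visit = 0, baseline_hazard = 0)
  hr1 <- default_hr_config(late_hr = 1)
  hr1 <- hr1[hr1$arm == "donepezil", ]
  trial <- generate_trial_cohort(specs, seqn, design = design,
                                 hr_config = hr1, seed = 4)
  expect_true(all(trial$cohort$converted == 0))
  expect_true(all(trial$cohort$time_months == 36))
})

test_that("event and censoring times obey the trial design", {
  specs <- simulation_battery(10, 2)
  seqn <- vapply(specs, `[[`, character(1), "name")
  trial <- generate_trial_cohort(specs, seqn, seed = 8)
  tc <- trial$cohort
  expect_true(all(tc$time_months > 0 & tc$time_months <= 36))
  # censored subjects stop at a visit month (dropout or administrative)
  censored <- tc$time_months[tc$converted == 0]
  expect_true(all(censored %% 6 == 0))
  # cognitive scores live in [0, 85] and vanish after dropout
  adas <- as.matrix(tc[, sprintf("adas13_m%d", seq(0, 36, 6))])
  expect_true(all(adas >= 0 & adas <= 85, na.rm = TRUE))
  last_obs <- apply(adas, 1, function(r) max(which(!is.na(r))))
  expect_true(all(last_obs >= 2))  # everyone attends the first follow-up
})

test_that("late-stage mixture weight is reproduced at trial scale", {
  specs <- simulation_battery(10, 2)
  seqn <- vapply(specs, `[[`, character(1), "name")
  trial <- generate_trial_cohort(specs, seqn, seed = 31, late_weight = 0.16)
  frac <- mean(trial$truth$true_stage > 8)
  se <- sqrt(0.16 * 0.84 / length(trial$truth$true_stage))
  expect_lt(abs(frac - 0.16), 3 * se)
})

test_that("Cox on the true late subgroup recovers the configured hazard ratio", {
  specs <- ad_cognitive_battery()
  seqn <- vapply(specs, `[[`, character(1), "name")
  design <- trial_design(n_per_arm = c(placebo = 259, donepezil = 253) * 20)
  hr <- default_hr_config(0.55)
  trial <- generate_trial_cohort(specs, seqn, design = design,
                                 hr_config = hr[hr$arm == "donepezil", ],
                                 seed = 17)
  late_ids <- names(trial$truth$true_stage)[trial$truth$true_stage > 8]
  fit <- cox_fit(trial$cohort, "donepezil", covariates = character(0),
                 subgroup = late_ids)
  expect_lt(abs(log(fit$hr) - log(0.55)), 0.1)
  # untreated late placebo conversion sits near the design's working point
  late_placebo <- trial$cohort$subject_id %in% late_ids &
    trial$cohort$arm == "placebo"
  expect_gt(mean(trial$cohort$converted[late_placebo]), 0.3)
})

test_that("generator rejects invalid configurations", {
  specs <- simulation_battery(4, 2)
  seqn <- vapply(specs, `[[`, character(1), "name")
  expect_error(generate_reference_cohort(specs[1], seed = 1),
               "at least 2 features")
  expect_error(
    generate_trial_cohort(specs, seqn, seed = 1,
                          hr_config = tibble::tibble(
                            arm = "donepezil", subgroup = "Others", hr = 0)),
    "positive")
  expect_error(
    generate_trial_cohort(specs, seqn, seed = 1,
                          hr_config = tibble::tibble(
                            arm = "nosucharm", subgroup = "Others", hr = 1)),
    "unknown arm")
  expect_error(trial_design(visit_interval = 7), "divide")
  expect_error(trial_design(dropout_rate_per_visit = 1), "dropout")
  expect_error(feature_spec("x", disease_direction = 1, normal_mean = 0,
                            normal_sd = -1, abnormal_mean = 1,
                            abnormal_sd = 1),
               "positive")
  expect_error(feature_spec("x", disease_direction = -1, normal_mean = 0,
                            normal_sd = 1, abnormal_mean = 1,
                            abnormal_sd = 1),
               "disease_direction side")
})
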