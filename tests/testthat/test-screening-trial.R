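# Stratification and the primary/secondary outcome statistics.

test_that("stratification applies the strictly-greater rule", {
  stages <- tibble::tibble(subject_id = c("a", "b", "c"),
                           stage = c(9L, 8L, 0L))
  lab <- stratify_by_stage(stages, threshold = 8)
  expect_equal(lab$subgroup, c("Late-stage", "Others", "Others"))
  all_zero <- stratify_by_stage(
    tibble::tibble(subject_id = letters[1:4], stage = 0L), 8)
  expect_true(all(all_zero$subgroup == "Others"))
  expect_equal(unname(attr(all_zero, "counts")["Late-stage"]), 0L)
})

test_that("the automatic threshold finds the valley between modes", {
  stages <- rep(c(2L, 3L, 4L, 9L, 10L), c(30, 40, 30, 3, 12))
  thr <- suggest_stage_threshold(stages, k = 10)
  expect_true(thr >= 5 && thr <= 8)
  # unimodal: nothing to split off
  expect_equal(suggest_stage_threshold(rep(c(1L, 2L), c(30, 20)), k = 10), 10)
})

test_that("KM matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_equal(km$survival[km$time == 1], 0.75)
  expect_equal(km$survival[km$time == 2], 0.50)
  expect_equal(km$survival[km$time == 4], 0.0)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$ci_low <= km$survival & km$survival <= km$ci_high,
                  na.rm = TRUE))
  # all censored: flat at one
  flat <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(flat$survival == 1))
  # duplicating every subject leaves the estimate unchanged
  km2 <- km_estimate(rep(c(1, 2, 3, 4), 2), rep(c(1, 1, 0, 1), 2))
  expect_equal(km2$survival, km$survival)
  expect_error(km_estimate(numeric(0), numeric(0)), "no subjects")
})

test_that("Cox is calibrated under the null", {
  set.seed(101)
  n <- 2000
  trial <- tibble::tibble(
    subject_id = as.character(1:n),
    arm = sample(c("placebo", "donepezil"), n, replace = TRUE),
    time_months = pmin(rexp(n, 0.03), 36),
    converted = as.integer(rexp(n, 0.03) <= 36),
    age = rnorm(n, 73, 7)
  )
  trial$converted <- as.integer(trial$time_months < 36)
  fit <- cox_fit(trial, "donepezil", covariates = "age")
  se <- (log(fit$ci_high) - log(fit$hr)) / qnorm(0.975)
  expect_lt(abs(log(fit$hr)), 3 * se)
})

test_that("Cox recovers a known exponential hazard ratio", {
  set.seed(103)
  n <- 5000
  group <- rep(c("placebo", "treated"), each = n / 2)
  rate <- ifelse(group == "placebo", 1, 2)
  time <- rexp(n, rate)
  trial <- tibble::tibble(subject_id = as.character(1:n), arm = group,
                          time_months = time, converted = 1L)
  fit <- cox_fit(trial, "treated", covariates = character(0))
  expect_lt(abs(fit$hr - 2), 0.1)
})

test_that("Cox coefficient matches brute-force partial likelihood", {
  trial <- tibble::tibble(
    subject_id = as.character(1:6),
    arm = c("placebo", "treated", "placebo", "treated", "placebo", "treated"),
    time_months = c(3, 5, 7, 11, 13, 17),
    converted = c(1L, 1L, 1L, 0L, 1L, 1L)
  )
  fit <- cox_fit(trial, "treated", covariates = character(0))
  x <- as.integer(trial$arm == "treated")
  brute <- optimize(function(b) cox_partial_ll(b, trial$time_months,
                                               trial$converted, x),
                    c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(log(fit$hr), brute$maximum, tolerance = 1e-6)
  expect_error(cox_fit(trial[trial$converted == 0, ], "treated",
                       covariates = character(0)), "zero events")
  trial$const <- 1
  expect_error(cox_fit(trial, "treated", covariates = "const"),
               "constant covariate")
})

test_that("analysis results do not depend on row order", {
  specs <- simulation_battery(10, 2)
  seqn <- vapply(specs, `[[`, character(1), "name")
  trial <- generate_trial_cohort(specs, seqn, seed = 41)$cohort
  lab <- stratify_by_stage(tibble::tibble(subject_id = trial$subject_id,
                                          stage = sample(0:10, nrow(trial),
                                                         replace = TRUE)))
  set.seed(1)
  shuffled <- trial[sample(nrow(trial)), ]
  a <- cox_fit(trial, "donepezil", covariates = c("age", "apoe4"))
  b <- cox_fit(shuffled, "donepezil", covariates = c("age", "apoe4"))
  expect_equal(a$hr, b$hr, tolerance = 1e-10)
  km_a <- km_estimate(trial$time_months, trial$converted)
  km_b <- km_estimate(shuffled$time_months, shuffled$converted)
  expect_equal(km_a, km_b)
})

test_that("Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  expect_equal(hochberg_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(hochberg_adjust(rep(0.2, 5)), rep(0.2, 5))
  # general properties on random input
  set.seed(107)
  p <- runif(20)
  adj <- hochberg_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(adj, p.adjust(p, "hochberg"))
  # NA entries stay NA but count toward the family
  p_na <- c(0.01, NA, 0.04)
  adj_na <- hochberg_adjust(p_na)
  expect_true(is.na(adj_na[2]))
  expect_equal(adj_na[c(1, 3)],
               p.adjust(c(0.01, 0.04), "hochberg", n = 3))
})

test_that("Mann-Whitney U matches exact enumeration on tiny samples", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # swapping the samples reflects U and keeps p
  mw2 <- mann_whitney_u(c(3, 4), c(1, 2))
  expect_equal(mw2$u, 4 - mw$u)
  expect_equal(mw2$p, mw$p)
  # identical samples: midrank U = n^2/2 and no evidence
  mw3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw3$u, 4.5)
  expect_gte(mw3$p, 0.95)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("Mann-Whitney p-values are uniform under the null", {
  set.seed(109)
  p <- replicate(200, mann_whitney_u(rnorm(30), rnorm(30))$p)
  # exact p-values are discrete, so ties are expected
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("primary analysis reports one Hochberg family over arms x strata", {
  d <- make_labeled_trial(seed = 51)
  po <- primary_outcome_analysis(d$trial, d$lab,
                                 covariates = c("age", "apoe4"))
  expect_equal(nrow(po$cox), 6)  # 2 arms x 3 strata
  expect_true(all(po$cox$p_adj >= po$cox$p_raw, na.rm = TRUE))
  expect_setequal(unique(po$cox$stratum), c("All", "Others", "Late-stage"))
  expect_true(all(c("time", "at_risk", "survival", "ci_low", "ci_high")
                  %in% names(po$km)))
  # KM curves exist for placebo and both arms in every stratum
  expect_equal(nrow(dplyr::distinct(po$km, .data$stratum, .data$arm)), 9)
})

test_that("an empty stratum is reported as non-estimable, family unchanged", {
  d <- make_labeled_trial(seed = 53)
  d$lab$subgroup[] <- "Others"  # nobody late
  po <- primary_outcome_analysis(d$trial, d$lab,
                                 covariates = c("age", "apoe4"))
  expect_equal(nrow(po$cox), 6)
  late <- po$cox[po$cox$stratum == "Late-stage", ]
  expect_true(all(is.na(late$hr)))
  expect_true(all(is.na(late$p_adj)))
})

test_that("familywise error is controlled when no effect exists", {
  set.seed(113)
  hits <- vapply(1:150, function(i) {
    d <- make_labeled_trial(seed = 7000 + i, late_hr = 1, n_scale = 0.35)
    po <- primary_outcome_analysis(d$trial, d$lab,
                                   covariates = c("age", "apoe4"))
    any(po$cox$p_adj < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("secondary analysis tests each subgroup at each visit", {
  d <- make_labeled_trial(seed = 57)
  so <- secondary_outcome_analysis(d$trial, d$lab)
  expect_equal(nrow(so), 12)  # 2 subgroups x 6 visits
  expect_true(all(so$p_adj >= so$p_raw, na.rm = TRUE))
  expect_true(all(so$visit_month %in% seq(6, 36, 6)))
  # per-visit n shrinks as subjects drop out
  n_by_visit <- tapply(so$n_placebo + so$n_treated, so$visit_month, sum)
  expect_true(all(diff(n_by_visit) <= 0))
})

test_that("a cognition effect in the late subgroup is localized there", {
  mult <- tibble::tibble(arm = "donepezil", subgroup = "Late-stage",
                         hr = 0.25)
  wins <- vapply(1:60, function(i) {
    d <- make_labeled_trial(seed = 9000 + i, cog_mult = mult)
    so <- secondary_outcome_analysis(d$trial, d$lab)
    best <- so$subgroup[which.min(so$p_adj)]
    identical(best, "Late-stage")
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("Cox CIs cover a configured late-stage effect at nominal rate", {
  # inflated n for power; truth stratification isolates the survival engine
  covered <- vapply(1:60, function(i) {
    d <- make_labeled_trial(seed = 11000 + i, late_hr = 0.55, n_scale = 2)
    late_ids <- d$lab$subject_id[d$lab$subgroup == "Late-stage"]
    fit <- cox_fit(d$trial, "donepezil", covariates = c("age", "apoe4"),
                   subgroup = late_ids)
    fit$ci_low <= 0.55 && 0.55 <= fit$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})
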