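# Sequence likelihood, optimizers, positional density, and staging.

test_that("likelihood matrix reproduces hand-evaluated Gaussian densities", {
  models <- list(
    f1 = toy_kernel_model(0, 10, bw = 1, feature = "f1"),
    f2 = toy_kernel_model(5, -5, bw = 2, direction = -1, feature = "f2")
  )
  cohort <- tibble::tibble(subject_id = c("a", "b", "c"),
                           f1 = c(1, 8, 5), f2 = c(4, -4, 0))
  lik <- build_likelihood_matrix(cohort, models)
  expect_equal(lik$p_event[, "f1"], dnorm(cohort$f1, 10, 1),
               tolerance = 1e-12)
  expect_equal(lik$p_noevent[, "f1"], dnorm(cohort$f1, 0, 1),
               tolerance = 1e-12)
  expect_equal(lik$p_event[, "f2"], dnorm(cohort$f2, -5, 2),
               tolerance = 1e-12)
  # a value at one class's kernel center scores higher under that class
  expect_gt(lik$p_event[2, "f1"], lik$p_noevent[2, "f1"])
  expect_gt(lik$p_noevent[1, "f1"], lik$p_event[1, "f1"])
})

test_that("missing values are masked and retained", {
  models <- list(f1 = toy_kernel_model(0, 10, 1, feature = "f1"),
                 f2 = toy_kernel_model(0, 10, 1, feature = "f2"))
  cohort <- tibble::tibble(subject_id = c("a", "b"),
                           f1 = c(NA, 2), f2 = c(NA, NA))
  lik <- build_likelihood_matrix(cohort, models)
  expect_equal(unname(lik$mask), matrix(c(TRUE, FALSE, TRUE, TRUE), 2))
  expect_equal(nrow(lik$p_event), 2)
  expect_error(build_likelihood_matrix(cohort, list(f3 = models$f1)),
               "lacks feature")
})

test_that("flat likelihoods make every ordering equally likely", {
  lik <- manual_likelihood(matrix(0.5, 1, 2), matrix(0.5, 1, 2))
  expect_equal(sequence_log_likelihood(lik, 1:2), log(0.25))
  expect_equal(sequence_log_likelihood(lik, 2:1), log(0.25))
  # fully abnormal subject: only the top stage survives
  k <- 4
  lik2 <- manual_likelihood(matrix(1, 1, k), matrix(0, 1, k))
  for (ord in list(1:4, c(3, 1, 4, 2))) {
    expect_equal(sequence_log_likelihood(lik2, ord), log(1 / (k + 1)))
  }
})

test_that("every ordering of the K=3 toy matches brute-force enumeration", {
  pe <- matrix(c(0.9, 0.8, 0.1), 1)
  pn <- matrix(c(0.1, 0.2, 0.9), 1)
  lik <- manual_likelihood(pe, pn)
  for (ord in all_permutations(3)) {
    expect_equal(sequence_log_likelihood(lik, ord),
                 naive_sequence_ll(pe, pn, ord), tolerance = 1e-12)
  }
})

test_that("likelihood agrees with naive enumeration on random matrices", {
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    n <- 8
    pe <- matrix(runif(n * k), n)
    pn <- matrix(runif(n * k), n)
    mask <- matrix(runif(n * k) < 0.2, n)
    ord <- sample(k)
    lik <- manual_likelihood(pe, pn, mask)
    expect_equal(sequence_log_likelihood(lik, ord),
                 naive_sequence_ll(pe, pn, ord, mask),
                 tolerance = 1e-9)
  }
})

test_that("greedy ascent finds the global optimum on strongly staged data", {
  specs <- simulation_battery(4, 4)
  sim <- generate_reference_cohort(specs, 50, 50, 100, seed = 13)
  models <- fit_cohort_mixtures(sim$cohort, specs)
  lik <- build_likelihood_matrix(sim$cohort, models)
  g <- greedy_ascent(lik, n_startpoints = 4, seed = 1)
  brute <- max(vapply(all_permutations(4), function(p) {
    sequence_log_likelihood(lik, p)
  }, numeric(1)))
  expect_equal(g$log_lik, brute, tolerance = 1e-12)
  # more restarts never hurt
  g1 <- greedy_ascent(lik, n_startpoints = 1, seed = 2)
  g16 <- greedy_ascent(lik, n_startpoints = 16, seed = 2)
  expect_gte(g16$log_lik, g1$log_lik)
  # flat landscape: any endpoint scores like any other permutation
  flat <- manual_likelihood(matrix(0.5, 5, 3), matrix(0.5, 5, 3))
  gf <- greedy_ascent(flat, 2, seed = 3)
  expect_equal(gf$log_lik, sequence_log_likelihood(flat, 1:3))
})

test_that("MCMC accepts everything on a flat landscape and proposes swaps", {
  flat <- manual_likelihood(matrix(0.5, 4, 4), matrix(0.5, 4, 4))
  ps <- mcmc_sample(flat, 1:4, n_iter = 500, seed = 5)
  expect_equal(ps$acceptance_rate, 1.0)
  diffs <- vapply(2:nrow(ps$samples), function(i) {
    sum(ps$samples[i, ] != ps$samples[i - 1, ])
  }, numeric(1))
  expect_true(all(diffs %in% c(0, 2)))   # swap proposals only
  expect_true(all(diffs == 2))           # flat: every proposal accepted
})

test_that("MCMC frequencies match the exact enumeration posterior", {
  pe <- matrix(rep(c(0.9, 0.8, 0.1), each = 6), 6)
  pn <- matrix(rep(c(0.1, 0.2, 0.9), each = 6), 6)
  lik <- manual_likelihood(pe, pn)
  exact <- exact_sequence_posterior(pe, pn)
  ps <- mcmc_sample(lik, 1:3, n_iter = 20000, seed = 6)
  keys <- apply(ps$samples, 1, paste, collapse = "")
  emp <- table(factor(keys, levels = vapply(exact$perms, paste,
                                            character(1), collapse = "")))
  emp <- as.numeric(emp) / length(keys)
  expect_lt(max(abs(emp - exact$prob)), 0.03)
})

test_that("positional density pools sample sets with equal weight", {
  mk <- function(rows, feats = paste0("f", 1:3)) {
    structure(list(samples = rows, log_lik = rep(0, nrow(rows)),
                   acceptance_rate = 1, features = feats, provenance = NULL),
              class = "posterior_samples")
  }
  # all samples identical: a permutation matrix
  a <- mk(matrix(rep(c(2L, 3L, 1L), 10), 10, byrow = TRUE))
  pd_a <- positional_density(a)
  expect_true(all(sort(unclass(pd_a)) %in% c(0, 1)))
  expect_equal(rowSums(unclass(pd_a)), setNames(rep(1, 3), rownames(pd_a)))
  # two sets of different sizes, each on its own single sequence:
  # the pooled matrix is the elementwise mean of two permutation matrices
  b <- mk(matrix(rep(c(1L, 2L, 3L), 50), 50, byrow = TRUE))
  pd <- unclass(positional_density(list(a, b)))
  perm_a <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE,
                   dimnames = list(c("f1", "f2", "f3"), NULL))
  perm_b <- diag(3)
  dimnames(perm_b) <- dimnames(perm_a)
  expected <- (perm_a + perm_b) / 2
  expect_equal(pd[sort(rownames(pd)), ], expected,
               ignore_attr = "dimnames")
  expect_equal(unname(rowSums(pd)), rep(1, 3), tolerance = 1e-12)
  expect_error(positional_density(list(a, mk(b$samples, paste0("g", 1:3)))),
               "different feature sets")
})

test_that("cross-validation recovers the sequence per fold and is reproducible", {
  specs <- simulation_battery(4, 4)
  sim <- generate_reference_cohort(specs, 60, 60, 80, seed = 19)
  fit <- cross_validated_fit(sim$cohort, specs, folds = 2, repeats = 1,
                             seed = 3, n_startpoints = 3, n_iter = 300)
  expect_equal(fit$meta$n_sets, 2)
  expect_identical(fit$ml_sequence, sim$truth$true_sequence)
  # modal sequence of each fold equals the truth under strong signal
  pd <- unclass(fit$positional_density)
  modal <- rownames(pd)[apply(pd, 2, which.max)]
  expect_identical(modal, sim$truth$true_sequence)
  fit2 <- cross_validated_fit(sim$cohort, specs, folds = 2, repeats = 1,
                              seed = 3, n_startpoints = 3, n_iter = 300)
  expect_identical(unclass(fit$positional_density),
                   unclass(fit2$positional_density))
  expect_error(cross_validated_fit(sim$cohort[sim$cohort$diagnosis != "AD", ],
                                   specs, folds = 2, repeats = 1, seed = 1),
               "stratification error")
})

test_that("stage posterior matches the hand-computed stage scan", {
  pe <- matrix(c(0.9, 0.8, 0.1), 1)
  pn <- matrix(c(0.1, 0.2, 0.9), 1)
  lik <- manual_likelihood(pe, pn)
  st <- stage_subjects(lik, 1:3)
  expected <- c(0.018, 0.162, 0.648, 0.072)
  expect_equal(st$stage_posterior[[1]], expected / sum(expected),
               tolerance = 1e-12)
  expect_equal(st$stage, 2L)
  # extremes and ties
  k <- 5
  lik0 <- manual_likelihood(matrix(0.01, 1, k), matrix(1, 1, k))
  expect_equal(stage_subjects(lik0, 1:k)$stage, 0L)
  likK <- manual_likelihood(matrix(1, 1, k), matrix(0.01, 1, k))
  expect_equal(stage_subjects(likK, 1:k)$stage, as.integer(k))
  flat <- manual_likelihood(matrix(0.5, 1, k), matrix(0.5, 1, k))
  expect_equal(stage_subjects(flat, 1:k)$stage, 0L)  # ties go low
})

test_that("all-masked subjects get a flagged uniform posterior", {
  pe <- matrix(0.9, 2, 3); pn <- matrix(0.1, 2, 3)
  mask <- rbind(rep(TRUE, 3), rep(FALSE, 3))
  lik <- manual_likelihood(pe, pn, mask)
  st <- stage_subjects(lik, 1:3)
  expect_true(st$all_masked[1])
  expect_false(st$all_masked[2])
  expect_equal(st$stage_posterior[[1]], rep(0.25, 4))
  expect_equal(st$stage[1], 0L)
})

test_that("AD subjects stage later than CN subjects", {
  specs <- simulation_battery(6, 2)
  sim <- generate_reference_cohort(specs, 200, 200, 0, seed = 23)
  models <- fit_cohort_mixtures(sim$cohort, specs)
  lik <- build_likelihood_matrix(sim$cohort, models)
  ml <- greedy_ascent(lik, 5, seed = 1)
  st <- stage_subjects(lik, ml$sequence)
  cn <- st$stage[sim$cohort$diagnosis == "CN"]
  ad <- st$stage[sim$cohort$diagnosis == "AD"]
  wt <- wilcox.test(ad, cn, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("stage posteriors always sum to one", {
  set.seed(29)
  pe <- matrix(runif(50 * 6), 50)
  pn <- matrix(runif(50 * 6), 50)
  st <- stage_subjects(manual_likelihood(pe, pn), sample(6))
  sums <- vapply(st$stage_posterior, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("kendall tau distance behaves like a distance", {
  expect_equal(kendall_tau_distance(1:5, 1:5), 0)
  expect_equal(kendall_tau_distance(1:5, 5:1), 1)
  expect_equal(kendall_tau_distance(c("a", "b", "c"), c("b", "a", "c")),
               1 / 3)
})

test_that("staging marginalizes features missing from the cohort", {
  specs <- simulation_battery(4, 4)
  sim <- generate_reference_cohort(specs, 50, 50, 50, seed = 31)
  fit <- stagescreen:::quick_ebm_fit(sim$cohort, specs, seed = 1,
                                     n_startpoints = 3)
  reduced <- sim$cohort[, setdiff(names(sim$cohort), "feature_01")]
  expect_warning(st <- stage_cohort(reduced, fit), "feature_01")
  expect_equal(nrow(st), nrow(sim$cohort))
  expect_false(any(st$all_masked))
})
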