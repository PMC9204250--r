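# Event-based model core: sequence likelihood, greedy + MCMC inference over
# event orderings, cross-validated positional density, and per-subject
# maximum-likelihood staging.
#
# The model: K biomarker "events" occur in an unknown order S. A subject at
# stage k has experienced exactly the first k events of S. With a uniform
# prior over stages, the likelihood of subject j's data under S is
#   (1/(K_j+1)) * sum_{k=0..K_j} prod_{i<=k} p_E[j,S(i)] * prod_{i>k} p_N[j,S(i)]
# where p_E / p_N are the abnormal / normal component densities of the
# observed values and masked (missing) features are dropped from the products
# (K_j counts the subject's observed features).

#' Evaluate component densities for every subject and feature
#'
#' @param cohort Data frame with one column per fitted feature.
#' @param models Named list of `kde_event_model`s (one per feature).
#' @return An `ebm_likelihood` object: matrices `p_event`, `p_noevent`
#'   (subjects x features), a logical `mask` (`TRUE` = missing), and the
#'   subject ids.
#' @export
build_likelihood_matrix <- function(cohort, models) {
  feats <- names(models)
  missing_models <- feats[!vapply(models, inherits, logical(1),
                                  "kde_event_model")]
  if (length(missing_models)) {
    stop("not a fitted kde_event_model: ",
         paste(missing_models, collapse = ", "))
  }
  absent <- setdiff(feats, names(cohort))
  if (length(absent)) {
    stop("cohort lacks feature columns: ", paste(absent, collapse = ", "))
  }
  n <- nrow(cohort)
  k <- length(feats)
  p_e <- p_n <- matrix(1, n, k, dimnames = list(NULL, feats))
  mask <- matrix(FALSE, n, k, dimnames = list(NULL, feats))
  for (i in seq_len(k)) {
    x <- cohort[[feats[i]]]
    obs <- !is.na(x)
    mask[!obs, i] <- TRUE
    if (any(obs)) {
      pair <- likelihood_pair(models[[feats[i]]], x[obs])
      p_e[obs, i] <- pair$p_event
      p_n[obs, i] <- pair$p_noevent
    }
  }
  structure(
    list(p_event = p_e, p_noevent = p_n, mask = mask,
         subject_id = cohort[["subject_id"]] %||% as.character(seq_len(n)),
         features = feats),
    class = "ebm_likelihood"
  )
}

#' @export
print.ebm_likelihood <- function(x, ...) {
  cat("<ebm_likelihood>", nrow(x$p_event), "subjects x",
      length(x$features), "features;", sum(x$mask), "masked values\n")
  invisible(x)
}

as_order <- function(lik, sequence) {
  if (is.character(sequence)) {
    ord <- match(sequence, lik$features)
    if (anyNA(ord) || length(ord) != length(lik$features)) {
      stop("sequence must be a permutation of the model's features")
    }
    ord
  } else {
    ord <- as.integer(sequence)
    if (!identical(sort(ord), seq_along(lik$features))) {
      stop("sequence must be a permutation of the model's features")
    }
    ord
  }
}

# stage-sum terms for complete rows: n x (K+1) matrix, column k+1 = term for
# stage k
stage_terms <- function(pe, pn) {
  k <- ncol(pe)
  n <- nrow(pe)
  cum_e <- pe
  for (j in seq_len(k)[-1]) cum_e[, j] <- cum_e[, j - 1] * pe[, j]
  cum_n <- pn
  if (k > 1) for (j in (k - 1):1) cum_n[, j] <- cum_n[, j + 1] * pn[, j]
  terms <- matrix(0, n, k + 1)
  terms[, 1] <- cum_n[, 1]
  terms[, k + 1] <- cum_e[, k]
  if (k > 1) for (j in 1:(k - 1)) terms[, j + 1] <- cum_e[, j] * cum_n[, j + 1]
  terms
}

#' Log-likelihood of the cohort under an event sequence
#'
#' Uniform prior over stages; masked features are dropped from the products
#' and from the per-subject stage count. Subjects with no observed feature
#' contribute zero (their data carry no information about the ordering).
#'
#' @param lik An `ebm_likelihood`.
#' @param sequence Feature names or integer positions (a permutation).
#' @return The scalar log-likelihood.
#' @export
sequence_log_likelihood <- function(lik, sequence) {
  ord <- as_order(lik, sequence)
  pe <- lik$p_event[, ord, drop = FALSE]
  pn <- lik$p_noevent[, ord, drop = FALSE]
  msk <- lik$mask[, ord, drop = FALSE]
  any_masked <- rowSums(msk) > 0
  total <- 0
  if (any(!any_masked)) {
    terms <- stage_terms(pe[!any_masked, , drop = FALSE],
                         pn[!any_masked, , drop = FALSE])
    total <- total + sum(log(rowSums(terms) / (ncol(pe) + 1)))
  }
  for (j in which(any_masked)) {
    keep <- !msk[j, ]
    kj <- sum(keep)
    if (kj == 0) next  # all-masked subject: likelihood 1 under the prior
    terms <- stage_terms(matrix(pe[j, keep], 1), matrix(pn[j, keep], 1))
    total <- total + log(sum(terms) / (kj + 1))
  }
  total
}

all_swaps <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx
}

#' Greedy ascent over event orderings
#'
#' From each of `n_startpoints` random start permutations, repeatedly applies
#' the best-improving pairwise swap until no swap improves, and returns the
#' best endpoint across starts.
#'
#' @param lik An `ebm_likelihood`.
#' @param n_startpoints Number of random restarts.
#' @param seed Integer seed (the search is deterministic given the seed).
#' @return List with `sequence` (feature names), `order` (integer positions)
#'   and `log_lik`.
#' @export
greedy_ascent <- function(lik, n_startpoints = 10, seed = 1) {
  stopifnot(n_startpoints >= 1)
  k <- length(lik$features)
  swaps <- all_swaps(k)
  run_with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_startpoints)) {
      ord <- sample(k)
      cur_ll <- sequence_log_likelihood(lik, ord)
      repeat {
        cand_ll <- apply(swaps, 1L, function(sw) {
          o2 <- ord
          o2[c(sw[1], sw[2])] <- o2[c(sw[2], sw[1])]
          sequence_log_likelihood(lik, o2)
        })
        i <- which.max(cand_ll)
        if (cand_ll[i] <= cur_ll + 1e-12) break
        ord[c(swaps[i, 1], swaps[i, 2])] <- ord[c(swaps[i, 2], swaps[i, 1])]
        cur_ll <- cand_ll[i]
      }
      if (is.null(best) || cur_ll > best$log_lik) {
        best <- list(order = ord, log_lik = cur_ll)
      }
    }
    list(sequence = lik$features[best$order], order = best$order,
         log_lik = best$log_lik)
  })
}

#' Metropolis MCMC over event orderings
#'
#' Proposal: swap two distinct uniformly chosen positions; accept with
#' probability `min(1, exp(delta log-likelihood))`. Every post-burn-in state
#' is recorded (including repeats of the current state after rejection).
#'
#' @param lik An `ebm_likelihood`.
#' @param start Start sequence (feature names or integer positions).
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed.
#' @param burn_in Fraction of iterations discarded (default 0.1).
#' @return A `posterior_samples` object: integer sample matrix
#'   (samples x K, entries are feature indices), log-likelihoods,
#'   acceptance rate, and the feature names.
#' @export
mcmc_sample <- function(lik, start, n_iter = 10000, seed = 1, burn_in = 0.1) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < 1)
  ord <- as_order(lik, start)
  k <- length(ord)
  n_burn <- floor(n_iter * burn_in)
  run_with_seed(seed, {
    cur_ll <- sequence_log_likelihood(lik, ord)
    keep <- matrix(0L, n_iter - n_burn, k)
    lls <- numeric(n_iter - n_burn)
    n_acc <- 0L
    for (it in seq_len(n_iter)) {
      sw <- sample.int(k, 2L)
      prop <- ord
      prop[sw] <- prop[c(sw[2], sw[1])]
      prop_ll <- sequence_log_likelihood(lik, prop)
      if (prop_ll >= cur_ll || runif(1) < exp(prop_ll - cur_ll)) {
        ord <- prop
        cur_ll <- prop_ll
        n_acc <- n_acc + 1L
      }
      if (it > n_burn) {
        keep[it - n_burn, ] <- ord
        lls[it - n_burn] <- cur_ll
      }
    }
    structure(
      list(samples = keep, log_lik = lls,
           acceptance_rate = n_acc / n_iter,
           features = lik$features,
           provenance = NULL),
      class = "posterior_samples"
    )
  })
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples>", nrow(x$samples), "samples over",
      length(x$features), "events; acceptance rate",
      sprintf("%.3f", x$acceptance_rate), "\n")
  invisible(x)
}

# event-by-position frequency matrix of one sample set
set_density <- function(ps) {
  k <- length(ps$features)
  m <- matrix(0, k, k, dimnames = list(ps$features, NULL))
  for (p in seq_len(k)) {
    tab <- tabulate(ps$samples[, p], nbins = k)
    m[, p] <- tab / nrow(ps$samples)
  }
  m
}

#' Positional density of event orderings
#'
#' Pools one or more posterior sample sets with equal per-set weight (each
#' set's empirical event-by-position distribution is averaged, not the raw
#' samples concatenated) into a K x K row-stochastic matrix: entry (i, p) is
#' the pooled posterior probability that event i occupies position p. Rows
#' are ordered by mean position, so a confident ordering shows as a dark
#' diagonal.
#'
#' @param samples A `posterior_samples` object or a list of them.
#' @return A `positional_density` object (matrix with ordered rownames).
#' @export
positional_density <- function(samples) {
  if (inherits(samples, "posterior_samples")) samples <- list(samples)
  stopifnot(length(samples) >= 1,
            all(vapply(samples, inherits, logical(1), "posterior_samples")))
  feats <- samples[[1]]$features
  for (s in samples) {
    if (!identical(s$features, feats)) {
      stop("sample sets were drawn over different feature sets")
    }
  }
  mats <- lapply(samples, set_density)
  pooled <- Reduce(`+`, mats) / length(mats)
  mean_pos <- as.vector(pooled %*% seq_len(ncol(pooled)))
  ord <- order(mean_pos)
  pooled <- pooled[ord, , drop = FALSE]
  colnames(pooled) <- paste0("pos_", seq_len(ncol(pooled)))
  structure(pooled, class = c("positional_density", "matrix"),
            n_sets = length(mats))
}

#' @export
print.positional_density <- function(x, ...) {
  cat("<positional_density>", nrow(x), "events, pooled from",
      attr(x, "n_sets"), "sample set(s)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tidy a positional density into long format
#'
#' @param x A `positional_density`.
#' @param ... Unused.
#' @return Tibble with columns event, position, density.
#' @export
tidy.positional_density <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    event = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    position = rep(seq_len(ncol(m)), each = nrow(m)),
    density = as.vector(m)
  )
}

derive_subseeds <- function(seed, n) {
  run_with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stratified_folds <- function(diagnosis, folds) {
  fold <- integer(length(diagnosis))
  for (g in unique(diagnosis)) {
    idx <- which(diagnosis == g)
    if (length(idx) < folds) {
      stop("stratification error: diagnosis group '", g,
           "' has fewer subjects (", length(idx), ") than folds (", folds, ")")
    }
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated event-based model fit
#'
#' Repeated stratified k-fold cross-validation of the whole pipeline stage:
#' for every repeat and fold, the KDE mixtures are refit on the training
#' split and an MCMC chain is run from the greedy-ascent optimum; the
#' `folds * repeats` posterior sample sets (50 under the defaults) are pooled
#' with equal weight into one cross-validated positional density. Separately,
#' the mixtures are fit on the full data and the greedy maximum-likelihood
#' sequence of that full-data model is retained for staging.
#'
#' @param cohort Cohort table (already covariate-adjusted if desired) with
#'   `diagnosis` and feature columns.
#' @param specs Feature specs (names and directions).
#' @param folds,repeats Cross-validation plan (defaults: 5 folds, 10 repeats).
#' @param seed Integer seed controlling fold assignment and all chains.
#' @param n_startpoints Greedy restarts per fit.
#' @param n_iter MCMC iterations per fold fit.
#' @param include_unlabeled Passed to [fit_cohort_mixtures()].
#' @param adjustment Optional `adjustment_model` stored alongside the fit
#'   (used later to adjust trial data before staging).
#' @return An `ebm_fit`: full-data mixtures and ML sequence, pooled
#'   positional density, and fit metadata.
#' @export
cross_validated_fit <- function(cohort, specs, folds = 5, repeats = 10,
                                seed = 1, n_startpoints = 10, n_iter = 10000,
                                include_unlabeled = TRUE, adjustment = NULL) {
  specs <- as_spec_list(specs)
  n_runs <- folds * repeats
  seeds <- derive_subseeds(seed, 2L * n_runs + 2L)
  fold_plan <- run_with_seed(seeds[1], {
    lapply(seq_len(repeats), function(r) stratified_folds(cohort$diagnosis,
                                                          folds))
  })
  sets <- vector("list", n_runs)
  i <- 0L
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      i <- i + 1L
      train <- cohort[fold_plan[[r]] != f, , drop = FALSE]
      models <- tryCatch(
        fit_cohort_mixtures(train, specs,
                            include_unlabeled = include_unlabeled),
        error = function(e) {
          stop("stratification error in repeat ", r, ", fold ", f, ": ",
               conditionMessage(e))
        })
      lik <- build_likelihood_matrix(train, models)
      start <- greedy_ascent(lik, n_startpoints, seed = seeds[2L * i])
      ps <- mcmc_sample(lik, start$order, n_iter = n_iter,
                        seed = seeds[2L * i + 1L])
      ps$provenance <- list(repeat_ = r, fold = f)
      sets[[i]] <- ps
    }
  }
  full_models <- fit_cohort_mixtures(cohort, specs,
                                     include_unlabeled = include_unlabeled)
  full_lik <- build_likelihood_matrix(cohort, full_models)
  ml <- greedy_ascent(full_lik, n_startpoints, seed = seeds[2L])
  structure(
    list(models = full_models,
         ml_sequence = ml$sequence,
         ml_log_lik = ml$log_lik,
         positional_density = positional_density(sets),
         specs = specs,
         adjustment = adjustment,
         meta = list(folds = folds, repeats = repeats, seed = seed,
                     n_startpoints = n_startpoints, n_iter = n_iter,
                     n_sets = n_runs,
                     include_unlabeled = include_unlabeled)),
    class = "ebm_fit"
  )
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat("<ebm_fit>", length(x$ml_sequence), "events;",
      x$meta$folds, "x", x$meta$repeats,
      "cross-validation pooled over", x$meta$n_sets, "sample sets\n")
  cat("  ML sequence:", paste(x$ml_sequence, collapse = " > "), "\n")
  invisible(x)
}

#' Summary statistics of a fitted event-based model
#'
#' @param x An `ebm_fit`.
#' @param ... Unused.
#' @return One-row tibble: number of events, log-likelihood of the ML
#'   sequence, sample sets pooled, and the mean positional certainty (mean of
#'   the row maxima of the positional density).
#' @export
glance.ebm_fit <- function(x, ...) {
  tibble::tibble(
    n_events = length(x$ml_sequence),
    ml_log_lik = x$ml_log_lik,
    n_sample_sets = x$meta$n_sets,
    mean_positional_certainty = mean(apply(unclass(x$positional_density),
                                           1, max))
  )
}

#' Per-event summary of a fitted event-based model
#'
#' @param x An `ebm_fit`.
#' @param ... Unused.
#' @return Tibble: event, ML position, posterior mean position, and mixture
#'   weight (estimated abnormal fraction).
#' @export
tidy.ebm_fit <- function(x, ...) {
  pd <- unclass(x$positional_density)
  mean_pos <- as.vector(pd %*% seq_len(ncol(pd)))
  tibble::tibble(
    event = rownames(pd),
    ml_position = match(rownames(pd), x$ml_sequence),
    mean_position = mean_pos,
    mixture_weight = vapply(x$models[rownames(pd)], `[[`, numeric(1),
                            "mixture_weight")
  )
}

# ---- staging ---------------------------------------------------------------

stage_posterior_matrix <- function(lik, sequence) {
  ord <- as_order(lik, sequence)
  pe <- lik$p_event[, ord, drop = FALSE]
  pn <- lik$p_noevent[, ord, drop = FALSE]
  msk <- lik$mask[, ord, drop = FALSE]
  pe[msk] <- 1  # masked features drop out of both products
  pn[msk] <- 1
  terms <- stage_terms(pe, pn)
  all_masked <- rowSums(!msk) == 0
  terms[all_masked, ] <- 1  # uniform posterior, flagged downstream
  post <- terms / rowSums(terms)
  list(posterior = post, all_masked = all_masked)
}

#' Maximum-likelihood disease stage per subject
#'
#' The stage posterior over `0..K` is proportional to
#' `prod_{i<=k} p_E[S(i)] * prod_{i>k} p_N[S(i)]` with masked features
#' dropped from both products; the assigned stage is the argmax, ties broken
#' toward the lower stage (conservative screening: fewer false late-stage
#' labels). Subjects with no observed features get a uniform posterior and
#' are flagged.
#'
#' @param lik An `ebm_likelihood` (or cohort + models via [stage_cohort()]).
#' @param sequence Event sequence to stage against (feature names or
#'   positions), typically the fit's ML sequence.
#' @return Tibble: subject_id, stage (integer `0..K`), stage_posterior
#'   (list-column of length-(K+1) vectors), all_masked flag.
#' @export
stage_subjects <- function(lik, sequence) {
  sp <- stage_posterior_matrix(lik, sequence)
  post <- sp$posterior
  # ties (within fp noise) break toward the lower stage
  first_max <- apply(post, 1L, function(p) which(p >= max(p) - 1e-12)[1]) - 1L
  tibble::tibble(
    subject_id = lik$subject_id,
    stage = as.integer(first_max),
    stage_posterior = lapply(seq_len(nrow(post)), function(i) post[i, ]),
    all_masked = sp$all_masked
  )
}

#' Stage a cohort with a fitted event-based model
#'
#' Applies the fit's covariate adjustment (if any), evaluates the mixture
#' likelihoods, and assigns each subject the maximum-likelihood stage under
#' the fit's full-data ML sequence. Features missing from the table are
#' marginalized out with a warning.
#'
#' @param cohort Data frame of subjects to stage.
#' @param fit An `ebm_fit`.
#' @param adjust Apply the stored covariate adjustment first (default TRUE
#'   when present).
#' @return Tibble as in [stage_subjects()].
#' @export
stage_cohort <- function(cohort, fit, adjust = !is.null(fit$adjustment)) {
  stopifnot(inherits(fit, "ebm_fit"))
  feats <- names(fit$models)
  absent <- setdiff(feats, names(cohort))
  if (length(absent)) {
    warning("staging without features (marginalized out): ",
            paste(absent, collapse = ", "))
    for (f in absent) cohort[[f]] <- NA_real_
  }
  if (adjust) {
    if (is.null(fit$adjustment)) stop("fit carries no adjustment model")
    cohort <- apply_covariate_adjustment(fit$adjustment, cohort)
  }
  lik <- build_likelihood_matrix(cohort, fit$models)
  stage_subjects(lik, fit$ml_sequence)
}

#' Normalized Kendall tau distance between two orderings
#'
#' Fraction of discordant pairs: 0 for identical orderings, 1 for a complete
#' reversal.
#'
#' @param a,b Two permutations of the same elements.
#' @return A number in `[0, 1]`.
#' @export
kendall_tau_distance <- function(a, b) {
  stopifnot(setequal(a, b), !anyDuplicated(a), !anyDuplicated(b))
  k <- length(a)
  pos <- match(a, b)
  disc <- 0L
  for (i in seq_len(k - 1)) {
    disc <- disc + sum(pos[(i + 1):k] < pos[i])
  }
  disc / choose(k, 2)
}
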