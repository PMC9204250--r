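# Two-component kernel-density mixtures: P(x | event) and P(x | no event).
#
# Each feature gets a pair of weighted Gaussian KDEs — a "normal" (pre-event)
# and an "abnormal" (post-event) component — fitted by alternating refit on a
# cohort containing labeled normals (e.g. CN), labeled abnormals (e.g. AD)
# and unlabeled subjects (e.g. MCI). KDE components accommodate the
# floor/ceiling pile-up of bounded cognitive instruments, where Gaussian
# components misbehave. Prior knowledge of disease direction is enforced by
# isotonic regression on the event posterior.

silverman_bw <- function(x, floor_frac = 1e-3) {
  n <- length(x)
  spread <- min(sd(x), IQR(x) / 1.34)
  bw <- 0.9 * spread * n^(-1 / 5)
  max(bw, floor_frac * diff(range(x)))
}

# weighted Gaussian KDE evaluated at query points
kde_eval <- function(query, centers, weights, bw) {
  w <- weights / sum(weights)
  out <- numeric(length(query))
  # chunk over query to bound the temporary matrix
  step <- max(1L, floor(5e6 / length(centers)))
  for (i in seq(1L, length(query), by = step)) {
    idx <- i:min(i + step - 1L, length(query))
    out[idx] <- as.vector(
      dnorm(outer(query[idx], centers, "-"), sd = bw) %*% w)
  }
  out
}

#' Fit a normal/abnormal KDE mixture for one feature
#'
#' Alternating refit: responsibilities are initialized from the labels
#' (unlabeled subjects start at 0.5); each iteration (a) re-estimates the two
#' weighted Gaussian-kernel densities, (b) sets the mixture weight to the
#' mean abnormal responsibility, and (c) updates the free responsibilities to
#' the posterior under the current mixture, stopping when the largest
#' responsibility change falls below `tol` (default 1e-4) or after `max_iter`
#' (default 200) passes.
#'
#' Bandwidths: Silverman's rule on the pooled sample (floored at `1e-3` of
#' the data range) sets the working scale; because the pooled two-class
#' sample is bimodal and Silverman's rule assumes unimodality, each component
#' additionally gets its own Silverman bandwidth from its labeled values once
#' the class medians separate by more than two pooled bandwidths. Without
#' separation both components share the pooled bandwidth, keeping the
#' no-signal posterior flat.
#'
#' Label noise: diagnosis labels are noisy proxies for per-feature event
#' status (an early event has already occurred in many "normal"-labeled
#' subjects), so labeled subjects can be released to float with the
#' posterior. Release happens (i) geometrically, before iterating, for values
#' on the wrong side of the midpoint between class medians by at least one
#' pooled bandwidth, and (ii) after each convergence, for values whose
#' posterior contradicts their label by more than 0.75, re-converging after
#' each release round (at most three). Both channels require real class
#' separation — under no signal nothing is released, so the fit cannot
#' polarize itself through label-flip feedback. Everyone else stays clamped
#' to their label.
#'
#' Finally the disease-direction constraint is imposed with
#' [enforce_direction()]. The fit is deterministic given its inputs.
#'
#' @param values Numeric feature values.
#' @param labels Character vector in `normal` / `abnormal` / `unlabeled`.
#' @param direction `+1` if the feature increases with disease, else `-1`.
#' @param min_labeled Minimum labeled subjects required per class.
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @param feature Optional feature name carried in the result.
#' @return A `kde_event_model`.
#' @export
fit_kde_mixture <- function(values, labels, direction,
                            min_labeled = 10, tol = 1e-4, max_iter = 200,
                            feature = NULL) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  if (!all(is.finite(values))) stop("values must be finite")
  if (!all(labels %in% c("normal", "abnormal", "unlabeled"))) {
    stop("labels must be 'normal', 'abnormal' or 'unlabeled'")
  }
  if (!direction %in% c(-1, 1)) stop("direction must be -1 or +1")
  n_norm <- sum(labels == "normal")
  n_abn <- sum(labels == "abnormal")
  if (n_norm < min_labeled || n_abn < min_labeled) {
    stop("insufficient data: need at least ", min_labeled,
         " labeled values per class (got ", n_norm, " normal, ",
         n_abn, " abnormal)")
  }
  if (diff(range(values)) == 0) {
    stop("degenerate density: all values are identical")
  }

  bw_full <- silverman_bw(values)
  floor_bw <- 1e-3 * diff(range(values))
  r0 <- ifelse(labels == "abnormal", 1, ifelse(labels == "normal", 0, 0.5))
  r <- r0

  # Diagnosis labels are noisy proxies for per-feature event status: an early
  # event has already happened in many "normal"-labeled subjects, and a late
  # event has not yet happened in many "abnormal"-labeled ones — either class
  # can carry substantial label contamination. Each class is therefore
  # anchored by the quartile of its values on its own side of the disease
  # direction (robust to contamination, which always pulls toward the other
  # side), and labeled points on the wrong side of the midpoint between the
  # anchors (by at least one pooled bandwidth) are released to float with the
  # posterior. Release is gated on the anchors actually separating: without
  # separation nothing is released and the components share the pooled
  # bandwidth, so a no-signal cohort cannot polarize itself through
  # label-flip feedback or bandwidth mismatch.
  med_norm <- median(values[labels == "normal"])
  med_abn <- median(values[labels == "abnormal"])
  classes_separate <- direction * (med_abn - med_norm) > 2 * bw_full
  loc_norm <- quantile(values[labels == "normal"],
                       if (direction > 0) 0.25 else 0.75, names = FALSE)
  loc_abn <- quantile(values[labels == "abnormal"],
                      if (direction > 0) 0.75 else 0.25, names = FALSE)
  midpoint <- (loc_abn + loc_norm) / 2
  released <- classes_separate & (
    (labels == "normal" & direction * (values - midpoint) > bw_full) |
      (labels == "abnormal" & direction * (values - midpoint) < -bw_full))
  free <- labels == "unlabeled" | released

  # Silverman's rule assumes a unimodal sample; on the pooled two-class data
  # it oversmooths the components, so once the classes separate each
  # component gets its own Silverman bandwidth, estimated from its labeled
  # values on its own side of the midpoint (contaminants excluded).
  class_bw <- function(x) {
    if (length(x) < 2) return(bw_full)
    b <- 0.9 * min(sd(x), IQR(x) / 1.34) * length(x)^(-1 / 5)
    if (!is.finite(b) || b <= 0) bw_full else max(b, floor_bw)
  }
  if (classes_separate) {
    bw_n <- class_bw(values[labels == "normal" &
                              direction * (values - midpoint) <= 0])
    bw_e <- class_bw(values[labels == "abnormal" &
                              direction * (values - midpoint) >= 0])
  } else {
    bw_n <- bw_e <- bw_full
  }

  kmat_n <- dnorm(outer(values, values, "-"), sd = bw_n)
  kmat_e <- if (bw_e == bw_n) kmat_n else
    dnorm(outer(values, values, "-"), sd = bw_e)
  post <- r
  # after each convergence, labeled points whose posterior decisively
  # contradicts their label (by > 0.75) are also released and the mixture is
  # re-converged; the margin is unreachable without real class separation
  for (round in 1:3) {
    for (iter in seq_len(max_iter)) {
      f_e <- as.vector(kmat_e %*% r) / sum(r)
      f_n <- as.vector(kmat_n %*% (1 - r)) / sum(1 - r)
      w <- mean(r)
      post <- w * f_e / (w * f_e + (1 - w) * f_n)
      post[!is.finite(post)] <- 0.5
      r_new <- ifelse(free, post, r0)
      delta <- max(abs(r_new - r))
      r <- r_new
      if (delta < tol) break
    }
    newly <- !free & labels != "unlabeled" & abs(post - r0) > 0.75
    if (!any(newly)) break
    free <- free | newly
  }

  model <- structure(
    list(feature = feature %||% "feature",
         centers = values,
         bandwidth_normal = bw_n,
         bandwidth_abnormal = bw_e,
         weights_abnormal = r / sum(r),
         weights_normal = (1 - r) / sum(1 - r),
         mixture_weight = mean(r),
         disease_direction = as.integer(direction),
         n_iter = iter,
         grid = NULL, posterior_grid = NULL, monotone_raw = NA),
    class = "kde_event_model"
  )
  enforce_direction(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kde_event_model <- function(x, ...) {
  cat(sprintf(
    "<kde_event_model> %s: %d kernels, bw %.4g/%.4g, abnormal fraction %.3f, dir %+d\n",
    x$feature, length(x$centers), x$bandwidth_normal, x$bandwidth_abnormal,
    x$mixture_weight, x$disease_direction))
  invisible(x)
}

#' Raw component densities of a fitted mixture
#'
#' @param model A `kde_event_model`.
#' @param x Query values.
#' @return A tibble with columns `x`, `f_event`, `f_noevent`.
#' @export
component_density <- function(model, x) {
  tibble::tibble(
    x = x,
    f_event = kde_eval(x, model$centers, model$weights_abnormal,
                       model$bandwidth_abnormal),
    f_noevent = kde_eval(x, model$centers, model$weights_normal,
                         model$bandwidth_normal)
  )
}

raw_posterior <- function(model, x) {
  d <- component_density(model, x)
  w <- model$mixture_weight
  num <- w * d$f_event
  den <- num + (1 - w) * d$f_noevent
  post <- num / den
  dead <- !is.finite(post)  # beyond all kernel support: take the limit
  if (any(dead)) {
    mid <- median(model$centers)
    post[dead] <- as.numeric(model$disease_direction * (x[dead] - mid) > 0)
  }
  attr(post, "beyond_support") <- dead
  post
}

# pool-adjacent-violators for a weighted non-decreasing least-squares fit
pava_nondecreasing <- function(y, w) {
  val <- as.numeric(y)
  wt <- as.numeric(w)
  reps <- rep(1L, length(y))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-15) {
      tot <- wt[i] + wt[i + 1]
      val[i] <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / tot
      wt[i] <- tot
      reps[i] <- reps[i] + reps[i + 1]
      val <- val[-(i + 1)]; wt <- wt[-(i + 1)]; reps <- reps[-(i + 1)]
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep(val, reps)
}

#' Impose the disease-direction constraint on the event posterior
#'
#' Isotonic regression (pool-adjacent-violators) of the event posterior
#' P(event | x) over a 512-point grid spanning the kernel range, oriented by
#' the model's disease direction and weighted by the mixture density at each
#' grid point — the monotone projection in the geometry of the data
#' distribution. Density weighting matters for bounded instruments: with a
#' floor/ceiling point mass the two components carry very different
#' bandwidths, the raw posterior spikes toward the wrong limit in the empty
#' region beyond the support edge, and an unweighted projection would pool
#' that artifact into a plateau across the populated range. The constrained
#' posterior replaces the raw one for all downstream use; raw component
#' densities are retained for reporting. When the raw posterior is already
#' monotone the model keeps evaluating it exactly (no grid interpolation), so
#' the projection is an identity there.
#'
#' @param model A `kde_event_model`.
#' @param grid_size Grid resolution.
#' @return The model with the constrained posterior attached.
#' @export
enforce_direction <- function(model, grid_size = 512) {
  rng <- range(model$centers)
  pad <- 3 * max(model$bandwidth_normal, model$bandwidth_abnormal)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = grid_size)
  post <- as.numeric(raw_posterior(model, grid))
  w <- model$mixture_weight
  dens <- component_density(model, grid)
  weight <- w * dens$f_event + (1 - w) * dens$f_noevent
  weight <- pmax(weight, max(weight) * 1e-12)
  fit <- if (model$disease_direction > 0) {
    pava_nondecreasing(post, weight)
  } else {
    rev(pava_nondecreasing(rev(post), rev(weight)))
  }
  fit <- pmin(pmax(fit, 0), 1)
  model$grid <- grid
  model$posterior_grid <- fit
  model$monotone_raw <- max(abs(fit - post)) < 1e-12
  model
}

#' Posterior probability that the event has occurred
#'
#' Evaluates the direction-constrained event posterior
#' `P(event | x) = w f_E(x) / (w f_E(x) + (1-w) f_N(x))`. Queries beyond all
#' kernel support take the limiting value implied by the disease direction
#' (1 on the disease side, 0 on the other) and are flagged in the
#' `beyond_support` attribute.
#'
#' @param model A `kde_event_model`.
#' @param x Query values.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
event_posterior <- function(model, x) {
  stopifnot(all(is.finite(x)))
  if (is.null(model$posterior_grid)) model <- enforce_direction(model)
  if (isTRUE(model$monotone_raw)) {
    post <- raw_posterior(model, x)
    dead <- attr(post, "beyond_support")
    post <- as.numeric(post)
  } else {
    post <- approx(model$grid, model$posterior_grid, x, rule = 2)$y
    dead <- x < model$grid[1] | x > model$grid[length(model$grid)]
    if (any(dead)) {
      mid <- median(model$centers)
      post[dead] <- as.numeric(model$disease_direction * (x[dead] - mid) > 0)
    }
  }
  post <- pmin(pmax(post, 0), 1)
  attr(post, "beyond_support") <- dead
  post
}

# (f_E, f_N) pair consistent with the constrained posterior: scaled so that
# the overall mixture density is preserved and the posterior under the
# mixture weight equals the constrained posterior. When the raw posterior is
# already monotone these are exactly the raw component densities.
likelihood_pair <- function(model, x) {
  d <- component_density(model, x)
  w <- min(max(model$mixture_weight, 1e-9), 1 - 1e-9)
  f_mix <- w * d$f_event + (1 - w) * d$f_noevent
  q <- as.numeric(event_posterior(model, x))
  floor_d <- 1e-300
  tibble::tibble(
    p_event = pmax(q * f_mix / w, floor_d),
    p_noevent = pmax((1 - q) * f_mix / (1 - w), floor_d)
  )
}

#' Fit KDE mixtures for every feature of a cohort
#'
#' Maps diagnosis labels to mixture labels (`CN` = normal, `AD` = abnormal,
#' anything else unlabeled by default) and fits one [fit_kde_mixture()] per
#' feature.
#'
#' @param cohort Data frame with `diagnosis` and feature columns.
#' @param specs Feature specs providing names and disease directions.
#' @param include_unlabeled If `FALSE`, drop unlabeled (e.g. MCI) rows from
#'   the mixture fit instead of letting them enter at responsibility 0.5.
#' @param label_map Named vector mapping diagnosis values to mixture labels.
#' @param ... Passed to [fit_kde_mixture()].
#' @return Named list of `kde_event_model`s.
#' @export
fit_cohort_mixtures <- function(cohort, specs, include_unlabeled = TRUE,
                                label_map = c(CN = "normal", AD = "abnormal"),
                                ...) {
  specs <- as_spec_list(specs)
  labels <- unname(label_map[as.character(cohort$diagnosis)])
  labels[is.na(labels)] <- "unlabeled"
  keep <- if (include_unlabeled) rep(TRUE, nrow(cohort)) else
    labels != "unlabeled"
  setNames(lapply(specs, function(s) {
    fit_kde_mixture(cohort[[s$name]][keep], labels[keep],
                    direction = s$disease_direction, feature = s$name, ...)
  }), spec_names(specs))
}
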