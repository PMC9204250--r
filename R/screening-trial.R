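# Stage-based stratification of trial participants and the subgroup
# analyses run on the resulting strata: Kaplan-Meier conversion curves, Cox
# proportional-hazards treatment effects with Hochberg familywise
# correction (primary outcome), and per-visit Mann-Whitney comparisons of
# cognition (secondary outcome).

#' Stratify staged subjects at a stage threshold
#'
#' Subjects with stage strictly greater than `threshold` are labeled
#' `"Late-stage"`, everyone else `"Others"` — an exhaustive, disjoint
#' partition.
#'
#' @param stages Tibble with `subject_id` and `stage` (as from
#'   [stage_cohort()]).
#' @param threshold Integer stage cut (default 8).
#' @return Tibble: subject_id, stage, subgroup; counts per label attached as
#'   attribute `"counts"`.
#' @export
stratify_by_stage <- function(stages, threshold = 8) {
  stopifnot(nrow(stages) > 0, threshold >= 0)
  out <- tibble::tibble(
    subject_id = stages$subject_id,
    stage = stages$stage,
    subgroup = ifelse(stages$stage > threshold, "Late-stage", "Others")
  )
  attr(out, "counts") <- table(factor(out$subgroup,
                                      levels = c("Others", "Late-stage")))
  attr(out, "threshold") <- threshold
  out
}

#' Suggest a stage threshold from the stage histogram
#'
#' Locates the minimum-count valley between the two largest modes of the
#' stage histogram — an automatic alternative to choosing the late-stage cut
#' by eye. Returns the stage at the bottom of that valley, so that
#' "late-stage" means strictly beyond it.
#'
#' @param stages Tibble with a `stage` column, or an integer vector.
#' @param k Maximum stage (defaults to the observed maximum).
#' @return An integer threshold.
#' @export
suggest_stage_threshold <- function(stages, k = NULL) {
  s <- if (is.data.frame(stages)) stages$stage else stages
  k <- k %||% max(s)
  counts <- tabulate(factor(s, levels = 0:k), nbins = k + 1)
  # local maxima of the histogram (plateau-tolerant)
  is_peak <- vapply(seq_along(counts), function(i) {
    left <- if (i == 1) -Inf else counts[i - 1]
    right <- if (i == length(counts)) -Inf else counts[i + 1]
    counts[i] >= left && counts[i] >= right && counts[i] > 0
  }, logical(1))
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(k)  # unimodal: no late mode to split off
  top2 <- peaks[order(counts[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- which.min(counts[lo:hi]) + lo - 1L
  as.integer(valley - 1L)  # stages are 0-based
}

#' Kaplan-Meier curve with Greenwood log-log confidence interval
#'
#' Product-limit estimate of the survival (non-conversion) function, with
#' 95% confidence bounds from Greenwood's variance on the log(-log) scale.
#'
#' @param times Positive event/censoring times.
#' @param events Event indicators (1 = converted, 0 = censored).
#' @param conf_level Confidence level.
#' @return A tibble (class `km_curve`): time, at_risk, n_event, survival,
#'   ci_low, ci_high.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0) stop("no subjects")
  stopifnot(length(times) == length(events), all(times > 0))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log", conf.int = conf_level)
  out <- tibble::tibble(
    time = sf$time,
    at_risk = sf$n.risk,
    n_event = sf$n.event,
    survival = sf$surv,
    ci_low = ifelse(is.na(sf$lower), ifelse(sf$surv == 0, 0, NA), sf$lower),
    ci_high = ifelse(is.na(sf$upper), ifelse(sf$surv %in% c(0, 1),
                                             sf$surv, NA), sf$upper)
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Cox proportional-hazards treatment effect
#'
#' Partial-likelihood fit (Efron tie handling) of conversion hazard on a
#' treatment indicator plus baseline covariates, comparing one treatment arm
#' against placebo. Intention-to-treat: every randomized subject in the two
#' arms is retained, with dropouts censored at their last attended visit.
#' The hazard ratio, Wald 95% confidence interval and Wald p-value refer to
#' the treatment coefficient.
#'
#' @param trial Trial table with `arm`, `time_months`, `converted` and the
#'   covariate columns.
#' @param treatment_arm Arm compared against placebo.
#' @param covariates Baseline covariate column names (default age, MMSE and
#'   APOE-e4 carriage).
#' @param placebo_label Label of the placebo arm.
#' @param subgroup Optional logical vector (or subject_id subset) restricting
#'   the analysis.
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble (class `cox_result`): arm, n, n_events, hr,
#'   ci_low, ci_high, p_raw, plus covariate coefficients as an attribute.
#' @export
cox_fit <- function(trial, treatment_arm,
                    covariates = c("age", "mmse", "apoe4"),
                    placebo_label = "placebo", subgroup = NULL,
                    conf_level = 0.95) {
  if (!is.null(subgroup)) {
    trial <- if (is.logical(subgroup)) trial[subgroup, , drop = FALSE]
    else trial[trial$subject_id %in% subgroup, , drop = FALSE]
  }
  trial <- trial[trial$arm %in% c(placebo_label, treatment_arm), ,
                 drop = FALSE]
  missing_cols <- setdiff(c("arm", "time_months", "converted", covariates),
                          names(trial))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (sum(trial$converted) < 1) stop("zero events in the analysis set")
  df <- trial
  df$.treated <- as.integer(df$arm == treatment_arm)
  for (cv in covariates) {
    if (length(unique(df[[cv]])) < 2) {
      stop("constant covariate in the analysis set: ", cv)
    }
  }
  rhs <- paste(c(".treated", sprintf("`%s`", covariates)), collapse = " + ")
  fml <- as.formula(paste("survival::Surv(time_months, converted) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    stop("Cox fit failed to converge")
  }
  beta <- coef(fit)[".treated"]
  se <- sqrt(diag(fit$var))[1]
  if (!is.finite(beta) || !is.finite(se)) {
    stop("Cox fit did not converge: non-finite treatment coefficient")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    arm = treatment_arm,
    n = nrow(df),
    n_events = sum(df$converted),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * se),
    ci_high = exp(unname(beta) + z * se),
    p_raw = 2 * pnorm(-abs(unname(beta) / se))
  )
  attr(out, "coefficients") <- coef(fit)
  class(out) <- c("cox_result", class(out))
  out
}

#' Hochberg step-up multiplicity adjustment
#'
#' Step-up adjusted p-values: with the raw values sorted ascending,
#' `adj(i) = min over j >= i of min(1, (m - j + 1) * p(j))`, returned in the
#' input order. `NA` entries (non-estimable tests) stay `NA` but still count
#' toward the family size, keeping the correction honest when a stratum
#' cannot be analyzed.
#'
#' @param p Raw p-values in `[0, 1]` (may contain `NA`).
#' @param family_size Family size m; defaults to `length(p)` including `NA`s.
#' @return Adjusted p-values in input order.
#' @export
hochberg_adjust <- function(p, family_size = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE),
            family_size >= sum(!is.na(p)))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) {
    out[ok] <- p.adjust(p[ok], method = "hochberg", n = family_size)
  }
  out
}

#' Mann-Whitney U test
#'
#' U statistic for `x` over `y` with midrank ties. The p-value is by exact
#' enumeration when `n_x * n_y <= 400` and there are no ties, otherwise by
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y Samples to compare.
#' @param two_sided Two-sided test (default).
#' @return One-row tibble: u, p, n_x, n_y, method.
#' @export
mann_whitney_u <- function(x, y, two_sided = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx * ny <= 400) && !ties
  alternative <- if (two_sided) "two.sided" else "greater"
  if (length(unique(c(x, y))) == 1) {
    p <- 1  # degenerate: all values identical
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = exact,
                  correct = TRUE))
    p <- wt$p.value
  }
  tibble::tibble(u = u, p = min(p, 1), n_x = nx, n_y = ny,
                 method = if (exact) "exact" else "normal approximation")
}

join_subgroups <- function(trial, labeling) {
  if (!all(trial$subject_id %in% labeling$subject_id)) {
    stop("labeling does not cover every trial subject")
  }
  dplyr::left_join(trial,
                   labeling[, c("subject_id", "subgroup")],
                   by = "subject_id")
}

#' Primary outcome: subgroup survival analysis
#'
#' For each analysis stratum (all subjects, Others, Late-stage) and each
#' non-placebo arm: a Kaplan-Meier curve pair (placebo and arm) and a Cox
#' treatment hazard ratio with covariates. All arm-by-stratum Cox p-values
#' form one Hochberg family — the correction spans every subgroup analyzed,
#' not just the one of interest. Strata where the Cox model is not estimable
#' (e.g. no events) are reported as `NA` but still count in the family.
#'
#' @param trial Trial table (baseline covariates, `arm`, `time_months`,
#'   `converted`).
#' @param labeling Subgroup labeling from [stratify_by_stage()].
#' @param arms Treatment arms to compare against placebo (default: all
#'   non-placebo arms in the table).
#' @param covariates Cox covariates.
#' @param placebo_label Placebo arm label.
#' @return A `primary_outcome` object: `$cox` tibble (stratum, arm, n,
#'   n_events, hr, ci_low, ci_high, p_raw, p_adj) and `$km` tibble
#'   (stratum, arm, time, at_risk, survival, ci_low, ci_high).
#' @export
primary_outcome_analysis <- function(trial, labeling, arms = NULL,
                                     covariates = c("age", "mmse", "apoe4"),
                                     placebo_label = "placebo") {
  trial <- join_subgroups(trial, labeling)
  arms <- arms %||% setdiff(unique(trial$arm), placebo_label)
  strata <- list(
    All = rep(TRUE, nrow(trial)),
    Others = trial$subgroup == "Others",
    `Late-stage` = trial$subgroup == "Late-stage"
  )
  if (sum(vapply(strata, any, logical(1))) < 2) {
    stop("need at least 2 non-empty analysis strata")
  }
  grid <- expand.grid(stratum = names(strata), arm = arms,
                      stringsAsFactors = FALSE)
  cox_rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- strata[[grid$stratum[i]]]
    res <- tryCatch(
      cox_fit(trial, grid$arm[i], covariates = covariates,
              placebo_label = placebo_label, subgroup = sel),
      error = function(e) tibble::tibble(
        arm = grid$arm[i],
        n = sum(sel & trial$arm %in% c(placebo_label, grid$arm[i])),
        n_events = sum(trial$converted[sel & trial$arm %in%
                                         c(placebo_label, grid$arm[i])]),
        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_raw = NA_real_)
    )
    dplyr::bind_cols(tibble::tibble(stratum = grid$stratum[i]),
                     tibble::as_tibble(res))
  })
  cox <- dplyr::bind_rows(cox_rows)
  cox$p_adj <- hochberg_adjust(cox$p_raw, family_size = nrow(cox))

  km_rows <- list()
  for (st in names(strata)) {
    for (a in c(placebo_label, arms)) {
      sel <- strata[[st]] & trial$arm == a
      if (!any(sel)) next
      curve <- km_estimate(trial$time_months[sel], trial$converted[sel])
      km_rows[[paste(st, a)]] <- dplyr::bind_cols(
        tibble::tibble(stratum = st, arm = a), tibble::as_tibble(curve))
    }
  }
  structure(list(cox = cox, km = dplyr::bind_rows(km_rows)),
            class = "primary_outcome")
}

#' @export
print.primary_outcome <- function(x, ...) {
  cat("<primary_outcome> Cox treatment effects by stratum:\n")
  print(as.data.frame(x$cox), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.primary_outcome <- function(x, ...) x$cox

#' Secondary outcome: per-visit cognition comparison
#'
#' Two-sided Mann-Whitney U test of the cognitive outcome between placebo
#' and treatment at each follow-up visit within each subgroup, on the values
#' observed at that visit (no imputation after dropout). All subgroup-by-
#' visit p-values form one Hochberg family.
#'
#' @param trial Trial table with `adas13_m<visit>` columns.
#' @param labeling Subgroup labeling from [stratify_by_stage()].
#' @param treatment_arm Treatment arm (default donepezil).
#' @param placebo_label Placebo arm label.
#' @param visits Visit months (default 6, 12, ..., 36).
#' @param outcome_prefix Prefix of the per-visit outcome columns.
#' @return Tibble (class `cognition_comparison`): subgroup, visit_month,
#'   n_placebo, n_treated, u, p_raw, p_adj.
#' @export
secondary_outcome_analysis <- function(trial, labeling,
                                       treatment_arm = "donepezil",
                                       placebo_label = "placebo",
                                       visits = seq(6, 36, by = 6),
                                       outcome_prefix = "adas13_m") {
  trial <- join_subgroups(trial, labeling)
  cols <- paste0(outcome_prefix, visits)
  absent <- setdiff(cols, names(trial))
  if (length(absent)) {
    stop("trial table is missing visit columns: ",
         paste(absent, collapse = ", "))
  }
  subgroups <- c("Others", "Late-stage")
  grid <- expand.grid(subgroup = subgroups, visit_month = visits,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    col <- paste0(outcome_prefix, grid$visit_month[i])
    in_sub <- trial$subgroup == grid$subgroup[i]
    x <- trial[[col]][in_sub & trial$arm == placebo_label]
    y <- trial[[col]][in_sub & trial$arm == treatment_arm]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(subgroup = grid$subgroup[i],
                            visit_month = grid$visit_month[i],
                            n_placebo = length(x), n_treated = length(y),
                            u = NA_real_, p_raw = NA_real_))
    }
    mw <- mann_whitney_u(x, y)
    tibble::tibble(subgroup = grid$subgroup[i],
                   visit_month = grid$visit_month[i],
                   n_placebo = mw$n_x, n_treated = mw$n_y,
                   u = mw$u, p_raw = mw$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- hochberg_adjust(out$p_raw, family_size = nrow(out))
  class(out) <- c("cognition_comparison", class(out))
  out
}
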