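#' Declare a cognitive feature for simulation and model fitting
#'
#' A feature spec describes one bounded cognitive instrument: its measurement
#' bounds, the direction in which it moves with disease, and the normal
#' (pre-event) and abnormal (post-event) sampling distributions used by the
#' synthetic-cohort generator. Optional linear age and education coefficients
#' let the generator induce covariate effects that the preprocessing step
#' must remove.
#'
#' @param name Feature name; becomes the cohort column name.
#' @param lower_bound,upper_bound Instrument bounds (either may be `NA` for
#'   unbounded). Generated values are clipped to these bounds, producing the
#'   floor/ceiling pile-up typical of cognitive scales.
#' @param disease_direction `+1` if the value increases with disease severity,
#'   `-1` if it decreases.
#' @param normal_mean,normal_sd Distribution of the measure before its event.
#' @param abnormal_mean,abnormal_sd Distribution after the event.
#' @param age_coef,edu_coef Additive change in the measure per year of age
#'   (centred at 73) and per year of education (centred at 14.6).
#' @return A `feature_spec` object (a named list).
#' @export
feature_spec <- function(name, lower_bound = NA_real_, upper_bound = NA_real_,
                         disease_direction, normal_mean, normal_sd,
                         abnormal_mean, abnormal_sd,
                         age_coef = 0, edu_coef = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!disease_direction %in% c(-1, 1)) {
    stop("disease_direction must be -1 or +1 for feature '", name, "'")
  }
  if (!is.na(lower_bound) && !is.na(upper_bound) && lower_bound >= upper_bound) {
    stop("lower_bound must be below upper_bound for feature '", name, "'")
  }
  if (normal_sd <= 0 || abnormal_sd <= 0) {
    stop("normal_sd and abnormal_sd must be positive for feature '", name, "'")
  }
  if (sign(abnormal_mean - normal_mean) != disease_direction) {
    stop("abnormal_mean must lie on the disease_direction side of normal_mean ",
         "for feature '", name, "'")
  }
  structure(
    list(name = name, lower_bound = lower_bound, upper_bound = upper_bound,
         disease_direction = as.integer(disease_direction),
         normal_mean = normal_mean, normal_sd = normal_sd,
         abnormal_mean = abnormal_mean, abnormal_sd = abnormal_sd,
         age_coef = age_coef, edu_coef = edu_coef),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf(
    "<feature_spec> %s [%s, %s] dir %+d  normal %.2f (%.2f)  abnormal %.2f (%.2f)\n",
    x$name, format(x$lower_bound), format(x$upper_bound), x$disease_direction,
    x$normal_mean, x$normal_sd, x$abnormal_mean, x$abnormal_sd))
  invisible(x)
}

spec_names <- function(specs) vapply(specs, `[[`, character(1), "name")

as_spec_list <- function(specs) {
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "feature_spec")))
  nm <- spec_names(specs)
  if (anyDuplicated(nm)) stop("duplicate feature names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  specs
}

#' Default cognitive test battery
#'
#' Ten bounded cognitive instruments spanning global function (CDR), general
#' cognition (MMSE), episodic memory (Logical Memory), language (Boston
#' Naming, category fluency), visuospatial/executive function (Clock Drawing,
#' DSST) and working memory (digit span backwards). ADAS-Cog is deliberately
#' absent: it serves as a trial outcome and must not enter the staging model.
#' Normal/abnormal locations and the covariate coefficients are chosen to
#' resemble published cognitively-normal and dementia group summaries for
#' these instruments; they are simulation defaults, not normative data.
#'
#' @return A list of [feature_spec()] objects.
#' @export
ad_cognitive_battery <- function() {
  list(
    feature_spec("clock_drawing", 0, 5, -1, 4.6, 0.6, 2.6, 1.2,
                 age_coef = -0.01, edu_coef = 0.02),
    feature_spec("cdr_global", 0, 3, +1, 0.06, 0.15, 1.0, 0.45),
    feature_spec("cdr_sob", 0, 18, +1, 0.15, 0.45, 5.5, 2.0,
                 age_coef = 0.01),
    feature_spec("lm_immediate", 0, 25, -1, 10.5, 3.0, 3.8, 2.6,
                 age_coef = -0.06, edu_coef = 0.25),
    feature_spec("lm_delayed", 0, 25, -1, 9.0, 3.0, 1.4, 1.9,
                 age_coef = -0.06, edu_coef = 0.22),
    feature_spec("mmse", 0, 30, -1, 29.0, 1.1, 23.2, 2.4,
                 age_coef = -0.03, edu_coef = 0.08),
    feature_spec("boston_naming", 0, 30, -1, 27.5, 2.3, 20.0, 5.0,
                 edu_coef = 0.20),
    feature_spec("animals", 0, NA, -1, 20.0, 4.8, 10.5, 4.0,
                 age_coef = -0.10, edu_coef = 0.30),
    feature_spec("digit_span_bwd", 0, 12, -1, 7.0, 2.0, 4.2, 1.7,
                 edu_coef = 0.12),
    feature_spec("dsst", 0, 93, -1, 45.0, 10.0, 21.0, 8.5,
                 age_coef = -0.45, edu_coef = 0.60)
  )
}

#' Generic feature specs with controlled class separation
#'
#' Produces `k` synthetic instruments whose normal component is standard
#' normal and whose abnormal component sits `separation` standard deviations
#' away in the disease direction. Used to study sequence and stage recovery
#' as a function of signal strength.
#'
#' @param k Number of features (events).
#' @param separation Distance between normal and abnormal means, in SD units.
#' @param directions Vector of `+1`/`-1`, recycled to length `k`. Default
#'   alternates so both orientations are exercised.
#' @param bounded If `TRUE`, clip at `+/- (separation + 3)` to mimic
#'   instrument floors/ceilings.
#' @return A list of [feature_spec()] objects named `feature_01`, ...
#' @export
simulation_battery <- function(k, separation = 2,
                               directions = rep(c(-1, 1), length.out = k),
                               bounded = FALSE) {
  stopifnot(k >= 2, separation > 0)
  directions <- rep_len(directions, k)
  lapply(seq_len(k), function(i) {
    d <- directions[i]
    feature_spec(
      sprintf("feature_%02d", i),
      lower_bound = if (bounded) -(separation + 3) else NA_real_,
      upper_bound = if (bounded) separation + 3 else NA_real_,
      disease_direction = d,
      normal_mean = 0, normal_sd = 1,
      abnormal_mean = d * separation, abnormal_sd = 1
    )
  })
}
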