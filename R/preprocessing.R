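# Covariate adjustment and complete-case filtering.
#
# Cognitive scores drift with age and education independently of disease, so
# features are residualized against those covariates before mixture fitting.
# The adjustment is estimated on the cognitively-normal reference group only
# (whose variation is presumed non-pathological) and then applied uniformly
# to every subject, preserving the CN group mean of each feature.

#' Fit a covariate-adjustment model on the reference group
#'
#' Ordinary least squares of each feature on the covariates, using only rows
#' whose diagnosis equals `reference_label`. The fitted coefficients and the
#' reference-group feature means are stored so that
#' [apply_covariate_adjustment()] can residualize any cohort — including a
#' trial cohort with no normal-control arm — against the same reference.
#'
#' @param cohort Data frame with a `diagnosis` column, the features, and the
#'   covariates.
#' @param features Character vector of feature column names.
#' @param covariates Covariate column names (default age and education).
#' @param reference_label Diagnosis label of the reference group.
#' @return An `adjustment_model` object.
#' @export
fit_covariate_adjustment <- function(cohort, features,
                                     covariates = c("age", "education"),
                                     reference_label = "CN") {
  missing_cols <- setdiff(c("diagnosis", features, covariates), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ref <- cohort[cohort$diagnosis == reference_label, , drop = FALSE]
  ref <- ref[complete.cases(ref[, covariates, drop = FALSE]), , drop = FALSE]
  for (cv in covariates) {
    if (length(unique(ref[[cv]])) < 2) {
      stop("rank-deficient design: covariate '", cv,
           "' is constant in the reference group")
    }
  }
  fits <- lapply(features, function(f) {
    rows <- ref[!is.na(ref[[f]]), , drop = FALSE]
    if (nrow(rows) < 3) {
      stop("need at least 3 complete reference subjects for feature '", f, "'")
    }
    fml <- as.formula(paste0("`", f, "` ~ ",
                             paste0("`", covariates, "`", collapse = " + ")))
    cf <- coef(lm(fml, data = rows))
    if (any(!is.finite(cf))) {
      stop("rank-deficient design for feature '", f, "': ",
           paste(covariates[which(!is.finite(cf[-1]))], collapse = ", "))
    }
    list(coefficients = cf, reference_mean = mean(rows[[f]]))
  })
  structure(
    list(features = features, covariates = covariates,
         reference_label = reference_label,
         fits = setNames(fits, features)),
    class = "adjustment_model"
  )
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("<adjustment_model>", length(x$features), "features adjusted for",
      paste(x$covariates, collapse = " + "),
      "fitted on", x$reference_label, "\n")
  invisible(x)
}

#' Residualize a cohort against the fitted covariate model
#'
#' Each feature value becomes `raw - (predicted - reference mean)`, i.e. the
#' covariate-predicted component is removed while the reference-group mean is
#' preserved. All diagnosis groups are adjusted identically. Adjusted values
#' are deliberately not re-clipped to instrument bounds: the boundary mass
#' the mixtures must handle is a property of the raw measurements, and
#' re-clipping would distort group separation after adjustment. Rows missing
#' a covariate pass through unadjusted and are flagged in an
#' `adjustment_skipped` column.
#'
#' @param model An `adjustment_model` from [fit_covariate_adjustment()].
#' @param cohort Data frame containing the model's features and covariates.
#' @return The cohort as a tibble with adjusted feature columns.
#' @export
apply_covariate_adjustment <- function(model, cohort) {
  stopifnot(inherits(model, "adjustment_model"))
  missing_cols <- setdiff(c(model$features, model$covariates), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(cohort)
  cov_mat <- as.matrix(out[, model$covariates, drop = FALSE])
  skip <- apply(cov_mat, 1L, function(r) any(is.na(r)))
  for (f in model$features) {
    fit <- model$fits[[f]]
    predicted <- fit$coefficients[1] +
      as.vector(cov_mat %*% fit$coefficients[-1])
    adj <- out[[f]] - (predicted - fit$reference_mean)
    out[[f]] <- ifelse(skip, out[[f]], adj)
  }
  out$adjustment_skipped <- skip
  out
}

#' Keep only subjects with complete data on the model features
#'
#' Retains exactly the rows with no missing value across the named features,
#' preserving row order and all other columns. Missingness in columns outside
#' `features` is ignored.
#'
#' @param cohort Data frame.
#' @param features Feature column names that must be complete.
#' @param quiet Suppress the retained-count message.
#' @return Filtered tibble; the per-diagnosis retention counts are attached
#'   as attribute `"retention"`.
#' @export
complete_case_filter <- function(cohort, features, quiet = FALSE) {
  missing_cols <- setdiff(features, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- complete.cases(cohort[, features, drop = FALSE])
  out <- tibble::as_tibble(cohort)[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("complete-case filter removed every row")
  if ("diagnosis" %in% names(cohort)) {
    retention <- dplyr::count(
      dplyr::mutate(tibble::as_tibble(cohort), .kept = keep),
      .data$diagnosis, .data$.kept)
    attr(out, "retention") <- retention
    if (!quiet) {
      message("complete cases: ", sum(keep), " of ", length(keep), " retained")
    }
  }
  out
}
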