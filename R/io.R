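# Serialization: cohort CSV (strict dialect: UTF-8, comma, header, '.'
# decimal), fitted-model JSON, ground-truth JSON, and YAML configuration.

#' Write / read a cohort table as CSV
#'
#' @param cohort Data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns a tibble; `write_cohort_csv` its input,
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

spec_to_list <- function(s) unclass(s)

list_to_spec <- function(l) do.call(feature_spec, l)

model_to_list <- function(m) {
  list(feature = m$feature, centers = m$centers,
       bandwidth_normal = m$bandwidth_normal,
       bandwidth_abnormal = m$bandwidth_abnormal,
       weights_abnormal = m$weights_abnormal,
       weights_normal = m$weights_normal,
       mixture_weight = m$mixture_weight,
       disease_direction = m$disease_direction,
       n_iter = m$n_iter, grid = m$grid,
       posterior_grid = m$posterior_grid, monotone_raw = m$monotone_raw)
}

list_to_model <- function(l) {
  l$disease_direction <- as.integer(l$disease_direction)
  structure(l, class = "kde_event_model")
}

#' Serialize a fitted event-based model to JSON
#'
#' The JSON carries everything needed to stage new data: per-feature kernel
#' mixtures (centers, weights, bandwidth, mixture weight, direction, isotonic
#' posterior grid), the covariate-adjustment model, the maximum-likelihood
#' sequence, the pooled positional density, and the fit metadata.
#'
#' @param fit An `ebm_fit`.
#' @param path Output path.
#' @return `read_model_json` reconstructs the `ebm_fit`.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "ebm_fit"))
  adj <- if (!is.null(fit$adjustment)) {
    list(features = fit$adjustment$features,
         covariates = fit$adjustment$covariates,
         reference_label = fit$adjustment$reference_label,
         fits = lapply(fit$adjustment$fits, function(f) {
           list(coefficients = as.list(f$coefficients),
                reference_mean = f$reference_mean)
         }))
  }
  pd <- unclass(fit$positional_density)
  payload <- list(
    specs = lapply(fit$specs, spec_to_list),
    adjustment = adj,
    models = lapply(fit$models, model_to_list),
    ml_sequence = fit$ml_sequence,
    ml_log_lik = fit$ml_log_lik,
    positional_density = list(events = rownames(pd),
                              matrix = unname(apply(pd, 1, identity,
                                                    simplify = FALSE)),
                              n_sets = attr(fit$positional_density, "n_sets")),
    meta = fit$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  specs <- lapply(j$specs, function(s) {
    s[vapply(s, is.null, logical(1))] <- NA_real_
    list_to_spec(s)
  })
  adjustment <- NULL
  if (!is.null(j$adjustment)) {
    fits <- lapply(j$adjustment$fits, function(f) {
      list(coefficients = unlist(f$coefficients),
           reference_mean = f$reference_mean)
    })
    adjustment <- structure(
      list(features = j$adjustment$features,
           covariates = j$adjustment$covariates,
           reference_label = j$adjustment$reference_label,
           fits = fits),
      class = "adjustment_model")
  }
  models <- lapply(j$models, list_to_model)
  pd <- do.call(rbind, lapply(j$positional_density$matrix, unlist))
  rownames(pd) <- j$positional_density$events
  colnames(pd) <- paste0("pos_", seq_len(ncol(pd)))
  pd <- structure(pd, class = c("positional_density", "matrix"),
                  n_sets = j$positional_density$n_sets)
  structure(
    list(models = models, ml_sequence = unlist(j$ml_sequence),
         ml_log_lik = j$ml_log_lik, positional_density = pd,
         specs = specs, adjustment = adjustment, meta = j$meta),
    class = "ebm_fit"
  )
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(
    list(true_sequence = truth$true_sequence,
         true_stage = as.list(truth$true_stage),
         true_hr_by_subgroup = as.list(truth$true_hr_by_subgroup),
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_sim_truth(j$true_sequence,
                setNames(as.integer(j$true_stage), names(j$true_stage)),
                feature_specs = NULL, seed = j$seed,
                true_hr_by_subgroup = unlist(j$true_hr_by_subgroup))
}

#' Export a positional density as a CSV matrix (events x positions)
#'
#' @param pd A `positional_density`.
#' @param path Output path.
#' @export
write_positional_density_csv <- function(pd, path) {
  m <- unclass(pd)
  df <- dplyr::bind_cols(tibble::tibble(event = rownames(m)),
                         tibble::as_tibble(m))
  readr::write_csv(df, path)
  invisible(path)
}
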