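#' Read and write population specifications as YAML
#'
#' @param spec a [population_spec()].
#' @param path file path.
#' @name population_io
NULL

#' @rdname population_io
#' @export
write_population_spec <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  out <- unclass(spec)
  out$latent_corr <- apply(out$latent_corr, 1, as.list)
  # named atomic vectors lose their names in YAML; write them as maps
  for (f in c("timing_base", "timing_sd", "timing_loadings", "bis_loadings"))
    out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname population_io
#' @export
read_population_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  r <- do.call(rbind, lapply(raw$latent_corr, unlist))
  nm <- names(raw$latent_corr)
  dimnames(r) <- list(nm, nm)
  population_spec(
    n_subjects = raw$n_subjects, latent_corr = r,
    base_log_threshold = raw$base_log_threshold, si_mean = raw$si_mean,
    ssc_sd = raw$ssc_sd, ssi_sd = raw$ssi_sd,
    mdd_noise_sd = raw$mdd_noise_sd,
    timing_base = unlist(raw$timing_base),
    timing_sd = unlist(raw$timing_sd),
    timing_loadings = unlist(raw$timing_loadings),
    bis_loadings = unlist(raw$bis_loadings),
    lapse_rate = raw$lapse_rate, motion_slope = raw$motion_slope,
    seed = raw$seed)
}

#' Write subject measures as tidy CSV
#'
#' @param measures a `subject_measures` data frame.
#' @param path file path.
#' @export
write_measures_csv <- function(measures, path) {
  utils::write.csv(as.data.frame(measures), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measures_csv
#' @export
read_measures_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("subject_measures", "data.frame")
  out
}

#' Write a long-format trial stream as CSV
#'
#' @param trials data frame with at least
#'   `subject_id, task, series_id, trial_index, level, response_correct`.
#' @param path file path.
#' @export
write_trials_csv <- function(trials, path) {
  need <- c("subject_id", "task", "series_id", "trial_index", "level",
            "response_correct")
  stopifnot(all(need %in% names(trials)))
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read or write a square covariance/correlation matrix as CSV
#'
#' The CSV has a header row and a leading name column.
#'
#' @param x square matrix.
#' @param path file path.
#' @name cov_csv
NULL

#' @rdname cov_csv
#' @export
write_cov_csv <- function(x, path) {
  utils::write.csv(data.frame(variable = rownames(x), x,
                              check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cov_csv
#' @export
read_cov_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  stopifnot(nrow(m) == ncol(m))
  m
}

#' Serialize a model fit as JSON
#'
#' @param fit a [fit_ml()] result.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sem_fit"))
  out <- list(
    estimates = as.list(fit$theta_hat),
    T = fit$T, df = fit$df, p_value = fit$p_value,
    cfi = fit$cfi, rmsea = fit$rmsea, srmr = fit$srmr, aic = fit$aic,
    F_ml = fit$F_ml, converged = fit$converged,
    standardized = lapply(fit$standardized, function(m)
      apply(m, 1, as.list)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a model specification as JSON
#'
#' Pattern cells are encoded as `"free"` or `"fixed:<value>"`.
#'
#' @param spec a [cov_model_spec()].
#' @param path file path.
#' @export
write_model_json <- function(spec, path) {
  enc <- function(m) apply(m, c(1, 2), function(v)
    if (is.na(v)) "free" else paste0("fixed:", format(v, digits = 12)))
  out <- list(obs_names = spec$obs_names, lat_names = spec$lat_names,
              lambda = enc(spec$lambda), beta = enc(spec$beta),
              psi = enc(spec$psi), theta = enc(spec$theta))
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(m) {
    out <- apply(m, c(1, 2), function(v)
      if (v == "free") NA_real_ else as.numeric(sub("^fixed:", "", v)))
    out
  }
  cov_model_spec(dec(raw$lambda), dec(raw$psi), dec(raw$theta),
                 dec(raw$beta), obs_names = raw$obs_names,
                 lat_names = raw$lat_names)
}
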