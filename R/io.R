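# Delimited-text and JSON input/output for datasets, summary tables, fit
# results, and study configuration files.

#' Write / read a trial-level dataset as delimited text
#'
#' Datasets are stored as comma-separated text with a header row, '.'
#' decimal separator, and UTF-8 encoding; columns `participant`,
#' `condition`, `rt`, `accuracy`, `contaminant`.  A bare two-column
#' `data.frame` of `rt`, `accuracy` (a single set of trials) round-trips the
#' same way.
#'
#' @param data The dataset `data.frame`.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the `data.frame`.
#' @export
write_dataset <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a summary-cell table as delimited text
#'
#' @param cells A [summarize_dataset()] result.
#' @param path File path.
#' @export
write_summaries <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Records the posterior summaries, convergence diagnostics, priors, seed,
#' and model tags -- everything needed to audit a fit without the draws.
#'
#' @param fit A [fit_model()] result.
#' @param path File path ending in `.json`.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "hez_fit"))
    stop_robez("'fit' must be a hez_fit object")
  obj <- list(summary = fit$summary,
              beta_mean = fit$beta_mean, beta_sd = fit$beta_sd,
              converged = fit$converged, max_rhat = fit$max_rhat,
              method = fit$spec$method, rt_scope = fit$spec$rt_scope,
              priors = fit$spec[c("mu_nu_prior", "beta_prior",
                                  "mu_alpha_prior", "mu_tau_prior",
                                  "sigma_nu_sd", "sigma_alpha_sd",
                                  "sigma_tau_sd")],
              mcmc = unclass(fit$mcmc), seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a study configuration file (YAML or JSON)
#'
#' Recognized keys mirror the arguments of [study_config()]; unknown keys
#' raise an error.  The file extension selects the parser (`.json` for
#' JSON, anything else is parsed as YAML, of which JSON is a subset).
#'
#' @param path Path to the configuration file.
#' @return A [study_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop_robez("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$mcmc)) raw$mcmc <- do.call(mcmc_control, raw$mcmc)
  do.call(study_config, raw)
}
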