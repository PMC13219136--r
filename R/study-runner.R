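# Factorial simulation-study orchestration: for each design cell (P, T,
# beta) and replicate, generate one clean dataset and its contaminated
# counterpart, fit the model under both summary methods, and record the
# evidence statistics and posterior summaries for all four
# integrity-by-method conditions.

#' Configure a simulation study
#'
#' The default configuration is a desk-scale study: a reduced grid with few
#' replicates that runs on one CPU in minutes.  The full factorial design
#' (`P` in 20/40/80/160, `T` in 20/40/80/160/320, `beta` in 0/0.1/0.2/0.4,
#' 1000 replicates per cell) uses the same code path but is cluster-scale.
#'
#' @param P,T,beta Numeric vectors of participant counts, trials per
#'   condition, and true effect sizes; the study runs their full cross.
#' @param preset Population preset, one of [study_presets()].
#' @param replicates Replicates per design cell (>= 1).
#' @param rate Contamination rate (default 0.05).
#' @param methods Summary methods to fit (default both).
#' @param rt_scope RT scope for summaries.  The default for study runs is
#'   `"all"`: with the signed drift ranges of the presets, accuracy can be
#'   near 0, which would leave correct-only cells empty.
#' @param mcmc An [mcmc_control()].
#' @param seed Master seed; every replicate derives its own stream from it.
#' @param stat Decision statistic recorded as `stat`
#'   (`"z_abs"` or `"savage_dickey_bf10"`; both are always stored).
#' @return A list of class `study_config`.
#' @export
study_config <- function(P = c(20, 40), T = c(20, 40), beta = c(0, 0.4),
                         preset = "main", replicates = 10, rate = 0.05,
                         methods = c("standard", "robust"),
                         rt_scope = "all",
                         mcmc = mcmc_control(chains = 2, adapt = 300,
                                             warmup = 300, draws = 500),
                         seed = 1, stat = "z_abs") {
  stopifnot(preset %in% study_presets())
  methods <- match.arg(methods, c("standard", "robust"), several.ok = TRUE)
  rt_scope <- match.arg(rt_scope, c("all", "correct_only"))
  stat <- match.arg(stat, c("z_abs", "savage_dickey_bf10"))
  replicates <- check_count(replicates, "replicates")
  check_scalar(rate, "rate", lower = 0, upper = 0.5)
  if (!inherits(mcmc, "mcmc_control")) mcmc <- do.call(mcmc_control, mcmc)
  structure(list(P = P, T = T, beta = beta, preset = preset,
                 replicates = replicates, rate = rate, methods = methods,
                 rt_scope = rt_scope, mcmc = mcmc,
                 seed = check_count(seed, "seed", min = 0L), stat = stat),
            class = "study_config")
}

#' Run one replicate of one design cell
#'
#' Draws a population and individuals, generates one clean dataset, builds
#' its contaminated counterpart (sharing the other 95% of trials), then
#' summarizes and fits every integrity-by-method combination.  All four
#' results share the same underlying truth.  The replicate's random stream
#' is derived deterministically from the master seed and the cell labels,
#' so any replicate can be reproduced in isolation and execution order does
#' not matter.
#'
#' @param config A [study_config()].
#' @param P,T,beta The design cell.
#' @param replicate Replicate id (>= 1).
#' @return A `data.frame` with one row per integrity-by-method condition:
#'   design labels, truth (`true_beta`, `true_mu_nu`, `true_mu_alpha`,
#'   `true_mu_tau`), posterior summaries (`beta_mean`, `beta_sd`,
#'   `mu_nu_mean`), evidence statistics (`stat_z`, `stat_bf10`, and `stat`,
#'   the configured one), and convergence flags.
#' @export
run_cell <- function(config, P, T, beta, replicate) {
  if (!inherits(config, "study_config"))
    stop_robez("'config' must be a study_config object")
  P <- check_count(P, "P")
  T <- check_count(T, "T")
  replicate <- check_count(replicate, "replicate")
  cell_seed <- derive_seed(config$seed, "cell", P, T, beta, config$preset,
                           replicate)
  set.seed(cell_seed)
  pop <- draw_population(config$preset, beta = beta)
  ind <- draw_individuals(pop, P)
  clean <- generate_dataset(ind, T)
  datasets <- list(clean = clean)
  if (config$rate > 0)
    datasets$contaminated <- contaminate(clean, ind, rate = config$rate)
  rows <- list()
  for (integrity in names(datasets)) {
    for (method in config$methods) {
      cells <- summarize_dataset(datasets[[integrity]], method = method,
                                 rt_scope = config$rt_scope)
      spec <- model_spec(method = method, rt_scope = config$rt_scope)
      model <- build_model(cells, spec)
      ft <- withCallingHandlers(
        fit_model(model, mcmc = config$mcmc,
                  seed = derive_seed(cell_seed, integrity, method)),
        warning = function(w) invokeRestart("muffleWarning"))
      z <- decision_statistic(ft, "z_abs")
      bf <- decision_statistic(ft, "savage_dickey_bf10")
      sm <- ft$summary
      rows[[length(rows) + 1L]] <- data.frame(
        P = P, T = T, beta = beta, preset = config$preset,
        replicate = replicate, integrity = integrity, method = method,
        true_beta = beta, true_mu_nu = pop$mu_nu,
        true_mu_alpha = pop$mu_alpha, true_mu_tau = pop$mu_tau,
        beta_mean = ft$beta_mean, beta_sd = ft$beta_sd,
        mu_nu_mean = sm$mean[sm$parameter == "mu_nu"],
        stat_z = z, stat_bf10 = bf,
        stat = if (config$stat == "z_abs") z else bf,
        converged = ft$converged, max_rhat = ft$max_rhat,
        seed = cell_seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run a full simulation study
#'
#' Crosses all design cells of the configuration with the replicate count,
#' runs [run_cell()] for each, and writes the raw per-dataset results, the
#' aggregated AUC/RMSE/bias tables, a JSON manifest (configuration echo,
#' seed, package and R versions), and a plain-text log to `outdir`.
#'
#' @param config A [study_config()].
#' @param outdir Output directory (created if missing).  If `NULL`, nothing
#'   is written and the results are only returned.
#' @param verbose Print progress lines.
#' @return Invisibly, a list with `results` (raw rows), `aggregate`
#'   (per-design-cell metrics), and `failures` (character vector of cells
#'   that errored; the run continues past individual failures).
#' @export
run_study <- function(config, outdir = NULL, verbose = FALSE) {
  if (!inherits(config, "study_config"))
    stop_robez("'config' must be a study_config object")
  grid <- expand.grid(P = config$P, T = config$T, beta = config$beta,
                      replicate = seq_len(config$replicates))
  all_rows <- vector("list", nrow(grid))
  failures <- character()
  log_lines <- character()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    label <- sprintf("P=%d T=%d beta=%g rep=%d", g$P, g$T, g$beta,
                     g$replicate)
    res <- try(run_cell(config, g$P, g$T, g$beta, g$replicate),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, paste0(label, ": ", attr(res, "condition")$message))
      log_lines <- c(log_lines, paste("FAIL", label))
    } else {
      all_rows[[i]] <- res
      log_lines <- c(log_lines, paste("ok  ", label))
    }
    if (verbose) message(log_lines[length(log_lines)])
  }
  results <- do.call(rbind, c(all_rows[!vapply(all_rows, is.null, TRUE)],
                              list(make.row.names = FALSE)))
  if (is.null(results) || !nrow(results))
    stop_robez("every cell of the study failed; first error: ",
               if (length(failures)) failures[1] else "none recorded")
  agg <- aggregate_results(results)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(outdir, "results.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(agg, file.path(outdir, "aggregate.csv"), row.names = FALSE,
              quote = FALSE)
    manifest <- list(config = unclass(config),
                     mcmc = unclass(config$mcmc),
                     n_results = nrow(results), failures = failures,
                     r_version = as.character(getRversion()),
                     package_version = as.character(packageVersion("robez")),
                     bias_convention = "estimate - truth; negative = underestimation")
    manifest$config$mcmc <- NULL
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(outdir, "run.log"))
  }
  invisible(list(results = results, aggregate = agg, failures = failures))
}

#' Aggregate raw study results into per-design-cell metrics
#'
#' For every (P, T, beta, integrity, method) combination, computes the AUC
#' of its evidence statistics against the matching `beta = 0` statistics
#' (same P, T, integrity, method; the `beta = 0` rows are compared against
#' themselves, making their AUC 0.5 by definition), plus the RMSE and bias
#' (estimate minus truth) of the posterior-mean effect size.
#'
#' @param results Raw rows as produced by [run_cell()] / [run_study()].
#' @return A `data.frame` with columns `P`, `T`, `beta`, `integrity`,
#'   `method`, `n`, `auc`, `rmse_beta`, `bias_beta`.
#' @export
aggregate_results <- function(results) {
  need <- c("P", "T", "beta", "integrity", "method", "stat", "beta_mean",
            "true_beta")
  if (!all(need %in% names(results)))
    stop_robez("'results' must have columns ", paste(need, collapse = ", "))
  groups <- unique(results[, c("P", "T", "beta", "integrity", "method")])
  groups <- groups[order(groups$P, groups$T, groups$beta, groups$integrity,
                         groups$method), ]
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sel <- results$P == g$P & results$T == g$T & results$beta == g$beta &
      results$integrity == g$integrity & results$method == g$method
    sub <- results[sel, ]
    null_sel <- results$P == g$P & results$T == g$T &
      results$beta == 0 & results$integrity == g$integrity &
      results$method == g$method
    auc <- if (any(null_sel)) {
      nulls <- results$stat[null_sel]
      alts <- if (g$beta == 0) nulls else sub$stat
      roc_auc(nulls, alts)$auc
    } else NA_real_
    rows[[i]] <- data.frame(P = g$P, T = g$T, beta = g$beta,
                            integrity = g$integrity, method = g$method,
                            n = nrow(sub), auc = auc,
                            rmse_beta = rmse(sub$beta_mean, sub$true_beta),
                            bias_beta = bias(sub$beta_mean, sub$true_beta),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
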