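# Diagnostic accuracy (ROC/AUC) and parameter-recovery metrics (RMSE, bias)
# over batches of simulation fits.

#' ROC curve and AUC from null and alternative evidence values
#'
#' Sweeps a decision threshold from maximally conservative to maximally
#' liberal over the pooled evidence values, recording the false-alarm rate
#' (proportion of null-data statistics at or above threshold) against the
#' detection rate (proportion of effect-data statistics at or above
#' threshold).  The area under the curve is computed by the rank
#' (Mann--Whitney) formulation with ties counted 1/2, which equals the
#' trapezoidal area under the swept curve.  An AUC of 0.5 means no
#' discrimination; comparing a set of statistics against itself gives 0.5
#' exactly.
#'
#' @param null_stats Evidence values from datasets generated with
#'   `beta = 0`.
#' @param alt_stats Evidence values from datasets generated with
#'   `beta != 0` (or the null set itself, by convention, for the
#'   `beta = 0` point of a summary curve).
#' @return An object of class `roc_result`: list with `points`
#'   (`data.frame` of `far`, `dr`, monotone from (0,0) to (1,1)) and `auc`.
#' @examples
#' roc_auc(c(1, 3), c(2, 4))$auc  # 0.75
#' @export
roc_auc <- function(null_stats, alt_stats) {
  null_stats <- as.numeric(null_stats)
  alt_stats <- as.numeric(alt_stats)
  if (!length(null_stats) || !length(alt_stats))
    stop_robez("both statistic sets must be nonempty")
  if (!all(is.finite(null_stats)) || !all(is.finite(alt_stats)))
    stop_robez("non-finite evidence statistics")
  thr <- c(Inf, sort(unique(c(null_stats, alt_stats)), decreasing = TRUE))
  far <- vapply(thr, function(t) mean(null_stats >= t), 0)
  dr <- vapply(thr, function(t) mean(alt_stats >= t), 0)
  n0 <- length(null_stats)
  n1 <- length(alt_stats)
  r <- rank(c(alt_stats, null_stats), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(points = data.frame(far = far, dr = dr), auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC with %d threshold points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Plot an ROC curve
#' @param x A [roc_auc()] result.
#' @param ... Passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$far, x$points$dr, type = "l",
       xlab = "False-alarm rate", ylab = "Detection rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Hanley-McNeil standard error of an AUC estimate (used only to judge
# whether two AUCs are within Monte-Carlo error of each other).
auc_se <- function(auc, n0, n1) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n0 * n1))
}

#' Root mean squared error of estimates against truth
#'
#' `sqrt(mean((estimate - truth)^2))`; combines bias and variability.
#'
#' @param estimates,truth Equal-length numeric vectors.
#' @return A nonnegative scalar.
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) != length(truth) || !length(estimates))
    stop_robez("'estimates' and 'truth' must have equal nonzero length")
  sqrt(mean((estimates - truth)^2))
}

#' Mean signed estimation error
#'
#' `mean(estimate - truth)`: negative values indicate underestimation.
#'
#' @inheritParams rmse
#' @return A signed scalar.
#' @export
bias <- function(estimates, truth) {
  if (length(estimates) != length(truth) || !length(estimates))
    stop_robez("'estimates' and 'truth' must have equal length")
  mean(estimates - truth)
}

#' Bin simulation results by the true population drift intercept
#'
#' Aggregates a batch of per-dataset results into equal-width bins of the
#' true `mu_nu`, reporting per bin the AUC of the binned effect-data
#' statistics against the pooled null statistics and the bias of the
#' posterior-mean `beta` and `mu_nu`.  Empty bins are reported with `NA`
#' values, never fabricated.
#'
#' @param results A `data.frame` with columns `true_beta`, `true_mu_nu`,
#'   `stat` (evidence value), `beta_mean`, and `mu_nu_mean` (e.g. rows of a
#'   [run_study()] result restricted to one integrity/method condition).
#' @param n_bins Number of equal-width bins (default 10).
#' @param range Length-2 numeric range of `mu_nu` to bin over; defaults to
#'   the range observed in `results`.
#' @return A `data.frame` with one row per bin: `bin`, `lower`, `upper`,
#'   `n`, `auc`, `bias_beta`, `bias_mu_nu`.
#' @export
bin_by_truth <- function(results, n_bins = 10, range = NULL) {
  n_bins <- check_count(n_bins, "n_bins")
  need <- c("true_beta", "true_mu_nu", "stat", "beta_mean", "mu_nu_mean")
  if (!all(need %in% names(results)))
    stop_robez("'results' must have columns ", paste(need, collapse = ", "))
  null_stats <- results$stat[results$true_beta == 0]
  alt <- results[results$true_beta != 0, ]
  if (is.null(range)) range <- base::range(results$true_mu_nu)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  out <- data.frame(bin = seq_len(n_bins), lower = edges[-(n_bins + 1L)],
                    upper = edges[-1L], n = NA_integer_, auc = NA_real_,
                    bias_beta = NA_real_, bias_mu_nu = NA_real_)
  idx <- findInterval(alt$true_mu_nu, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > n_bins] <- NA_integer_
  for (b in seq_len(n_bins)) {
    sub <- alt[!is.na(idx) & idx == b, ]
    out$n[b] <- nrow(sub)
    if (nrow(sub)) {
      if (length(null_stats))
        out$auc[b] <- roc_auc(null_stats, sub$stat)$auc
      out$bias_beta[b] <- bias(sub$beta_mean, sub$true_beta)
      out$bias_mu_nu[b] <- bias(sub$mu_nu_mean, sub$true_mu_nu)
    }
  }
  out
}
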