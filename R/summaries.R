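# Per-cell summary statistics.  The standard summaries are the sample mean
# and unbiased variance of RT; the robust summaries replace them with the
# median and the interquartile-range variance estimate
#   Var_IQR = ((Q3 - Q1) / 1.349)^2,
# which is consistent for the variance under normality because the IQR of
# N(0, 1) is 2 * qnorm(0.75) = 1.3490.  The accuracy statistic (count of
# correct responses) is identical under both methods.

# Normal-consistency divisor for the IQR scale estimate.
iqr_divisor <- function() 2 * qnorm(0.75)

cell_stats <- function(rt, method) {
  if (method == "standard") {
    list(loc = mean(rt), scale = var(rt))
  } else {
    q <- quantile(rt, c(0.25, 0.75), names = FALSE, type = 7)
    list(loc = median(rt), scale = ((q[2] - q[1]) / 1.349)^2)
  }
}

summaries_impl <- function(trials, method) {
  if (!is.data.frame(trials) || !all(c("rt", "accuracy") %in% names(trials)))
    stop_robez("'trials' must be a data.frame with columns rt and accuracy")
  n <- nrow(trials)
  if (n < 4L)
    stop_robez("at least 4 trials are required for cell summaries (got ",
               n, ")")
  st <- cell_stats(trials$rt, method)
  list(n = n, n_correct = sum(trials$accuracy == 1), loc = st$loc,
       scale = st$scale, method = method)
}

#' Standard summary statistics of one cell of trials
#'
#' @param trials A `data.frame` with columns `rt` and `accuracy` (>= 4 rows).
#' @return A list with `n`, `n_correct`, `loc` (mean RT), `scale` (unbiased
#'   sample variance of RT), `method`.
#' @examples
#' standard_summaries(data.frame(rt = 1:4, accuracy = c(1, 1, 0, 1)))
#' @export
standard_summaries <- function(trials) summaries_impl(trials, "standard")

#' Robust summary statistics of one cell of trials
#'
#' Location is the sample median; scale is `((Q3 - Q1)/1.349)^2`, the
#' squared normal-consistent IQR scale estimate.  Quartiles use linear
#' interpolation of order statistics (type-7 convention).
#'
#' @inheritParams standard_summaries
#' @return As [standard_summaries()], with `loc` the median and `scale` the
#'   IQR variance estimate.
#' @examples
#' robust_summaries(data.frame(rt = c(1, 2, 3, 4, 100), accuracy = rep(1, 5)))
#' @export
robust_summaries <- function(trials) summaries_impl(trials, "robust")

#' Summarize a dataset into per-cell summary statistics
#'
#' Computes one row of summary statistics per participant-by-condition cell.
#' RT location and scale are computed over the trials selected by
#' `rt_scope` (`"correct_only"`: trials with `accuracy == 1`, the classical
#' EZ convention; `"all"`: every trial), while `n_correct` and `n_total` are
#' always counted over all trials of the cell.
#'
#' @param data A dataset from [generate_dataset()] / [contaminate()], or any
#'   `data.frame` with columns `participant`, `condition`, `rt`, `accuracy`.
#' @param method `"standard"` or `"robust"`.
#' @param rt_scope `"correct_only"` (default) or `"all"`.
#' @return A `data.frame` of class `summary_cells` with columns
#'   `participant`, `condition`, `n` (RT count used), `n_total`,
#'   `n_correct`, `loc`, `scale`, `method`.
#' @export
summarize_dataset <- function(data, method = c("standard", "robust"),
                              rt_scope = c("correct_only", "all")) {
  method <- match.arg(method)
  rt_scope <- match.arg(rt_scope)
  need <- c("participant", "condition", "rt", "accuracy")
  if (!all(need %in% names(data)))
    stop_robez("'data' must have columns ", paste(need, collapse = ", "))
  parts <- sort(unique(data$participant))
  rows <- list()
  for (p in parts) {
    for (k in sort(unique(data$condition))) {
      cell <- data[data$participant == p & data$condition == k, ]
      n_total <- nrow(cell)
      n_correct <- sum(cell$accuracy == 1)
      sel <- if (rt_scope == "correct_only") cell$accuracy == 1 else
        rep(TRUE, n_total)
      if (sum(sel) < 4L)
        stop_robez(sprintf(
          "cell participant=%s condition=%s has %d usable trials (< 4) under rt_scope='%s'",
          p, k, sum(sel), rt_scope))
      st <- cell_stats(cell$rt[sel], method)
      rows[[length(rows) + 1L]] <-
        data.frame(participant = p, condition = k, n = sum(sel),
                   n_total = n_total, n_correct = n_correct, loc = st$loc,
                   scale = st$scale, method = method,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("summary_cells", "data.frame")
  out
}
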