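# Internal helpers: argument checking and deterministic seed derivation.

stop_robez <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_robez(sprintf("'%s' must be a single finite number", name))
  if (strict_lower && x <= lower)
    stop_robez(sprintf("'%s' must be > %g", name, lower))
  if (!strict_lower && x < lower)
    stop_robez(sprintf("'%s' must be >= %g", name, lower))
  if (x > upper)
    stop_robez(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    stop_robez(sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Mixes a master seed with an arbitrary sequence of labels (coerced to
#' character) through a multiplicative string hash, returning an integer in
#' `[1, 2^31 - 2]`.  Used by the study runner so that every
#' (cell, replicate) pair gets its own reproducible random stream that does
#' not depend on execution order.
#'
#' @param master Integer master seed.
#' @param ... Labels (numbers or strings) identifying the substream.
#' @return A single integer seed.
#' @examples
#' derive_seed(42, "cell", 20, 40, 0.4, "main", 3)
#' @export
derive_seed <- function(master, ...) {
  master <- check_count(master, "master", min = 0L)
  m <- 2147483629  # prime below 2^31; products stay exact in doubles
  h <- (master %% m) + 1
  for (lab in list(...)) {
    for (ch in utf8ToInt(paste0(format(lab, trim = TRUE), "|"))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h + 1)
}
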