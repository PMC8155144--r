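#' Percentile bootstrap confidence interval
#'
#' Case-resampling percentile interval: draws `B` resamples of the rows
#' (or elements) of `data` with replacement, evaluates `statistic` on
#' each, and reports the (1 - conf)/2 and 1 - (1 - conf)/2 quantiles.
#' Resamples on which the statistic is undefined (non-finite or an error)
#' are redrawn and counted. Deterministic under a fixed `seed`.
#'
#' @param data A vector or data frame.
#' @param statistic Function of a resample returning a scalar.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Optional seed for the resampling stream.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `estimate` (statistic on the full data),
#'   `conf.low`, `conf.high`, `B`, `conf`, `n_redrawn`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, seed = NULL, conf = 0.95) {
  run <- function() {
    n <- if (is.data.frame(data)) nrow(data) else length(data)
    if (n < 1) abort("`data` is empty.")
    take <- if (is.data.frame(data)) {
      function(idx) data[idx, , drop = FALSE]
    } else {
      function(idx) data[idx]
    }
    vals <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      for (try in 1:100) {
        v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (length(v) == 1 && is.finite(v)) break
        redrawn <- redrawn + 1L
        v <- NA_real_
      }
      if (is.na(v)) abort("statistic undefined on 100 consecutive resamples.")
      vals[b] <- v
    }
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(vals, c(alpha, 1 - alpha)))
    tibble(estimate = statistic(data), conf.low = ci[1], conf.high = ci[2],
           B = B, conf = conf, n_redrawn = redrawn)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
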