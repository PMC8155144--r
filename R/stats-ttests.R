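#' Two-sample t test between groups, tidied
#'
#' Pooled-variance Student's t test (the convention of the source
#' software family; `var_equal = FALSE` switches to Welch) comparing a
#' response between the two levels of a grouping column.
#'
#' @param data A data frame.
#' @param response,group Columns (tidy-eval); `group` must have exactly
#'   two observed levels.
#' @param var_equal Pool the variances (default TRUE).
#' @return One-row tibble: group labels and means, `estimate`
#'   (mean1 - mean2), `statistic`, `df`, `p.value`.
#' @export
t_test_groups <- function(data, response, group, var_equal = TRUE) {
  resp_col <- as_name(enquo(response))
  grp_col <- as_name(enquo(group))
  assert_cols(data, c(resp_col, grp_col), "`data`")
  d <- tibble(y = as.numeric(data[[resp_col]]),
              g = as.character(data[[grp_col]]))
  d <- d[complete.cases(d), ]
  levels <- sort(unique(d$g))
  if (length(levels) != 2) abort("`group` must have exactly two observed levels.")
  y1 <- d$y[d$g == levels[1]]
  y2 <- d$y[d$g == levels[2]]
  if (length(y1) < 2 || length(y2) < 2) abort("need n >= 2 per group.")
  if (sd(y1) == 0 && sd(y2) == 0) {
    abort("zero variance in both groups: t is undefined.",
          class = "glustress_zero_variance")
  }
  ht <- stats::t.test(y1, y2, var.equal = var_equal)
  tibble(group1 = levels[1], group2 = levels[2],
         mean1 = mean(y1), mean2 = mean(y2),
         estimate = mean(y1) - mean(y2),
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value,
         method = if (var_equal) "student" else "welch")
}

#' Paired t test, tidied
#'
#' Two-tailed paired t test on pre/post vectors. Identical vectors give
#' t = 0; constant nonzero differences (zero variance of the change with a
#' nonzero mean) are signalled as an error rather than reported as an
#' infinite t.
#'
#' @param pre,post Paired numeric vectors.
#' @return One-row tibble: `estimate` (mean change post - pre),
#'   `statistic`, `df`, `p.value`.
#' @export
t_test_paired <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must be paired.")
  ok <- complete.cases(pre, post)
  delta <- post[ok] - pre[ok]
  n <- length(delta)
  if (n < 2) abort("need at least 2 complete pairs.")
  if (sd(delta) == 0) {
    if (mean(delta) == 0) {
      return(tibble(estimate = 0, statistic = 0, df = n - 1L, p.value = 1))
    }
    abort("zero-variance change scores with nonzero mean: t is infinite.",
          class = "glustress_zero_variance")
  }
  ht <- stats::t.test(delta)
  tibble(estimate = mean(delta), statistic = unname(ht$statistic),
         df = unname(ht$parameter), p.value = ht$p.value)
}
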