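#' Test-retest intraclass correlation (two-way mixed, absolute agreement)
#'
#' Single-measure ICC under the two-way mixed model with absolute
#' agreement, McGraw & Wong's ICC(A,1):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, session and
#' error mean squares of the two-way layout. Absolute agreement penalizes
#' systematic session offsets, unlike the consistency ICC. The p-value
#' tests ICC = 0 via F = MS_R / MS_E on (n - 1, (n - 1)(k - 1)) degrees of
#' freedom.
#'
#' @param data Long table with one row per subject x session measurement.
#' @param subject,session,value Column names (tidy-eval) identifying the
#'   subject, the repeated session, and the measurement.
#' @return One-row tibble: `icc`, `statistic` (F), `df1`, `df2`, `p.value`,
#'   `n_subjects`, `n_sessions`.
#' @export
#' @examples
#' d <- tibble::tibble(subj = rep(1:6, 2), sess = rep(c("a", "b"), each = 6),
#'                     y = c(1:6, 1:6 + 0.1))
#' icc_agreement(d, subj, sess, y)
icc_agreement <- function(data, subject, session, value) {
  subject <- as_name(enquo(subject))
  session <- as_name(enquo(session))
  value <- as_name(enquo(value))
  assert_cols(data, c(subject, session, value), "`data`")

  wide <- tidyr::pivot_wider(as_tibble(data)[c(subject, session, value)],
                             names_from = dplyr::all_of(session),
                             values_from = dplyr::all_of(value))
  Y <- as.matrix(wide[-1])
  if (anyNA(Y)) abort("missing cells: every subject needs every session.")
  n <- nrow(Y)
  k <- ncol(Y)
  if (n < 3) abort("need at least 3 subjects.")
  if (k < 2) abort("need at least 2 sessions.")

  grand <- mean(Y)
  ms_r <- k * var(rowMeans(Y))
  ms_c <- n * var(colMeans(Y))
  ss_total <- sum((Y - grand)^2)
  ss_e <- ss_total - (n - 1) * ms_r - (k - 1) * ms_c
  ms_e <- ss_e / ((n - 1) * (k - 1))

  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  icc <- if (denom == 0) 1 else (ms_r - ms_e) / denom
  f <- if (ms_e == 0) Inf else ms_r / ms_e
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  tibble(icc = icc, statistic = f, df1 = df1, df2 = df2,
         p.value = pf(f, df1, df2, lower.tail = FALSE),
         n_subjects = n, n_sessions = k)
}
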