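#' Salivary cortisol percent change from the pre-stress baseline
#'
#' Scales each participant's cortisol series relative to the pre-stressor
#' timepoint: `100 * (c_t - c_pre) / c_pre`, so the pre timepoint maps to
#' exactly 0. Participants without a positive baseline or with a missing
#' timepoint are flagged unscorable rather than dropped. The result is
#' invariant to rescaling the whole series (a unit change leaves the
#' percent values untouched).
#'
#' @param data Long cortisol table: `id`, `timepoint`
#'   (`pre_mast`/`post1`/`post2`), `nmol_per_l`.
#' @return Tibble `id`, `timepoint`, `pct_change`, `scorable`.
#' @export
cortisol_percent_change <- function(data) {
  assert_cols(data, c("id", "timepoint", "nmol_per_l"), "`data`")
  tps <- c("pre_mast", "post1", "post2")
  bad <- setdiff(unique(data$timepoint), tps)
  if (length(bad)) {
    abort(sprintf("unknown cortisol timepoint(s): %s", paste(bad, collapse = ", ")))
  }
  as_tibble(data) |>
    group_by(.data$id) |>
    mutate(
      scorable = all(tps %in% .data$timepoint) &&
        !anyNA(.data$nmol_per_l) &&
        .data$nmol_per_l[.data$timepoint == "pre_mast"][1] > 0,
      pct_change = if_else(
        .data$scorable,
        100 * (.data$nmol_per_l -
                 .data$nmol_per_l[match("pre_mast", .data$timepoint)]) /
          .data$nmol_per_l[match("pre_mast", .data$timepoint)],
        NA_real_)
    ) |>
    ungroup() |>
    select("id", "timepoint", "pct_change", "scorable")
}

#' Negative-affect score from bipolar visual analogue mood scales
#'
#' Each 0-100 bipolar item carries a declared orientation: items whose
#' positive mood pole sits at the high end of the stored scale are
#' reflected (`100 - x`) so that higher always means more negative
#' emotional experience, then items are averaged per participant and
#' timepoint. The score is invariant to consistently relabeling an item's
#' stored polarity together with its declared orientation.
#'
#' @param data Long VAMS table: `id`, `timepoint`, `item`, `score` (0-100),
#'   `positive_pole` (`"high"` = positive mood at the high end of the
#'   stored score, `"low"` = positive mood at the low end).
#' @return Tibble `id`, `timepoint`, `neg_affect` (0-100).
#' @export
vams_negative_score <- function(data) {
  assert_cols(data, c("id", "timepoint", "item", "score", "positive_pole"),
              "`data`")
  bad <- setdiff(unique(data$positive_pole), c("high", "low"))
  if (length(bad)) {
    abort(sprintf("unknown item orientation(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(data$score < 0 | data$score > 100, na.rm = TRUE)) {
    abort("VAMS scores must lie in [0, 100].")
  }
  as_tibble(data) |>
    mutate(neg = if_else(.data$positive_pole == "high",
                         100 - .data$score, .data$score)) |>
    group_by(.data$id, .data$timepoint) |>
    summarise(neg_affect = mean(.data$neg), .groups = "drop")
}

#' Standardized mean change (paired effect size)
#'
#' The change-score standardized effect size
#' `d = mean(post - pre) / sd(post - pre)` (sample sd), the conventional
#' mean-change statistic for paired pre/post designs. A `"pre"`
#' standardizer (sd of the pre scores) is available as an alternative.
#' `d` is invariant to adding a constant to both vectors and antisymmetric
#' under negating the change scores.
#'
#' @param pre,post Paired numeric vectors of equal length (n >= 2).
#' @param standardizer `"change"` (default) or `"pre"`.
#' @return The effect size `d` (scalar).
#' @export
#' @examples
#' standardized_mean_change(c(0, 0, 0, 0), c(1, 1, 1, 3)) # 1.5
standardized_mean_change <- function(pre, post,
                                     standardizer = c("change", "pre")) {
  standardizer <- match.arg(standardizer)
  if (length(pre) != length(post)) abort("`pre` and `post` must be paired.")
  ok <- complete.cases(pre, post)
  pre <- pre[ok]
  post <- post[ok]
  if (length(pre) < 2) abort("need at least 2 complete pairs.")
  delta <- post - pre
  s <- if (standardizer == "change") sd(delta) else sd(pre)
  if (s == 0) {
    if (mean(delta) == 0) return(0)
    abort("standardizer sd is zero with nonzero mean change: d is undefined.")
  }
  mean(delta) / s
}
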