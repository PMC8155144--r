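#' Fit the healthy-control calibration law for glutamate change
#'
#' Ordinary least squares of percent-change glutamate on raw (uncentered)
#' PSS over the designated calibration sample only. The fitted line plays
#' the role of the expected glutamate response at a given level of recent
#' perceived stress; the published calibration is
#' `%dGlu_expected = 35.647 - 3.093 * PSS`. Residuals over the calibration
#' sample sum to zero by construction, so the mean maladaptive glutamate
#' response of the calibration sample is exactly 0.
#'
#' @param data Table holding the calibration sample.
#' @param pss,change Columns (tidy-eval) with the PSS scores and observed
#'   percent-change glutamate.
#' @param sample_label Optional label naming the calibration sample.
#' @return An object of class `glu_calibration` with elements `intercept`,
#'   `slope`, `n`, `sample_label` and the underlying `lm` fit. Supports
#'   [tidy()], [glance()], `print()` and [expected_change()].
#' @export
#' @examples
#' d <- tibble::tibble(pss = seq(0, 50, 5),
#'                     chg = 35.647 - 3.093 * seq(0, 50, 5))
#' fit_calibration(d, pss, chg)
fit_calibration <- function(data, pss = pss, change = pct_change_glu,
                            sample_label = NULL) {
  pss_col <- as_name(enquo(pss))
  chg_col <- as_name(enquo(change))
  assert_cols(data, c(pss_col, chg_col), "`data`")
  d <- tibble(pss = data[[pss_col]], change = data[[chg_col]])
  d <- d[complete.cases(d), ]
  if (nrow(d) < 3) abort("calibration needs at least 3 complete pairs.")
  if (sd(d$pss) == 0) abort("PSS is constant: the calibration slope is undefined.")
  fit <- lm(change ~ pss, data = d)
  structure(
    list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         n = nrow(d), sample_label = sample_label, fit = fit),
    class = "glu_calibration"
  )
}

#' @export
print.glu_calibration <- function(x, ...) {
  cat("Glutamate-change calibration (OLS on the calibration sample)\n")
  if (!is.null(x$sample_label)) cat("  sample:", x$sample_label, "\n")
  cat(sprintf("  expected %%dGlu = %.4f %+.4f * PSS   (n = %d)\n",
              x$intercept, x$slope, x$n))
  invisible(x)
}

#' @export
tidy.glu_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", "pss"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.glu_calibration <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, n = x$n,
         sample_label = x$sample_label %||% NA_character_)
}

#' Expected percent-change glutamate at a PSS level
#'
#' Evaluates the calibration line `intercept + slope * pss`.
#'
#' @param model A [fit_calibration()] object.
#' @param pss Numeric vector of PSS scores.
#' @return Numeric vector of expected percent changes.
#' @export
expected_change <- function(model, pss) {
  if (!inherits(model, "glu_calibration")) {
    abort("`model` must be a glu_calibration object.")
  }
  model$intercept + model$slope * pss
}

#' Maladaptive glutamate response
#'
#' The observed-minus-expected residual: positive values mean mPFC
#' glutamate rose more than the calibration law predicts at the subject's
#' perceived-stress level.
#'
#' @param observed,expected Percent-change vectors.
#' @return `observed - expected`.
#' @export
compute_mgr <- function(observed, expected) {
  observed - expected
}

#' Score maladaptive glutamate response out of sample
#'
#' Joins participants' PSS onto QC-passing metabolite changes and scores
#' `mgr = observed - expected` against a calibration model fitted elsewhere
#' (never on the scored subjects themselves; the calibration sample is
#' named in the pipeline config, so out-of-sample discipline is structural).
#'
#' @param changes Output of [score_metabolite_changes()] (uses `included`
#'   rows only).
#' @param participants Participant table with `id` and `pss`.
#' @param model A [fit_calibration()] object.
#' @return Tibble `id`, `pss`, `pct_change_glu_observed`,
#'   `pct_change_glu_expected`, `mgr`.
#' @export
score_mgr <- function(changes, participants, model) {
  assert_cols(changes, c("id", "pct_change_glu"), "`changes`")
  assert_cols(participants, c("id", "pss"), "`participants`")
  scored <- changes
  if ("included" %in% names(scored)) scored <- filter(scored, .data$included)
  scored |>
    select(-dplyr::any_of("pss")) |>
    inner_join(select(as_tibble(participants), "id", "pss"), by = "id") |>
    mutate(pct_change_glu_observed = .data$pct_change_glu,
           pct_change_glu_expected = expected_change(model, .data$pss),
           mgr = compute_mgr(.data$pct_change_glu_observed,
                             .data$pct_change_glu_expected)) |>
    select("id", "pss", "pct_change_glu_observed",
           "pct_change_glu_expected", "mgr")
}
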