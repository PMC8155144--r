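#' Percent change of a creatine-normalized metabolite ratio
#'
#' The pre-to-post percent change `100 * (post - pre) / pre`, the single
#' code path used for Glu/Cr, Glx/Cr and Cho/Cr alike. Values are carried
#' on the 0-100 percent scale.
#'
#' @param pre,post Positive ratio vectors (recycled to a common length).
#' @return Numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(0.80, 1.00) # 25
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    abort("`pre` must be strictly positive and finite.")
  }
  100 * (post - pre) / pre
}

#' Scan-quality thresholds
#'
#' The exclusion rules are strict inequalities: a scan fails if SNR < 9,
#' FWHM > 0.15 ppm, or glutamate CRLB > 20 percent; boundary values are
#' retained.
#'
#' @param snr_min Minimum acceptable signal-to-noise ratio.
#' @param fwhm_max Maximum acceptable full width at half maximum (ppm).
#' @param crlb_glu_max Maximum acceptable glutamate Cramer-Rao lower
#'   bound (percent).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snr_min = 9, fwhm_max = 0.15, crlb_glu_max = 20) {
  structure(list(snr_min = snr_min, fwhm_max = fwhm_max,
                 crlb_glu_max = crlb_glu_max),
            class = "qc_thresholds")
}

#' Flag per-scan quality failures
#'
#' Applies the strict-inequality quality rules to every scan record and
#' records each violated rule.
#'
#' @param scans Scan table with columns `snr`, `fwhm`, `crlb_glu`.
#' @param thresholds A [qc_thresholds()] object.
#' @return `scans` with logical `qc_pass` and a semicolon-delimited
#'   `qc_reasons` column (empty when passing).
#' @export
apply_scan_qc <- function(scans, thresholds = qc_thresholds()) {
  assert_cols(scans, c("snr", "fwhm", "crlb_glu"), "`scans`")
  if (anyNA(scans$snr) || anyNA(scans$fwhm) || anyNA(scans$crlb_glu)) {
    abort("quality fields (snr, fwhm, crlb_glu) must not be missing.")
  }
  fail_snr <- scans$snr < thresholds$snr_min
  fail_fwhm <- scans$fwhm > thresholds$fwhm_max
  fail_crlb <- scans$crlb_glu > thresholds$crlb_glu_max
  reasons <- purrr::pmap_chr(
    list(fail_snr, fail_fwhm, fail_crlb),
    function(s, f, c) join_reasons(if (s) "snr" else "",
                                   if (f) "fwhm" else "",
                                   if (c) "crlb_glu" else "")
  )
  mutate(as_tibble(scans),
         qc_pass = !(fail_snr | fail_fwhm | fail_crlb),
         qc_reasons = reasons)
}

#' Flag percent-change outliers
#'
#' Flags values more than `k` sample standard deviations from the mean of
#' the non-missing values. With zero spread nothing is flagged.
#'
#' @param changes Table of metabolite changes.
#' @param metric Name of the column to screen (default `pct_change_glu`).
#' @param k Threshold in standard deviations (default 3).
#' @return `changes` with an added logical `outlier` column (FALSE for
#'   missing values).
#' @export
flag_change_outliers <- function(changes, metric = "pct_change_glu", k = 3) {
  assert_cols(changes, metric, "`changes`")
  x <- changes[[metric]]
  ok <- is.finite(x)
  if (sum(ok) < 2) abort("need at least 2 finite values to screen outliers.")
  m <- mean(x[ok])
  s <- sd(x[ok])
  out <- rep(FALSE, length(x))
  if (s > 0) out[ok] <- abs(x[ok] - m) > k * s
  mutate(as_tibble(changes), outlier = out)
}

#' Score metabolite percent changes with QC and outlier exclusions
#'
#' For each participant with one `pre` and one `post` scan, computes the
#' percent change in Glu/Cr, Glx/Cr and Cho/Cr through the single
#' [percent_change()] code path, applies the per-scan quality rules (a
#' participant fails if either session fails), and flags glutamate-change
#' outliers beyond `outlier_sd` standard deviations among the QC-passing
#' participants. Percent-change fields are reported only for participants
#' whose both sessions pass QC.
#'
#' @param scans Scan table (`id`, `session`, `glu_cr`, `glx_cr`, `cho_cr`,
#'   `snr`, `fwhm`, `crlb_glu`).
#' @param thresholds A [qc_thresholds()] object.
#' @param outlier_sd Outlier threshold in standard deviations (3 by
#'   default); `NULL` disables outlier screening.
#' @return Tibble with one row per participant: `id`, the three
#'   `pct_change_*` columns (NA when QC fails), `qc_pass`, `outlier`,
#'   `included` (QC pass and not an outlier) and semicolon-delimited
#'   `exclusion_reasons`.
#' @export
score_metabolite_changes <- function(scans, thresholds = qc_thresholds(),
                                     outlier_sd = 3) {
  assert_cols(scans, c("id", "session", "glu_cr", "glx_cr", "cho_cr"),
              "`scans`")
  bad_session <- setdiff(unique(scans$session), c("pre", "post"))
  if (length(bad_session)) {
    abort(sprintf("unknown session label(s): %s",
                  paste(bad_session, collapse = ", ")))
  }
  dup <- scans |>
    count(.data$id, .data$session) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicated session record(s) for id(s): %s",
                  paste(unique(dup$id), collapse = ", ")))
  }
  if (any(scans$glu_cr <= 0 | scans$glx_cr <= 0 | scans$cho_cr <= 0)) {
    abort("metabolite ratios must be strictly positive.")
  }

  flagged <- apply_scan_qc(scans, thresholds)
  per_scan <- flagged |>
    select("id", "session", "glu_cr", "glx_cr", "cho_cr",
           "qc_pass", "qc_reasons")
  wide <- tidyr::pivot_wider(per_scan, id_cols = "id",
                             names_from = "session",
                             values_from = c("glu_cr", "glx_cr", "cho_cr",
                                             "qc_pass", "qc_reasons"))
  for (col in c("glu_cr_pre", "glu_cr_post", "qc_pass_pre", "qc_pass_post")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }

  has_both <- !is.na(wide$qc_pass_pre) & !is.na(wide$qc_pass_post)
  qc_pass <- has_both & wide$qc_pass_pre & wide$qc_pass_post
  reasons <- purrr::pmap_chr(
    list(has_both,
         wide$qc_reasons_pre %||% "", wide$qc_reasons_post %||% ""),
    function(both, rp, ro) {
      if (!both) return("missing_session")
      labs <- unique(unlist(strsplit(c(rp, ro), ";", fixed = TRUE)))
      join_reasons(labs)
    }
  )

  pct_of <- function(metric) {
    pre <- wide[[paste0(metric, "_pre")]]
    post <- wide[[paste0(metric, "_post")]]
    out <- rep(NA_real_, nrow(wide))
    ok <- qc_pass & !is.na(pre) & !is.na(post)
    out[ok] <- percent_change(pre[ok], post[ok])
    out
  }
  changes <- tibble(
    id = wide$id,
    pct_change_glu = pct_of("glu_cr"),
    pct_change_glx = pct_of("glx_cr"),
    pct_change_cho = pct_of("cho_cr"),
    qc_pass = qc_pass,
    exclusion_reasons = reasons
  )

  if (!is.null(outlier_sd) && sum(is.finite(changes$pct_change_glu)) >= 2) {
    changes <- flag_change_outliers(changes, "pct_change_glu", k = outlier_sd)
  } else {
    changes$outlier <- FALSE
  }
  changes |>
    mutate(
      included = .data$qc_pass & !.data$outlier,
      exclusion_reasons = purrr::map2_chr(
        .data$exclusion_reasons, .data$outlier,
        function(r, o) join_reasons(r, if (o) "glu_change_outlier" else "")
      )
    )
}
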