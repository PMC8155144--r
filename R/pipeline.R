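#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the generator (or
#' externally read) inputs, the name of the calibration sample, scan-QC
#' thresholds, the glutamate-change outlier rule, EMA validity rules and
#' the usable-survey inclusion floor, and the bootstrap size for partial
#' correlation intervals.
#'
#' @param generator A [cohort_config()] used when no input tables are
#'   supplied (its seed drives every stochastic step).
#' @param calibration_group Group label fitted by [fit_calibration()];
#'   all other stress-condition groups are scored out of sample.
#' @param qc A [qc_thresholds()] object.
#' @param ema_rules An [ema_filter_rules()] object.
#' @param outlier_sd Glutamate-change outlier threshold (sd units).
#' @param min_usable_surveys EMA inclusion floor (valid surveys).
#' @param bootstrap_B Bootstrap resamples for partial-correlation CIs
#'   (NULL disables the intervals).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            calibration_group = "hc_stress_calibration",
                            qc = qc_thresholds(),
                            ema_rules = ema_filter_rules(),
                            outlier_sd = 3,
                            min_usable_surveys = 20,
                            bootstrap_B = NULL) {
  if (!inherits(generator, "cohort_config")) {
    abort("`generator` must be built by cohort_config().")
  }
  if (!calibration_group %in% generator$groups) {
    abort("`calibration_group` must name one of the generator's groups.")
  }
  structure(list(generator = generator, calibration_group = calibration_group,
                 qc = qc, ema_rules = ema_rules, outlier_sd = outlier_sd,
                 min_usable_surveys = min_usable_surveys,
                 bootstrap_B = bootstrap_B),
            class = "pipeline_config")
}

one_way_anova <- function(data, response, group) {
  d <- tibble(y = as.numeric(data[[response]]), g = factor(data[[group]]))
  d <- d[complete.cases(d), ]
  an <- anova(lm(y ~ g, data = d))
  tibble(effect = group, df1 = an$Df[1], df2 = an$Df[2],
         statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1])
}

safe_row <- function(expr) {
  tryCatch(expr, error = function(e) tibble(error = conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates, in fixed order, scan QC and percent-change scoring,
#' glutamate-change outlier screening, calibration of the PSS law on the
#' designated calibration sample, out-of-sample MGR scoring, EMA filtering
#' and summarization, and the full statistical battery: manipulation
#' checks (VAMS and cortisol repeated-measures ANOVAs, post-scan rating
#' comparisons), per-group PSS-metabolite Spearman correlations,
#' moderation and quadratic regressions, EMA group comparisons, MGR
#' partial correlations and the Steiger comparison of the pessimistic
#' versus optimistic associations. Identical config (and seed) gives an
#' identical report.
#'
#' @param config A [pipeline_config()] object.
#' @param data Optional named list of input tables (`participants`,
#'   `scans`, `cortisol`, `vams`, optionally `ema_surveys`); when NULL
#'   everything is generated from `config$generator`. When `ema_surveys`
#'   is absent the EMA stream is generated from the scored MGR values.
#' @return Object of class `glu_stress_report`; see
#'   [write_report_json()] for serialization.
#' @export
run_analysis <- function(config = pipeline_config(), data = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be built by pipeline_config().")
  }
  if (is.null(data)) data <- generate_cohort(config$generator)
  for (nm in c("participants", "scans", "cortisol", "vams")) {
    if (is.null(data[[nm]])) abort(sprintf("input table `%s` is missing.", nm))
  }
  participants <- as_tibble(data$participants)
  if (nrow(participants) == 0) {
    abort("empty analyzable sample: no participants.",
          class = "glustress_empty_sample")
  }
  ledger <- list()
  note_exclusions <- function(stage, ids, reasons) {
    if (length(ids)) {
      ledger[[length(ledger) + 1L]] <<- tibble(stage = stage, id = ids,
                                               reason = reasons)
    }
  }

  # --- stage 1: scan QC, percent change, outliers -------------------------
  changes <- score_metabolite_changes(data$scans, config$qc, config$outlier_sd)
  excl <- filter(changes, !.data$included)
  note_exclusions("mrs_qc", excl$id, excl$exclusion_reasons)
  analyzed <- changes |>
    filter(.data$included) |>
    inner_join(participants, by = "id")
  if (nrow(analyzed) == 0) {
    abort("empty analyzable sample after QC.", class = "glustress_empty_sample")
  }

  # --- stage 2: calibration and out-of-sample MGR -------------------------
  cal <- filter(analyzed, .data$group == config$calibration_group)
  if (nrow(cal) < 3) {
    abort("calibration sample has fewer than 3 usable participants.",
          class = "glustress_empty_sample")
  }
  calibration <- fit_calibration(cal, pss, pct_change_glu,
                                 sample_label = config$calibration_group)
  mgr_targets <- filter(analyzed,
                        .data$condition == "stress",
                        .data$group != config$calibration_group)
  mgr_tbl <- score_mgr(mgr_targets, participants, calibration)

  # --- stage 3: EMA -------------------------------------------------------
  surveys <- data$ema_surveys
  if (is.null(surveys) && nrow(mgr_tbl) > 0) {
    surveys <- generate_ema_streams(participants,
                                    select(mgr_tbl, "id", "mgr"),
                                    config$generator)
  }
  ema <- NULL
  if (!is.null(surveys) && nrow(surveys) > 0) {
    filtered <- filter_surveys(surveys, config$ema_rules)
    pairs <- build_matched_pairs(filtered)
    summaries <- summarize_ema(filtered, pairs, config$min_usable_surveys)
    dropped <- filter(summaries, !.data$included)
    note_exclusions("ema_inclusion", dropped$id,
                    rep("fewer_than_min_usable_surveys", nrow(dropped)))
    ema <- list(filtered = filtered, pairs = pairs, summaries = summaries)
  }

  # --- stage 4: statistics ------------------------------------------------
  group3 <- function(g) dplyr::case_when(g == "nsc" ~ "nsc",
                                         g == "mdd" ~ "mdd",
                                         TRUE ~ "hc_stress")

  vams_scores <- vams_negative_score(data$vams) |>
    inner_join(select(participants, "id", "group"), by = "id") |>
    mutate(group3 = group3(.data$group))
  vams_complete <- vams_scores |>
    group_by(.data$id) |>
    filter(dplyr::n_distinct(.data$timepoint) == 4) |>
    ungroup()
  vams_anova <- safe_row(tidy(rm_anova_gg(vams_complete, id, timepoint,
                                          neg_affect, between = group3)))

  cort_pct <- cortisol_percent_change(data$cortisol) |>
    filter(.data$scorable) |>
    inner_join(select(participants, "id", "group", "condition"), by = "id") |>
    mutate(group3 = group3(.data$group))
  cort_anova <- safe_row(tidy(rm_anova_gg(cort_pct, id, timepoint,
                                          pct_change, between = group3)))
  cort_wide <- data$cortisol |>
    tidyr::pivot_wider(id_cols = "id", names_from = "timepoint",
                       values_from = "nmol_per_l") |>
    inner_join(select(participants, "id", "condition"), by = "id")
  stress_wide <- filter(cort_wide, .data$condition == "stress",
                        complete.cases(.data$pre_mast, .data$post1))
  nsc_wide <- filter(cort_wide, .data$condition == "no_stress",
                     complete.cases(.data$pre_mast, .data$post1))
  cortisol_d <- if (nrow(stress_wide) >= 2) {
    standardized_mean_change(stress_wide$pre_mast, stress_wide$post1)
  } else NA_real_
  manipulation <- list(
    vams_anova = vams_anova,
    cortisol_anova = cort_anova,
    cortisol_d = cortisol_d,
    cortisol_t_stress = safe_row(t_test_paired(stress_wide$pre_mast,
                                               stress_wide$post1)),
    cortisol_t_nsc = safe_row(t_test_paired(nsc_wide$pre_mast,
                                            nsc_wide$post1)),
    ratings = purrr::map_dfr(
      c("rating_stress", "rating_unpleasant", "rating_difficulty"),
      function(v) {
        mutate(one_way_anova(mutate(participants, g3 = group3(.data$group)),
                             v, "g3"),
               rating = v, .before = 1)
      })
  )

  spearman_by_group <- tidyr::expand_grid(
    group = unique(analyzed$group),
    metric = c("pct_change_glu", "pct_change_glx", "pct_change_cho")
  ) |>
    purrr::pmap(function(group, metric) {
      d <- analyzed[analyzed$group == group, ]
      res <- safe_row(cor_spearman(d, pss, !!rlang::sym(metric)))
      mutate(res, group = group, metric = metric, .before = 1)
    }) |>
    bind_rows()

  hc_all <- analyzed |>
    filter(.data$group %in% c("hc_stress_calibration", "hc_stress_replication",
                              "nsc")) |>
    mutate(acute_stress = .data$condition == "stress")
  stress_all <- analyzed |>
    filter(.data$condition == "stress") |>
    mutate(mdd_group = .data$group == "mdd")
  metabolites <- list(
    spearman = spearman_by_group,
    interaction_acute = safe_row(glance(hierarchical_regression(
      hc_all, pct_change_glu,
      block1 = c("pss", "acute_stress"),
      block2 = c("site", "age", "sex", "pss:acute_stress")))),
    interaction_acute_terms = safe_row(tidy(hierarchical_regression(
      hc_all, pct_change_glu,
      block1 = c("pss", "acute_stress"),
      block2 = c("site", "age", "sex", "pss:acute_stress")))),
    interaction_mdd = safe_row(glance(hierarchical_regression(
      stress_all, pct_change_glu,
      block1 = c("pss", "mdd_group"),
      block2 = c("age", "sex", "site", "pss:mdd_group")))),
    cho_control = safe_row(glance(hierarchical_regression(
      hc_all, pct_change_cho,
      block1 = c("pss", "acute_stress"),
      block2 = c("site", "age", "sex", "pss:acute_stress")))),
    quadratic = safe_row(quadratic_term_model(stress_all, pct_change_glu, pss)),
    baseline_age = safe_row({
      base <- data$scans |>
        filter(.data$session == "pre") |>
        inner_join(select(participants, "id", "age"), by = "id")
      cor_partial(base, glu_cr, age)
    })
  )

  ema_stats <- NULL
  if (!is.null(ema)) {
    esum <- ema$summaries |>
      filter(.data$included) |>
      inner_join(select(participants, "id", "group", "age", "sex"), by = "id") |>
      mutate(diag = if_else(.data$group == "mdd", "mdd", "hc"))
    ema_vars <- c("expected_outcome", "experienced_outcome", "inaccuracy",
                  "pessimistic_mean", "optimistic_mean", "prop_accurate",
                  "prop_pessimistic", "prop_optimistic", "pos_affect",
                  "neg_affect")
    group_comp <- purrr::map_dfr(ema_vars, function(v) {
      mutate(safe_row(t_test_groups(esum, !!rlang::sym(v), diag)),
             variable = v, .before = 1)
    })
    with_mgr <- inner_join(esum, mgr_tbl[c("id", "mgr")], by = "id")
    partials <- purrr::map_dfr(ema_vars, function(v) {
      res <- safe_row(cor_partial(with_mgr, mgr, !!rlang::sym(v),
                                  covariates = c("age", "sex", "diag"),
                                  boot_B = config$bootstrap_B,
                                  boot_seed = config$generator$seed + 2L))
      mutate(res, variable = v, .before = 1)
    })
    steiger <- safe_row({
      both <- with_mgr[complete.cases(with_mgr[c("mgr", "pessimistic_mean",
                                                 "optimistic_mean", "age",
                                                 "sex", "diag")]), ]
      Z <- model.matrix(~ age + sex + diag, data = both)
      rx <- stats::lm.fit(Z, both$mgr)$residuals
      ry <- stats::lm.fit(Z, both$pessimistic_mean)$residuals
      rz <- stats::lm.fit(Z, both$optimistic_mean)$residuals
      steiger_z(cor(rx, ry), cor(rx, rz), cor(ry, rz), nrow(both))
    })
    ema_stats <- list(group_comparisons = group_comp,
                      mgr_partials = partials,
                      steiger_pess_vs_opt = steiger)
  }

  structure(
    list(
      seed = config$generator$seed,
      calibration_group = config$calibration_group,
      n_input = nrow(participants),
      manipulation = manipulation,
      metabolites = metabolites,
      calibration = list(intercept = calibration$intercept,
                         slope = calibration$slope,
                         n = calibration$n,
                         sample_label = calibration$sample_label),
      mgr = mgr_tbl,
      ema = ema_stats,
      data = list(participants = participants, changes = changes,
                  mgr = mgr_tbl,
                  ema_summaries = if (is.null(ema)) NULL else ema$summaries,
                  ema_pairs = if (is.null(ema)) NULL else ema$pairs),
      exclusions = if (length(ledger)) bind_rows(ledger) else
        tibble(stage = character(), id = character(), reason = character())
    ),
    class = "glu_stress_report"
  )
}

#' @export
print.glu_stress_report <- function(x, ...) {
  cat("Acute-stress glutamate analysis report\n")
  cat(sprintf("  participants: %d (seed %s); exclusions ledgered: %d\n",
              x$n_input, format(x$seed), nrow(x$exclusions)))
  cat(sprintf("  calibration (%s, n = %d): expected %%dGlu = %.3f %+.3f * PSS\n",
              x$calibration$sample_label, x$calibration$n,
              x$calibration$intercept, x$calibration$slope))
  cat("  PSS-metabolite Spearman correlations:\n")
  print(x$metabolites$spearman)
  if (!is.null(x$ema)) {
    cat("  MGR partial correlations with EMA variables:\n")
    print(x$ema$mgr_partials)
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes every statistic of the report (tibbles become arrays of
#' row-objects) so the result set round-trips without loss of any
#' statistic or degrees of freedom.
#'
#' @param report A [run_analysis()] report.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- unclass(report)
  payload$data <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", POSIXt = "ISO8601")
  invisible(path)
}
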