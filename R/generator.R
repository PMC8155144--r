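#' Generate a synthetic acute-stress MRS cohort
#'
#' Draws a full cohort with the statistical structure the downstream
#' analysis assumes: participants with group, site, age, sex and PSS;
#' paired pre/post MRS scan records whose implied percent-change glutamate
#' follows `multiplier * (intercept + slope * PSS) + noise`; salivary
#' cortisol series that rise after the stressor only in the stress
#' condition; and four-timepoint mood (VAMS) series peaking in negativity
#' after the stressor in the stress condition. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @return A named list of tibbles: `participants`, `scans`, `cortisol`,
#'   `vams` (schemas match the CSV interfaces of [write_cohort()]).
#' @seealso [generate_ema_streams()], [write_cohort()]
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be built by cohort_config().")
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  prefix <- c(hc_stress_calibration = "cal", hc_stress_replication = "rep",
              nsc = "nsc", mdd = "mdd")
  participants <- vector("list", length(cfg$groups))
  scans <- vector("list", length(cfg$groups))
  cortisol <- vector("list", length(cfg$groups))
  vams <- vector("list", length(cfg$groups))

  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[gi]
    n <- cfg$n[[g]]
    id <- sprintf("%s_%03d", prefix[[g]], seq_len(n))
    condition <- if (g == "nsc") "no_stress" else "stress"
    site <- if (g == "hc_stress_calibration") "mclean" else "emory"

    # age and baseline Glu/Cr share a Gaussian copula with target correlation
    rho <- cfg$age_glu_cor
    z_age <- rnorm(n)
    z_glu <- rho * z_age + sqrt(1 - rho^2) * rnorm(n)
    age <- round(clamp(cfg$age_mean[[g]] + cfg$age_sd[[g]] * z_age,
                       cfg$age_range[1], cfg$age_range[2]))
    sex <- if_else(runif(n) < cfg$pct_female[[g]] / 100, "F", "M")
    pss <- round(rnorm(n, cfg$pss_mean[[g]], cfg$pss_sd[[g]]))
    if (cfg$clip_pss) pss <- clamp(pss, 0, 40)

    rating_mean <- if (condition == "stress") cfg$rating_stress_mean else cfg$rating_nsc_mean
    rating <- function(shift) grid_round(rnorm(n, rating_mean + shift, 0.7), 1, 5)
    strain_acute <- if (site == "emory") stats::rpois(n, 5) else NA_integer_
    strain_chronic <- if (site == "emory") stats::rpois(n, 4) else NA_integer_

    participants[[gi]] <- tibble(
      id = id, group = g, condition = condition, site = site,
      age = age, sex = sex, pss = pss,
      rating_stress = rating(0),
      rating_unpleasant = rating(0.2),
      rating_difficulty = rating(-0.2),
      strain_acute_count = strain_acute,
      strain_chronic_count = strain_chronic
    )

    # metabolite changes: the generating law, exactly invertible via Eq.-1 scoring
    mult <- cfg$slope_multiplier[[g]]
    pct_glu <- mult * (cfg$calibration_intercept + cfg$calibration_slope * pss) +
      rnorm(n, 0, cfg$residual_sd)
    pct_glx <- pct_glu + rnorm(n, 0, cfg$glx_change_sd)
    pct_cho <- rnorm(n, 0, cfg$cho_change_sd)
    pre_glu <- pmax(cfg$baseline_glu_mean + cfg$baseline_glu_sd * z_glu, 0.05)
    pre_glx <- pmax(rnorm(n, cfg$baseline_glx_mean, cfg$baseline_glx_sd), 0.05)
    pre_cho <- pmax(rnorm(n, cfg$baseline_cho_mean, cfg$baseline_cho_sd), 0.01)

    qmetrics <- function() {
      tibble(snr = pmax(rnorm(n, cfg$snr_mean, cfg$snr_sd), 0.5),
             fwhm = pmax(rnorm(n, cfg$fwhm_mean, cfg$fwhm_sd), 0.005),
             crlb_glu = pmax(rnorm(n, cfg$crlb_mean, cfg$crlb_sd), 0.5))
    }
    pre_q <- qmetrics()
    post_q <- qmetrics()
    sc <- bind_rows(
      tibble(id = id, session = "pre",
             glu_cr = pre_glu, glx_cr = pre_glx, cho_cr = pre_cho, pre_q),
      tibble(id = id, session = "post",
             glu_cr = pmax(pre_glu * (1 + pct_glu / 100), 1e-6),
             glx_cr = pmax(pre_glx * (1 + pct_glx / 100), 1e-6),
             cho_cr = pmax(pre_cho * (1 + pct_cho / 100), 1e-6),
             post_q)
    )
    if (cfg$qc_fail_fraction > 0) {
      n_bad <- round(cfg$qc_fail_fraction * nrow(sc))
      if (n_bad > 0) {
        bad <- sample.int(nrow(sc), n_bad)
        mode <- sample(c("snr", "fwhm", "crlb"), n_bad, replace = TRUE)
        sc$snr[bad[mode == "snr"]] <- runif(sum(mode == "snr"), 5, 8.9)
        sc$fwhm[bad[mode == "fwhm"]] <- runif(sum(mode == "fwhm"), 0.16, 0.25)
        sc$crlb_glu[bad[mode == "crlb"]] <- runif(sum(mode == "crlb"), 21, 40)
      }
    }
    scans[[gi]] <- sc

    # cortisol: percent rise applied to a log-normal baseline
    pre_c <- stats::rlnorm(n, log(cfg$cortisol_baseline_mean), 0.35)
    if (condition == "stress") {
      rise1 <- cfg$cortisol_peak_rise + rnorm(n, 0, cfg$cortisol_noise_sd)
      rise2 <- cfg$cortisol_peak_rise * cfg$cortisol_decay +
        rnorm(n, 0, cfg$cortisol_noise_sd)
    } else {
      rise1 <- cfg$cortisol_nsc_rise + rnorm(n, 0, cfg$cortisol_noise_sd)
      rise2 <- cfg$cortisol_nsc_rise + rnorm(n, 0, cfg$cortisol_noise_sd)
    }
    cortisol[[gi]] <- tibble(
      id = rep(id, 3),
      timepoint = rep(c("pre_mast", "post1", "post2"), each = n),
      nmol_per_l = pmax(c(pre_c, pre_c * (1 + rise1 / 100),
                          pre_c * (1 + rise2 / 100)), 0)
    )

    # VAMS: negativity trajectory, stored under mixed item polarities
    items <- c("happy_sad", "relaxed_tense", "friendly_hostile",
               "sociable_withdrawn", "quick_witted_slow")
    poles <- c(happy_sad = "low", relaxed_tense = "low",
               friendly_hostile = "high", sociable_withdrawn = "high",
               quick_witted_slow = "low")
    tp_offset <- if (condition == "stress") {
      c(0, 2, cfg$vams_amplitude, -2)
    } else {
      c(0, -2, -4, -8)
    }
    base_i <- cfg$vams_baseline +
      (if (g == "mdd") cfg$vams_mdd_shift else 0) + rnorm(n, 0, 5)
    # shared subject-by-timepoint deviation: items of one administration move together
    tp_dev <- matrix(rnorm(n * 4, 0, cfg$vams_tp_noise_sd), n, 4)
    grid <- tidyr::expand_grid(idx = seq_len(n), timepoint = 1:4, item = items)
    negativity <- clamp(base_i[grid$idx] + tp_offset[grid$timepoint] +
                          tp_dev[cbind(grid$idx, grid$timepoint)] +
                          rnorm(nrow(grid), 0, cfg$vams_noise_sd), 0, 100)
    pole <- poles[grid$item]
    vams[[gi]] <- tibble(
      id = id[grid$idx], timepoint = grid$timepoint, item = grid$item,
      score = if_else(pole == "high", 100 - negativity, negativity),
      positive_pole = unname(pole)
    )
  }

  list(participants = bind_rows(participants),
       scans = bind_rows(scans),
       cortisol = bind_rows(cortisol),
       vams = bind_rows(vams))
}

#' Generate synthetic EMA survey streams coupled to MGR
#'
#' Emulates the follow-up ecological momentary assessment: six surveys on
#' every other day over a four-week window, with timestamps, 1-5 affect
#' items, a -4..+4 planned-activity expectation, a happened flag and a
#' -4..+4 experienced outcome. The subject-level mean shift of
#' (outcome - expectation) is coupled to the supplied maladaptive glutamate
#' response values with strength `config$ema$coupling`, so pessimistic
#' expectation scoring can recover the coupling. A configurable fraction of
#' surveys is corrupted with labeled validity violations for filter testing.
#'
#' @param participants Participant table (needs `id` and `group`).
#' @param mgr Tibble with columns `id` and `mgr`; every id must appear in
#'   `participants`.
#' @param config A [cohort_config()] (its `ema` component and `seed` are
#'   used; the EMA stream is drawn from seed + 1 so it is independent of
#'   the cohort draw).
#' @return A tibble of survey records (one row per sent survey) with a
#'   `corruption` label column (NA for clean rows).
#' @export
generate_ema_streams <- function(participants, mgr, config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be built by cohort_config().")
  }
  assert_cols(participants, c("id", "group"), "`participants`")
  assert_cols(mgr, c("id", "mgr"), "`mgr`")
  unknown <- setdiff(mgr$id, participants$id)
  if (length(unknown)) {
    abort(sprintf("unknown participant id(s) in `mgr`: %s",
                  paste(unknown, collapse = ", ")))
  }
  with_seed(config$seed + 1L, generate_ema_impl(participants, mgr, config$ema))
}

generate_ema_impl <- function(participants, mgr, ec) {
  n <- nrow(mgr)
  grp <- participants$group[match(mgr$id, participants$id)]
  affect_grp <- if_else(grp == "mdd", "mdd", "hc")
  # standardize MGR within diagnostic group: the coupled pessimism signal is
  # the within-group variation (group itself is partialled out on recovery)
  mgr_z <- numeric(n)
  for (gv in unique(affect_grp)) {
    idx <- affect_grp == gv
    v <- mgr$mgr[idx]
    mgr_z[idx] <- if (length(v) > 1 && sd(v) > 0) (v - mean(v)) / sd(v) else 0
  }
  z <- ec$coupling * mgr_z + sqrt(1 - ec$coupling^2) * rnorm(n)
  shift <- ec$delta_base + ec$delta_scale * z
  re_pos <- rnorm(n, 0, 0.4)
  re_neg <- rnorm(n, 0, 0.4)

  dates <- as.Date("2024-03-01") + 2L * (seq_len(ec$days) - 1L)
  slots <- seq_len(ec$surveys_per_day)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    grid <- tidyr::expand_grid(date = dates, schedule_index = slots)
    m <- nrow(grid)
    sent <- as.POSIXct(paste0(grid$date, " 10:00:00"), tz = "UTC") +
      (grid$schedule_index - 1L) * 7200
    done <- runif(m) < ec$completion_prob
    # whole-second timestamps (survey platforms log at second resolution)
    started <- sent + round(runif(m, 30, 600))
    completed <- started + round(runif(m, 60, 300))
    started[!done] <- NA
    completed[!done] <- NA

    pa <- ec$pos_affect_mean[[affect_grp[i]]] + re_pos[i]
    na_ <- ec$neg_affect_mean[[affect_grp[i]]] + re_neg[i]
    affect <- function(mu) {
      x <- grid_round(rnorm(m, mu, ec$affect_sd), 1, 5)
      x[!done] <- NA
      x
    }
    expectation <- grid_round(rnorm(m, ec$expectation_mean[[affect_grp[i]]],
                                    ec$expectation_sd), -4, 4)
    expectation[!done] <- NA

    # outcome references the previous completed survey of the same day
    happened <- rep(NA, m)
    outcome <- rep(NA_real_, m)
    for (d in unique(grid$date)) {
      idx <- which(grid$date == d & done)
      if (!length(idx)) next
      happened[idx[1]] <- FALSE
      for (k in seq_along(idx)[-1]) {
        j <- idx[k]
        happened[j] <- runif(1) < ec$happened_prob
        if (happened[j]) {
          delta <- if (runif(1) < ec$accurate_mass) 0 else
            round(shift[i] + rnorm(1, 0, ec$delta_noise_sd))
          outcome[j] <- clamp(expectation[idx[k - 1]] + delta, -4, 4)
        }
      }
    }

    out[[i]] <- tibble(
      id = mgr$id[i], date = grid$date, schedule_index = grid$schedule_index,
      sent_at = sent, started_at = started, completed_at = completed,
      enthusiastic = affect(pa), cheerful = affect(pa), relaxed = affect(pa),
      irritable = affect(na_), anxious = affect(na_), sad = affect(na_),
      expectation = expectation, happened = happened, outcome = outcome,
      corruption = NA_character_
    )
  }
  surveys <- bind_rows(out)

  if (ec$invalid_fraction > 0) {
    surveys <- corrupt_surveys(surveys, ec$invalid_fraction)
  }
  arrange(surveys, .data$id, .data$date, .data$schedule_index)
}

# Inject labeled validity violations into completed surveys so the
# downstream filter's exclusion reasons can be asserted exactly. At most one
# survey per participant-day is corrupted, so corruptions never interact
# through the spacing anchor and every label maps to a deterministic reason.
corrupt_surveys <- function(surveys, fraction) {
  done_idx <- which(!is.na(surveys$completed_at))
  n_bad <- round(fraction * length(done_idx))
  if (n_bad == 0) return(surveys)
  day_key <- paste(surveys$id, surveys$date)
  days <- sample(unique(day_key[done_idx]))
  taken <- 0L
  for (dk in days) {
    if (taken >= n_bad) break
    rows <- done_idx[day_key[done_idx] == dk]
    type <- sample(c("too_fast", "too_late", "beyond_sixth", "off_schedule",
                     "incomplete"), 1)
    if (type == "off_schedule" && length(rows) < 2) type <- "too_fast"
    j <- if (type == "off_schedule") rows[length(rows)] else sample(rows, 1)
    if (type == "too_fast") {
      surveys$completed_at[j] <- surveys$started_at[j] + 10
    } else if (type == "too_late") {
      surveys$started_at[j] <- surveys$sent_at[j] + 24.5 * 3600
      surveys$completed_at[j] <- surveys$sent_at[j] + 25 * 3600
    } else if (type == "beyond_sixth") {
      surveys$schedule_index[j] <- 7L
    } else if (type == "off_schedule") {
      anchor <- max(surveys$completed_at[setdiff(rows, j)])
      surveys$completed_at[j] <- anchor + 1800
      surveys$started_at[j] <- surveys$completed_at[j] - 120
    } else {
      surveys$completed_at[j] <- as.POSIXct(NA)
      surveys$expectation[j] <- NA
    }
    surveys$corruption[j] <- type
    taken <- taken + 1L
  }
  surveys
}
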