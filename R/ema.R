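#' EMA survey validity rules
#'
#' A survey is invalid if it is incomplete, extends beyond the sixth survey
#' of the day, was completed in under 30 seconds or more than 24 hours
#' after delivery, or was not completed within 1 to 3 hours after the
#' previous valid survey of the same day. Completion duration is measured
#' start-to-completion; the 24-hour staleness bound is measured
#' send-to-completion; the spacing rule compares consecutive completion
#' times within a day with inclusive bounds, treating invalid surveys as
#' transparent.
#'
#' @param min_duration_s Minimum active filling time, seconds.
#' @param max_latency_s Maximum send-to-completion time, seconds.
#' @param spacing_s Two-element inclusive window (seconds) for the gap to
#'   the previous valid completion of the same day.
#' @param max_daily_index Highest allowed within-day schedule index.
#' @return A list of class `ema_filter_rules`.
#' @export
ema_filter_rules <- function(min_duration_s = 30,
                             max_latency_s = 24 * 3600,
                             spacing_s = c(3600, 3 * 3600),
                             max_daily_index = 6) {
  if (length(spacing_s) != 2 || spacing_s[1] > spacing_s[2]) {
    abort("`spacing_s` must be an increasing two-element window.")
  }
  structure(list(min_duration_s = min_duration_s,
                 max_latency_s = max_latency_s,
                 spacing_s = spacing_s,
                 max_daily_index = max_daily_index),
            class = "ema_filter_rules")
}

ema_response_cols <- c("enthusiastic", "cheerful", "relaxed",
                       "irritable", "anxious", "sad", "expectation")

#' Filter EMA surveys by the validity rules
#'
#' Flags every survey with all violated rules: `incomplete` (missing
#' completion or missing required responses), `beyond_sixth`, `too_fast`,
#' `too_late`, `spacing`, and `bad_timestamp` for unparseable timestamps
#' (flagged, never silently dropped). The spacing rule walks each
#' participant-day in completion order and compares each otherwise-eligible
#' survey to the most recent survey that passed all rules, so invalid
#' surveys neither anchor the window nor accumulate a spacing reason on
#' top of their own violations, and filtering is idempotent.
#'
#' @param surveys Survey table (see [generate_ema_streams()] for the
#'   schema).
#' @param rules An [ema_filter_rules()] object.
#' @return `surveys` with logical `valid` and semicolon-delimited
#'   `invalid_reasons` columns.
#' @export
filter_surveys <- function(surveys, rules = ema_filter_rules()) {
  assert_cols(surveys, c("id", "date", "schedule_index", "sent_at",
                         "started_at", "completed_at", ema_response_cols,
                         "happened"), "`surveys`")
  s <- as_tibble(surveys)
  n <- nrow(s)

  parse_ts <- function(x, nm) {
    if (inherits(x, "POSIXct")) {
      list(t = x, bad = rep(FALSE, n))
    } else {
      # per-element parsing: one bad string must not poison the others
      chr <- as.character(x)
      parsed <- as.POSIXct(strptime(chr, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
      miss <- is.na(parsed) & !is.na(chr)
      if (any(miss)) {
        parsed[miss] <- as.POSIXct(strptime(chr[miss], "%Y-%m-%d %H:%M:%OS",
                                            tz = "UTC"))
      }
      list(t = parsed, bad = !is.na(chr) & is.na(parsed))
    }
  }
  sent <- parse_ts(s$sent_at, "sent_at")
  started <- parse_ts(s$started_at, "started_at")
  completed <- parse_ts(s$completed_at, "completed_at")
  bad_ts <- sent$bad | started$bad | completed$bad

  resp <- as.matrix(s[ema_response_cols])
  incomplete <- is.na(completed$t) | apply(is.na(resp), 1, any) |
    is.na(s$happened) |
    (!is.na(s$happened) & s$happened & is.na(s$outcome))
  beyond <- !is.na(s$schedule_index) & s$schedule_index > rules$max_daily_index
  duration <- as.numeric(completed$t - started$t, units = "secs")
  too_fast <- !is.na(duration) & duration < rules$min_duration_s
  latency <- as.numeric(completed$t - sent$t, units = "secs")
  too_late <- !is.na(latency) & latency > rules$max_latency_s

  spacing <- rep(FALSE, n)
  valid <- rep(FALSE, n)
  base_invalid <- bad_ts | incomplete | beyond | too_fast | too_late
  ord <- order(s$id, s$date, completed$t, s$schedule_index)
  anchor <- as.POSIXct(NA)
  cur_key <- ""
  for (j in ord) {
    key <- paste(s$id[j], s$date[j])
    if (key != cur_key) {
      cur_key <- key
      anchor <- as.POSIXct(NA)
    }
    if (is.na(completed$t[j]) || base_invalid[j]) next
    ok <- TRUE
    if (!is.na(anchor)) {
      gap <- as.numeric(completed$t[j] - anchor, units = "secs")
      if (gap < rules$spacing_s[1] || gap > rules$spacing_s[2]) {
        spacing[j] <- TRUE
        ok <- FALSE
      }
    }
    if (ok) {
      valid[j] <- TRUE
      anchor <- completed$t[j]
    }
  }

  reasons <- purrr::pmap_chr(
    list(bad_ts, incomplete, beyond, too_fast, too_late, spacing),
    function(b, i, x, f, l, sp) {
      join_reasons(if (b) "bad_timestamp" else "",
                   if (i) "incomplete" else "",
                   if (x) "beyond_sixth" else "",
                   if (f) "too_fast" else "",
                   if (l) "too_late" else "",
                   if (sp) "spacing" else "")
    }
  )
  mutate(s, valid = valid, invalid_reasons = reasons)
}

#' Classify an expectation-outcome delta
#'
#' `accurate` when the outcome equals the expectation, `pessimistic` when
#' the outcome exceeded the expectation (the expectation was worse than
#' what happened), `optimistic` when the outcome fell short of it.
#'
#' @param delta Numeric vector of `outcome - expectation`.
#' @return Character vector of class labels.
#' @export
classify_delta <- function(delta) {
  dplyr::case_when(delta > 0 ~ "pessimistic",
                   delta < 0 ~ "optimistic",
                   delta == 0 ~ "accurate")
}

#' Build expectation-outcome matched pairs
#'
#' For each valid survey after the first valid survey of its day that
#' reports its last planned activity as having happened, pairs the reported
#' outcome with the expectation recorded at the immediately preceding valid
#' survey (invalid surveys are transparent). First-of-day outcomes and
#' not-happened surveys contribute no pair.
#'
#' @param surveys A survey table already passed through [filter_surveys()]
#'   (must carry the `valid` column).
#' @return Tibble `id`, `date`, `expectation`, `outcome`, `delta`, `class`.
#' @export
build_matched_pairs <- function(surveys) {
  if (!"valid" %in% names(surveys)) {
    abort("`surveys` must carry a `valid` column; run filter_surveys() first.")
  }
  as_tibble(surveys) |>
    filter(.data$valid) |>
    group_by(.data$id, .data$date) |>
    arrange(.data$completed_at, .by_group = TRUE) |>
    mutate(prev_expectation = lag(.data$expectation),
           rank_in_day = row_number()) |>
    ungroup() |>
    filter(.data$rank_in_day > 1,
           .data$happened %in% TRUE,
           !is.na(.data$outcome),
           !is.na(.data$prev_expectation)) |>
    mutate(expectation = .data$prev_expectation,
           delta = .data$outcome - .data$expectation,
           class = classify_delta(.data$delta)) |>
    select("id", "date", "expectation", "outcome", "delta", "class")
}

#' Per-participant EMA summary
#'
#' Computes, per participant, the daily-life expectation variables:
#' usable-survey count, mean expected outcome (all valid surveys), mean
#' experienced outcome and mean absolute expectation inaccuracy (happened
#' pairs), signed directional means over pessimistic and optimistic pairs
#' (absent -- NA, not zero -- when a class has no pairs), class
#' proportions over all pairs, mean positive and negative affect, and the
#' inclusion flag (at least `min_usable` valid surveys).
#'
#' @param surveys Output of [filter_surveys()].
#' @param pairs Output of [build_matched_pairs()].
#' @param min_usable Minimum number of valid surveys for inclusion
#'   (default 20; "less than 20" excludes).
#' @return One row per participant with at least one valid survey.
#' @export
summarize_ema <- function(surveys, pairs, min_usable = 20) {
  if (!"valid" %in% names(surveys)) {
    abort("`surveys` must carry a `valid` column; run filter_surveys() first.")
  }
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

  per_survey <- as_tibble(surveys) |>
    filter(.data$valid) |>
    group_by(.data$id) |>
    summarise(
      n_valid = n(),
      expected_outcome = mean(.data$expectation),
      pos_affect = mean(c(.data$enthusiastic, .data$cheerful, .data$relaxed)),
      neg_affect = mean(c(.data$irritable, .data$anxious, .data$sad)),
      .groups = "drop"
    )
  per_pair <- as_tibble(pairs) |>
    group_by(.data$id) |>
    summarise(
      n_pairs = n(),
      experienced_outcome = mean(.data$outcome),
      inaccuracy = mean(abs(.data$delta)),
      pessimistic_mean = mean_or_na(.data$delta[.data$delta > 0]),
      optimistic_mean = mean_or_na(.data$delta[.data$delta < 0]),
      prop_accurate = mean(.data$class == "accurate"),
      prop_pessimistic = mean(.data$class == "pessimistic"),
      prop_optimistic = mean(.data$class == "optimistic"),
      .groups = "drop"
    )
  per_survey |>
    left_join(per_pair, by = "id") |>
    mutate(n_pairs = if_else(is.na(.data$n_pairs), 0L, .data$n_pairs),
           included = .data$n_valid >= min_usable)
}
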