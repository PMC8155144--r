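# Small configs and hand-built fixtures shared across tests.

small_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed,
                n = c(hc_stress_calibration = 12L, hc_stress_replication = 10L,
                      nsc = 8L, mdd = 10L),
                ...)
}

ts <- function(x) as.POSIXct(x, tz = "UTC")

# Hand-scored EMA fixture: participant "p" has 12 surveys over two active
# days covering every filter violation type and all three pair classes;
# participant "q" has only an accurate pair (directional means absent).
#
# Hand scoring for "p":
#   day 1: S1 idx1 E=2 valid (first of day);
#          S2 idx2 E=-1 valid, outcome 3 pairs with S1 (delta +1, pessimistic);
#          S3 idx3 completed in 25 s -> too_fast;
#          S4 idx4 E=1 valid, outcome -3 pairs with S2 (delta -2, optimistic);
#          S5 idx5 E=0 valid, outcome 1 pairs with S4 (delta 0, accurate);
#          S6 idx7 -> beyond_sixth;
#          S7 idx6 completed 3 h 32 min after S5 -> spacing.
#   day 2: S8 idx1 completed 25 h after send -> too_late;
#          S9 idx2 never completed -> incomplete;
#          S10 idx3 E=-2 valid, happened with outcome 2 but it is the first
#              valid survey of the day -> no pair;
#          S11 idx4 E=4 valid, happened = no -> no pair;
#          S12 idx5 E=0 valid, outcome 4 pairs with S11 (delta 0, accurate).
# Valid surveys: 7. Pair deltas {+1, -2, 0, 0}.
#   expected_outcome  = mean(2, -1, 1, 0, -2, 4, 0) = 4/7
#   experienced_outcome = mean(3, -3, 1, 4) = 5/4
#   inaccuracy        = mean(1, 2, 0, 0) = 3/4
#   pessimistic_mean  = +1 ; optimistic_mean = -2
#   proportions       = accurate 1/2, pessimistic 1/4, optimistic 1/4
#   pos_affect = 4, neg_affect = 2 (all items constant)
ema_hand_fixture <- function() {
  row <- function(id, date, idx, sent, started, completed, E, happened, O) {
    tibble::tibble(
      id = id, date = as.Date(date), schedule_index = idx,
      sent_at = ts(paste(date, sent)),
      started_at = if (is.na(started)) ts(NA) else ts(started),
      completed_at = if (is.na(completed)) ts(NA) else ts(completed),
      enthusiastic = 4, cheerful = 4, relaxed = 4,
      irritable = 2, anxious = 2, sad = 2,
      expectation = E, happened = happened, outcome = O)
  }
  d1 <- "2024-03-01"
  d2 <- "2024-03-03"
  p <- dplyr::bind_rows(
    row("p", d1, 1, "10:00:00", paste(d1, "10:05:00"), paste(d1, "10:08:00"), 2, FALSE, NA),
    row("p", d1, 2, "12:00:00", paste(d1, "12:04:00"), paste(d1, "12:06:00"), -1, TRUE, 3),
    row("p", d1, 3, "14:00:00", paste(d1, "14:02:00"), paste(d1, "14:02:25"), 0, TRUE, 0),
    row("p", d1, 4, "14:30:00", paste(d1, "14:58:00"), paste(d1, "15:02:00"), 1, TRUE, -3),
    row("p", d1, 5, "16:00:00", paste(d1, "16:30:00"), paste(d1, "16:33:00"), 0, TRUE, 1),
    row("p", d1, 7, "18:00:00", paste(d1, "18:03:00"), paste(d1, "18:05:00"), 2, TRUE, 2),
    row("p", d1, 6, "20:00:00", paste(d1, "20:02:00"), paste(d1, "20:05:00"), 3, TRUE, 2),
    row("p", d2, 1, "10:00:00", paste(d2, "10:05:00"), "2024-03-04 11:00:00", 1, TRUE, 1),
    row("p", d2, 2, "12:00:00", NA, NA, NA, NA, NA),
    row("p", d2, 3, "14:00:00", paste(d2, "14:02:00"), paste(d2, "14:05:00"), -2, TRUE, 2),
    row("p", d2, 4, "16:00:00", paste(d2, "16:00:30"), paste(d2, "16:04:00"), 4, FALSE, NA),
    row("p", d2, 5, "18:00:00", paste(d2, "18:01:00"), paste(d2, "18:03:00"), 0, TRUE, 4)
  )
  q <- dplyr::bind_rows(
    row("q", d1, 1, "10:00:00", paste(d1, "10:02:00"), paste(d1, "10:05:00"), 1, FALSE, NA),
    row("q", d1, 2, "12:00:00", paste(d1, "12:02:00"), paste(d1, "12:05:00"), 0, TRUE, 1)
  )
  dplyr::bind_rows(p, q)
}

# expected per-participant summary for "p" under min_usable = 7
ema_hand_expected <- list(
  n_valid = 7L,
  expected_outcome = 4 / 7,
  experienced_outcome = 5 / 4,
  inaccuracy = 3 / 4,
  pessimistic_mean = 1,
  optimistic_mean = -2,
  prop_accurate = 1 / 2,
  prop_pessimistic = 1 / 4,
  prop_optimistic = 1 / 4,
  pos_affect = 4,
  neg_affect = 2
)
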