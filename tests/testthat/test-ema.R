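test_that("each validity rule fires with its own reason", {
  f <- filter_surveys(ema_hand_fixture())
  p <- dplyr::filter(f, id == "p")
  expect_equal(sum(p$valid), 7)
  reason_of <- function(idx, day) {
    p$invalid_reasons[p$schedule_index == idx & p$date == as.Date(day)]
  }
  expect_equal(reason_of(3, "2024-03-01"), "too_fast")
  expect_equal(reason_of(7, "2024-03-01"), "beyond_sixth")
  expect_equal(reason_of(6, "2024-03-01"), "spacing")
  expect_equal(reason_of(1, "2024-03-03"), "too_late")
  expect_equal(reason_of(2, "2024-03-03"), "incomplete")
  # a 2-h gap with a 120-s duration at index 3 is valid
  expect_true(p$valid[p$schedule_index == 4 & p$date == as.Date("2024-03-01")])
})

test_that("unparseable timestamps are flagged, not dropped", {
  s <- ema_hand_fixture() |>
    dplyr::mutate(dplyr::across(c(sent_at, started_at, completed_at),
                                ~ format(.x, "%Y-%m-%dT%H:%M:%S")))
  # corrupt a row that is already invalid so downstream verdicts are untouched
  s$completed_at[3] <- "not-a-time"
  f <- filter_surveys(s)
  expect_equal(nrow(f), nrow(s))
  expect_match(f$invalid_reasons[3], "bad_timestamp")
  # ISO strings otherwise parse to the same verdicts as POSIXct input
  f2 <- filter_surveys(ema_hand_fixture())
  expect_equal(f$valid[-3], f2$valid[-3])
})

test_that("filtering is idempotent", {
  f <- filter_surveys(ema_hand_fixture())
  kept <- dplyr::filter(f, valid)
  again <- filter_surveys(kept[names(ema_hand_fixture())])
  expect_true(all(again$valid))
})

test_that("pairing walks valid surveys with invalid ones transparent", {
  f <- filter_surveys(ema_hand_fixture())
  pairs <- build_matched_pairs(f)
  p <- dplyr::filter(pairs, id == "p")
  expect_equal(nrow(p), 4)
  expect_equal(p$delta, c(1, -2, 0, 0))
  expect_equal(p$class, c("pessimistic", "optimistic", "accurate", "accurate"))
  # S4's outcome is paired with S2's expectation: S3 (invalid) is skipped
  expect_equal(p$expectation[2], -1)
  expect_error(build_matched_pairs(ema_hand_fixture()), "filter_surveys")
})

test_that("delta classification is the exact trichotomy", {
  expect_equal(classify_delta(c(4, -4, 0, 1e-9)),
               c("pessimistic", "optimistic", "accurate", "pessimistic"))
  # E = -1, O = 3 is a pessimistic pair with delta +4
  expect_equal(classify_delta(3 - (-1)), "pessimistic")
  expect_equal(classify_delta(0 - 4), "optimistic")
})

test_that("the hand-scored fixture reproduces every summary field exactly", {
  f <- filter_surveys(ema_hand_fixture())
  s <- summarize_ema(f, build_matched_pairs(f), min_usable = 7)
  p <- dplyr::filter(s, id == "p")
  exp <- ema_hand_expected
  for (nm in names(exp)) expect_equal(p[[nm]], exp[[nm]], label = nm)
  expect_true(p$included)
  # directional means are absent, not zero, when a class is empty
  q <- dplyr::filter(s, id == "q")
  expect_true(is.na(q$pessimistic_mean))
  expect_true(is.na(q$optimistic_mean))
  expect_equal(q$prop_accurate, 1)
})

test_that("pair deltas {+4, 0, -4} summarize per the variable definitions", {
  pairs <- tibble::tibble(id = "p", date = as.Date("2024-03-01"),
                          expectation = c(-1, 2, 4), outcome = c(3, 2, 0),
                          delta = c(4, 0, -4),
                          class = classify_delta(c(4, 0, -4)))
  surveys <- dplyr::filter(filter_surveys(ema_hand_fixture()), id == "p")
  s <- summarize_ema(surveys, pairs, min_usable = 1)
  expect_equal(s$inaccuracy, 8 / 3)
  expect_equal(s$pessimistic_mean, 4)
  expect_equal(s$optimistic_mean, -4)
  expect_equal(s$prop_accurate, 1 / 3)
  expect_equal(s$prop_pessimistic, 1 / 3)
  expect_equal(s$prop_optimistic, 1 / 3)
})

test_that("inclusion threshold counts valid surveys with a hard boundary", {
  mk <- function(n_valid) {
    days <- ceiling(n_valid / 6)
    rows <- purrr::map(seq_len(n_valid), function(i) {
      day <- as.Date("2024-03-01") + 2 * ((i - 1) %/% 6)
      idx <- ((i - 1) %% 6) + 1
      sent <- as.POSIXct(paste(day, "08:00:00"), tz = "UTC") + idx * 7200
      tibble::tibble(id = "x", date = day, schedule_index = idx,
                     sent_at = sent, started_at = sent + 60,
                     completed_at = sent + 240,
                     enthusiastic = 3, cheerful = 3, relaxed = 3,
                     irritable = 2, anxious = 2, sad = 2,
                     expectation = 0, happened = FALSE, outcome = NA_real_)
    })
    filter_surveys(dplyr::bind_rows(rows))
  }
  f19 <- mk(19)
  f20 <- mk(20)
  expect_true(all(f19$valid))
  expect_false(summarize_ema(f19, build_matched_pairs(f19))$included)
  expect_true(summarize_ema(f20, build_matched_pairs(f20))$included)
})

test_that("proportions and the inaccuracy decomposition hold on generated streams", {
  cfg <- small_config(seed = 21, ema = ema_config(invalid_fraction = 0.1))
  parts <- tibble::tibble(id = sprintf("s%02d", 1:12),
                          group = rep(c("mdd", "hc_stress_replication"), 6))
  mgr <- tibble::tibble(id = parts$id, mgr = withr::with_seed(21, rnorm(12, 0, 20)))
  f <- filter_surveys(generate_ema_streams(parts, mgr, cfg))
  pairs <- build_matched_pairs(f)
  s <- summarize_ema(f, pairs)
  with_pairs <- dplyr::filter(s, n_pairs > 0)
  expect_equal(with_pairs$prop_accurate + with_pairs$prop_pessimistic +
                 with_pairs$prop_optimistic,
               rep(1, nrow(with_pairs)))
  # mean |delta| = p_pess * mean(delta | pess) - p_opt * mean(delta | opt)
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  recon <- zero_na(with_pairs$prop_pessimistic * with_pairs$pessimistic_mean) -
    zero_na(with_pairs$prop_optimistic * with_pairs$optimistic_mean)
  expect_equal(with_pairs$inaccuracy, recon, tolerance = 1e-12)
})
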