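test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(small_config(seed = 12))))
})

test_that("generated tables respect instrument ranges and schema", {
  cohort <- generate_cohort(small_config(seed = 2, clip_pss = TRUE))
  p <- cohort$participants
  expect_true(all(p$pss >= 0 & p$pss <= 40))
  expect_true(all(p$age >= 18 & p$age <= 60))
  expect_true(all(p$sex %in% c("F", "M")))
  expect_true(all(p$rating_stress %in% 1:5))
  expect_true(all(cohort$scans$glu_cr > 0))
  expect_setequal(unique(cohort$scans$session), c("pre", "post"))
  expect_true(all(cohort$vams$score >= 0 & cohort$vams$score <= 100))
  expect_true(all(cohort$cortisol$nmol_per_l >= 0))
  # two scans per participant, three cortisol samples, 4 x 5 VAMS items
  expect_true(all(table(cohort$scans$id) == 2))
  expect_true(all(table(cohort$cortisol$id) == 3))
  expect_true(all(table(cohort$vams$id) == 20))
})

test_that("scan pairs invert to the generating percent-change law", {
  cfg <- small_config(seed = 3)
  cohort <- generate_cohort(cfg)
  ch <- score_metabolite_changes(cohort$scans, outlier_sd = NULL)
  d <- dplyr::inner_join(ch, cohort$participants, by = "id")
  cal <- dplyr::filter(d, group == "hc_stress_calibration")
  # implied changes follow intercept + slope * PSS + noise: residual sd near config
  fit <- lm(pct_change_glu ~ pss, data = cal)
  expect_lt(abs(coef(fit)[2] - cfg$calibration_slope), 3 * summary(fit)$coefficients[2, 2])
})

test_that("a flat group shows no PSS association at large n", {
  cfg <- cohort_config(seed = 4,
                       n = c(hc_stress_calibration = 5, hc_stress_replication = 5,
                             nsc = 5000, mdd = 5))
  cohort <- generate_cohort(cfg)
  d <- score_metabolite_changes(cohort$scans, outlier_sd = NULL) |>
    dplyr::filter(included) |>
    dplyr::inner_join(cohort$participants, by = "id") |>
    dplyr::filter(group == "nsc")
  expect_lt(abs(cor(d$pss, d$pct_change_glu)), 0.03)
})

test_that("per-group PSS moments match the configured distribution", {
  cfg <- cohort_config(seed = 5,
                       n = c(hc_stress_calibration = 5, hc_stress_replication = 5,
                             nsc = 5, mdd = 100000),
                       clip_pss = FALSE)
  p <- generate_cohort(cfg)$participants
  mdd <- dplyr::filter(p, group == "mdd")
  expect_equal(mean(mdd$pss), 27.43, tolerance = 0.06 / 27.43)
  expect_equal(sd(mdd$pss), sqrt(5.89^2 + 1 / 12), tolerance = 0.02)
})

test_that("law recovery: regression recovers multiplier * slope within MC tolerance", {
  cfg <- cohort_config(seed = 6,
                       n = c(hc_stress_calibration = 5000, hc_stress_replication = 5,
                             nsc = 5000, mdd = 5))
  cohort <- generate_cohort(cfg)
  d <- score_metabolite_changes(cohort$scans, outlier_sd = NULL) |>
    dplyr::filter(included) |>
    dplyr::inner_join(cohort$participants, by = "id")
  for (g in c("hc_stress_calibration", "nsc")) {
    dd <- dplyr::filter(d, group == g)
    fit <- summary(lm(pct_change_glu ~ pss, data = dd))
    target <- cfg$calibration_slope * cfg$slope_multiplier[[g]]
    expect_lt(abs(fit$coefficients[2, 1] - target), 2 * fit$coefficients[2, 2])
  }
})

test_that("EMA stream is deterministic and complete under ideal settings", {
  cfg <- small_config(seed = 7,
                      ema = ema_config(days = 3, completion_prob = 1,
                                       invalid_fraction = 0))
  parts <- tibble::tibble(id = c("a", "b"), group = c("mdd", "nsc"))
  mgr <- tibble::tibble(id = c("a", "b"), mgr = c(10, -5))
  s <- generate_ema_streams(parts, mgr, cfg)
  expect_identical(s, generate_ema_streams(parts, mgr, cfg))
  f <- filter_surveys(s)
  expect_true(all(f$valid))
  expect_equal(nrow(dplyr::filter(f, id == "a")), 3 * 6)
  expect_true(all(dplyr::between(f$expectation, -4, 4)))
  expect_true(all(dplyr::between(f$outcome, -4, 4), na.rm = TRUE))
  aff <- unlist(f[c("enthusiastic", "cheerful", "relaxed",
                    "irritable", "anxious", "sad")])
  expect_true(all(aff %in% 1:5))
  expect_error(generate_ema_streams(parts, tibble::tibble(id = "zz", mgr = 1), cfg),
               "unknown participant")
})

test_that("zero coupling leaves pessimism unrelated to MGR", {
  n <- 1000
  parts <- tibble::tibble(id = sprintf("s%04d", 1:n), group = "hc_stress_replication")
  mgr <- tibble::tibble(id = parts$id, mgr = withr::with_seed(8, rnorm(n, 0, 20)))
  cfg <- cohort_config(seed = 8, ema = ema_config(coupling = 0, days = 8))
  s <- generate_ema_streams(parts, mgr, cfg)
  f <- filter_surveys(s)
  sm <- summarize_ema(f, build_matched_pairs(f), min_usable = 1)
  d <- dplyr::inner_join(sm, mgr, by = "id")
  expect_lt(abs(cor(d$mgr, d$pessimistic_mean, use = "complete.obs")), 0.05)
})

test_that("corrupted surveys carry labels matching the filter's reasons", {
  cfg <- small_config(seed = 9, ema = ema_config(invalid_fraction = 0.2))
  parts <- tibble::tibble(id = sprintf("s%02d", 1:6), group = "mdd")
  mgr <- tibble::tibble(id = parts$id, mgr = rnorm(6))
  f <- filter_surveys(generate_ema_streams(parts, mgr, cfg))
  lab <- dplyr::filter(f, !is.na(corruption))
  expect_gt(nrow(lab), 0)
  hit <- purrr::map2_lgl(lab$corruption, lab$invalid_reasons, function(type, reasons) {
    expected <- switch(type, off_schedule = "spacing", type)
    grepl(expected, reasons, fixed = TRUE)
  })
  expect_true(all(hit))
})

test_that("cohort CSVs round-trip losslessly, including empty tables", {
  cfg <- small_config(seed = 10, ema = ema_config(days = 2))
  cohort <- generate_cohort(cfg)
  mgr <- tibble::tibble(id = cohort$participants$id[1:4], mgr = c(1, -2, 0, 5))
  cohort$ema_surveys <- generate_ema_streams(cohort$participants, mgr, cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  for (nm in names(cohort)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(cohort[[nm]]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # empty cohort: header-only files that read back with zero rows
  empty <- purrr::map(cohort[c("participants", "scans", "cortisol", "vams")],
                      function(t) t[0, ])
  dir2 <- withr::local_tempdir()
  write_cohort(empty, dir2)
  back2 <- read_cohort(dir2)
  expect_true(all(purrr::map_int(back2, nrow) == 0))
  expect_identical(names(back2$participants), names(cohort$participants))
})

test_that("invalid generator configs are rejected with named fields", {
  expect_error(cohort_config(n = c(hc_stress_calibration = 0,
                                   hc_stress_replication = 5, nsc = 5, mdd = 5)),
               "`n`")
  expect_error(cohort_config(pss_sd = c(hc_stress_calibration = -1,
                                        hc_stress_replication = 5,
                                        nsc = 5, mdd = 5)),
               "`pss_sd`")
  expect_error(cohort_config(residual_sd = -2), "`residual_sd`")
  expect_error(ema_config(coupling = 1.5), "`coupling`")
  expect_error(ema_config(surveys_per_day = 7), "`surveys_per_day`")
})
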