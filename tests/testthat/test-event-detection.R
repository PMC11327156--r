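test_that("sub-minute gaps are linearly interpolated, longer gaps preserved", {
  obs <- rep(TRUE, 200)
  obs[100:129] <- FALSE  # 30 s gap
  x <- rep(10, 200); x[130:200] <- 20; x[!obs] <- NA
  day <- immersion_day("P01", 1L, x, observed = obs)
  fixed <- interpolate_gaps(day)
  expect_true(all(fixed$observed))
  # midpoint of the 30 s gap sits halfway between the flanking 10 and 20
  expect_equal(fixed$immersion[114], 10 + (20 - 10) * (114 - 99) / (130 - 99))
  expect_equal(fixed$immersion[c(99, 130)], c(10, 20))

  obs2 <- rep(TRUE, 400); obs2[100:219] <- FALSE  # 120 s gap
  x2 <- rep(10, 400); x2[!obs2] <- NA
  fixed2 <- interpolate_gaps(immersion_day("P01", 1L, x2, observed = obs2))
  expect_identical(fixed2$observed, obs2)

  # a gap of exactly 60 s is not repaired ("less than one minute")
  obs3 <- rep(TRUE, 400); obs3[100:159] <- FALSE
  x3 <- rep(10, 400); x3[!obs3] <- NA
  expect_identical(interpolate_gaps(immersion_day("P01", 1L, x3, observed = obs3))$observed,
                   obs3)

  # leading gaps have no flanking sample and stay missing
  obs4 <- rep(TRUE, 400); obs4[1:10] <- FALSE
  x4 <- rep(10, 400); x4[!obs4] <- NA
  expect_identical(interpolate_gaps(immersion_day("P01", 1L, x4, observed = obs4))$observed,
                   obs4)
})

test_that("the 4-hour day filter is inclusive at the boundary", {
  mk <- function(hours, id) immersion_day(id, 1L, rnorm(round(hours * 3600), 50, 5))
  days <- list(mk(3.9, "P01"), mk(4.0, "P02"), mk(4.5, "P03"))
  ex <- exclude_short_days(days, min_hours = 4)
  expect_equal(vapply(ex$retained, `[[`, character(1), "participant_id"),
               c("P02", "P03"))
  expect_equal(ex$log$retained, c(FALSE, TRUE, TRUE))
  # recount against the durations directly
  expect_equal(sum(ex$log$observed_hours >= 4), length(ex$retained))
})

test_that("person thresholds pool the full retained record", {
  d <- immersion_day("P01", 1L, c(1, 2, 3, 4, 5))
  thr <- person_thresholds(list(d))
  expect_equal(thr$median_immersion, 3)
  expect_equal(thr$sd_immersion, sqrt(2.5), tolerance = 1e-12)

  # two days with different means pool into one median/SD
  d1 <- immersion_day("P02", 1L, c(1, 1, 1, 1))
  d2 <- immersion_day("P02", 2L, c(5, 5, 5, 9))
  thr2 <- person_thresholds(list(d1, d2))
  v <- c(1, 1, 1, 1, 5, 5, 5, 9)
  expect_equal(thr2$median_immersion, median(v))
  expect_equal(thr2$sd_immersion, sd(v))
  expect_false(isTRUE(all.equal(thr2$sd_immersion,
                                mean(c(sd(c(1, 1, 1, 1)), sd(c(5, 5, 5, 9)))))))

  expect_error(person_thresholds(list(immersion_day("P03", 1L, rep(2, 10)))),
               "constant")
})

test_that("the OU generator's person median is recovered", {
  co <- small_cohort()
  thr <- person_thresholds(co$days)
  # baseline means are drawn from [40, 60]; medians must sit inside
  expect_true(all(thr$median_immersion > 30 & thr$median_immersion < 70))
})

test_that("detection applies the strict threshold and inclusive duration rules", {
  thr <- flat_thresholds(m = 50, s = 5)

  # flat series at the median: nothing beyond either threshold
  ev <- detect_events(make_flat_day(50), thr)
  expect_equal(nrow(ev), 0)

  # 200 s excursion to m - 2 SD: one trough, duration 200, depth 2 SD
  d200 <- make_flat_day(50, excursions = list(list(start = 501, len = 200, value = 40)))
  ev <- detect_events(d200, thr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "trough")
  expect_equal(ev$duration_s, 200)
  expect_equal(ev$start_offset_s, 500)
  expect_equal(ev$mean_depth, 10)
  expect_equal(ev$extremum, 40)

  # 170 s excursion: below the 180 s minimum
  d170 <- make_flat_day(50, excursions = list(list(start = 501, len = 170, value = 40)))
  expect_equal(nrow(detect_events(d170, thr)), 0)

  # 180 s exactly: inclusive boundary
  d180 <- make_flat_day(50, excursions = list(list(start = 501, len = 180, value = 40)))
  expect_equal(nrow(detect_events(d180, thr)), 1)

  # a value exactly at the threshold is not strictly beyond it
  dthr <- make_flat_day(50, excursions = list(list(start = 501, len = 300, value = 42.5)))
  expect_equal(nrow(detect_events(dthr, thr)), 0)

  # unobserved samples split runs: two 100 s halves of a 201 s excursion fail
  obs <- rep(TRUE, 3600); obs[601] <- FALSE
  dsplit <- make_flat_day(50, excursions = list(list(start = 501, len = 201, value = 40)),
                          observed = obs)
  expect_equal(nrow(detect_events(dsplit, thr, event_params(1.5, 180))), 0)
  expect_equal(nrow(detect_events(dsplit, thr, event_params(1.5, 100))), 2)

  # peaks are symmetric: above m + k SD
  dpk <- make_flat_day(50, excursions = list(list(start = 501, len = 200, value = 60)))
  ev <- detect_events(dpk, thr)
  expect_equal(ev$kind, "peak")
  expect_equal(ev$mean_height, 10)
})

test_that("detection matches the brute-force scanner on random series", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(200:2000, 1)
    x <- 50 + cumsum(rnorm(n, 0, 1)) * 0.5 + rnorm(n, 0, 3)
    observed <- rep(TRUE, n)
    if (runif(1) < 0.5) {
      for (g in seq_len(sample(1:3, 1))) {
        st <- sample(n - 20, 1)
        observed[st:(st + sample(5:20, 1))] <- FALSE
      }
    }
    x[!observed] <- NA
    m <- 50; s <- 3
    k <- sample(c(0.3, 0.5, 1), 1)
    dur <- sample(c(10, 20, 40), 1)
    day <- immersion_day("PX", 1L, x, observed = observed)
    got <- detect_events(day, flat_thresholds("PX", m, s), event_params(k, dur))
    want <- scan_events_bruteforce(x, observed, m, k * s, dur)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$kind, want$kind)
      expect_equal(got$start_offset_s, want$start_offset_s)
      expect_equal(got$duration_s, want$duration_s)
      dev <- ifelse(got$kind == "trough", got$mean_depth, got$mean_height)
      expect_equal(dev, want$mean_dev, tolerance = 1e-12)
      expect_equal(got$extremum, want$extremum)
    }
  }
})

test_that("troughs and peaks are disjoint and counts are monotone in the parameters", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 1500
    x <- 50 + cumsum(rnorm(n)) * 0.3
    day <- immersion_day("PX", 1L, x)
    thr <- flat_thresholds("PX", median(x), sd(x))
    ev <- detect_events(day, thr, event_params(0.5, 20))
    if (nrow(ev) > 1) {
      ivl <- cbind(ev$start_offset_s, ev$start_offset_s + ev$duration_s)
      ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
      expect_true(all(diff(ivl[, 1]) >= ivl[-nrow(ivl), 2] - ivl[-nrow(ivl), 1]))
    }
    # counts are monotone non-increasing in the duration rule
    n_at <- function(k, d) nrow(detect_events(day, thr, event_params(k, d)))
    expect_gte(n_at(0.5, 20), n_at(0.5, 60))
    expect_gte(n_at(1.0, 20), n_at(1.0, 60))
    # a stricter threshold yields events nested inside looser-threshold events
    # (the count itself may rise when a long run splits in two)
    lo <- detect_events(day, thr, event_params(0.5, 20))
    hi <- detect_events(day, thr, event_params(1.0, 20))
    if (nrow(hi) > 0) {
      for (i in seq_len(nrow(hi))) {
        same <- lo[lo$kind == hi$kind[i], ]
        expect_true(any(same$start_offset_s <= hi$start_offset_s[i] &
                          same$start_offset_s + same$duration_s >=
                            hi$start_offset_s[i] + hi$duration_s[i]))
      }
    }
  }
})

test_that("per-day event counts equal the sum over time-of-day bins", {
  pl <- default_cohort_pipeline()
  f <- pl$features
  expect_equal(f$n_troughs,
               f$n_troughs_morning + f$n_troughs_afternoon +
                 f$n_troughs_evening + f$n_troughs_other)
  expect_equal(f$n_peaks,
               f$n_peaks_morning + f$n_peaks_afternoon +
                 f$n_peaks_evening + f$n_peaks_other)
})

test_that("grid search selects a candidate able to see the injected events", {
  co <- cached_cohort("gridsearch", function()
    generate_cohort(cohort_config(
      n_participants = 12, n_days = 10, hours_per_day_range = c(3, 3.5),
      event_amplitude_sd_mult = 1.5, event_duration_range_s = c(280, 300),
      trough_rate_per_day = 3, peak_rate_per_day = 1,
      beta_trough = -0.5, beta_peak = 0, beta_trough_energy = -0.4,
      mood_intercept = 4.6, report_missing_prob = 0, gap_prob = 0,
      seed = 21)))
  thr <- person_thresholds(co$days)
  grid <- lapply(expand.grid(k = c(1, 1.5, 2), d = c(120, 300)) |> asplit(1),
                 function(r) event_params(r[["k"]], r[["d"]]))
  gs <- grid_search_params(co$days, co$reports, grid, thresholds = thr)
  expect_s3_class(gs, "grid_search_report")
  expect_equal(nrow(gs$report), 6)
  # amplitude 1.5 SD with ~300 s duration: only thresholds inside the
  # excursion envelope and durations short enough can score
  expect_lte(gs$best$sd_multiplier, 1.5)
  expect_lte(gs$best$min_duration_s, 300)
  expect_gt(max(abs(gs$report$objective)), 0.1)

  # a one-candidate grid is returned as-is
  gs1 <- grid_search_params(co$days, co$reports, list(event_params(1, 120)),
                            thresholds = thr)
  expect_equal(gs1$best$sd_multiplier, 1)
  expect_equal(gs1$best$min_duration_s, 120)
})

test_that("grid search on a null cohort finds only weak correlations", {
  co <- cached_cohort("gridnull", function()
    generate_cohort(cohort_config(
      n_participants = 12, n_days = 10, hours_per_day_range = c(3, 3.5),
      preset = "null", mood_intercept = 3.2, report_missing_prob = 0,
      gap_prob = 0, seed = 22)))
  thr <- person_thresholds(co$days)
  grid <- lapply(c(1, 1.5, 2), function(k) event_params(k, 180))
  gs <- grid_search_params(co$days, co$reports, grid, thresholds = thr)
  expect_lt(max(abs(gs$report$objective)), 0.3)
})
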