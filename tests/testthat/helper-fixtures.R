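# Shared fixtures and independent oracles for the suite.

# Independent brute-force event scanner: walks the series sample by sample,
# collecting maximal runs strictly beyond the thresholds, and keeps runs of
# at least `min_n` samples. Deliberately written as an explicit loop so it
# shares no code path with detect_events().
scan_events_bruteforce <- function(x, observed, m, half, min_n, hz = 1) {
  out <- list()
  for (kind in c("trough", "peak")) {
    in_run <- FALSE
    run_start <- 0L
    n <- length(x)
    for (i in seq_len(n + 1L)) {
      hit <- if (i <= n) {
        observed[i] && !is.na(x[i]) &&
          (if (kind == "trough") x[i] < m - half else x[i] > m + half)
      } else FALSE
      if (hit && !in_run) { in_run <- TRUE; run_start <- i }
      if (!hit && in_run) {
        in_run <- FALSE
        len <- i - run_start
        if (len >= min_n) {
          v <- x[run_start:(i - 1L)]
          out[[length(out) + 1L]] <- data.frame(
            kind = kind, start_offset_s = (run_start - 1) / hz,
            duration_s = len / hz,
            mean_dev = if (kind == "trough") mean(m - v) else mean(v - m),
            extremum = if (kind == "trough") min(v) else max(v))
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$start_offset_s), ]
}

# A hand-built day: constant baseline with optional rectangular excursions.
make_flat_day <- function(value = 50, n = 3600, id = "P01", day = 1L,
                          excursions = list(), observed = rep(TRUE, n)) {
  x <- rep(value, n)
  for (e in excursions) x[e$start:(e$start + e$len - 1L)] <- e$value
  immersion_day(id, day, x, observed = observed)
}

flat_thresholds <- function(id = "P01", m = 50, s = 5)
  tibble::tibble(participant_id = id, median_immersion = m, sd_immersion = s,
                 n_obs = 1000L)

# Memoized cohorts so several test files can share one generation run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, maker) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- maker()
  .cohort_cache[[key]]
}

# The study-calibrated default cohort plus its processed stages.
default_cohort_pipeline <- function() {
  cached_cohort("default", function() {
    co <- generate_cohort(cohort_config(seed = 1))
    days <- lapply(co$days, interpolate_gaps)
    ex <- exclude_short_days(days)
    thr <- person_thresholds(ex$retained)
    ev <- detect_events_cohort(ex$retained, thr)
    feats <- build_daily_features(ev, ex$retained, co$reports)
    list(cohort = co, days = days, excl = ex, thresholds = thr,
         events = ev, features = feats)
  })
}

# A small, quick cohort for tests that only need plumbing, not calibration.
small_cohort <- function() {
  cached_cohort("small", function() {
    generate_cohort(cohort_config(
      n_participants = 6, n_days = 6, hours_per_day_range = c(1, 1.5),
      report_missing_prob = 0, seed = 42))
  })
}
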