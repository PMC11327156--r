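#' Construct a single-day immersion series
#'
#' A participant-day of regularly sampled scalar immersion values with an
#' observation mask. Sample `i` sits at offset `(i - 1) / hz` seconds from the
#' start of recording; `observed = FALSE` marks gaps (the stored value at a
#' gap is `NA`).
#'
#' @param participant_id Identifier string.
#' @param day_index Integer day ordinal (1-based).
#' @param immersion Numeric vector of immersion values.
#' @param observed Logical vector, same length (default all `TRUE`).
#' @param start_clock_s Recording start in seconds since midnight.
#' @param hz Sampling rate, samples/second.
#' @return An object of class `immersion_day`.
#' @export
immersion_day <- function(participant_id, day_index, immersion,
                          observed = rep(TRUE, length(immersion)),
                          start_clock_s = 7 * 3600, hz = 1) {
  stopifnot(length(observed) == length(immersion), is.logical(observed))
  structure(
    list(participant_id = as.character(participant_id),
         day_index = as.integer(day_index),
         start_clock_s = start_clock_s, hz = hz,
         immersion = as.numeric(immersion), observed = observed),
    class = "immersion_day")
}

#' @export
print.immersion_day <- function(x, ...) {
  cat(sprintf("<immersion_day> %s day %d: %d samples (%.2f h), %.1f%% observed\n",
              x$participant_id, x$day_index, length(x$immersion),
              length(x$immersion) / x$hz / 3600,
              100 * mean(x$observed)))
  invisible(x)
}

#' Observed recording time of a day
#'
#' @param day An [immersion_day()].
#' @return Hours of observed (non-gap) samples.
#' @export
observed_hours <- function(day) sum(day$observed) / day$hz / 3600

# Raised-cosine (Tukey) event envelope: cosine onset/offset ramps around a
# flat plateau, so threshold crossings are smooth rather than square-pulse
# artifacts.
event_envelope <- function(n, ramp) {
  w <- rep(1, n)
  r <- min(ramp, floor(n / 2))
  if (r > 0) {
    t <- seq_len(r)
    w[t] <- 0.5 * (1 - cos(pi * t / r))
    w[n - r + t] <- pmin(w[n - r + t], 0.5 * (1 - cos(pi * (r - t + 1) / r)))
  }
  w
}

# Discretized Ornstein-Uhlenbeck path with stationary sd `sigma`, reversion
# rate `theta` (per second), at `hz` samples/second.
ou_path <- function(n, mu, sigma, theta, hz) {
  phi <- exp(-theta / hz)
  innov_sd <- sigma * sqrt(1 - phi^2)
  mu + as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi, "recursive",
                                init = rnorm(1, 0, sigma)))
}

#' Generate a synthetic immersion cohort
#'
#' Simulates per-participant 1 Hz immersion recordings and linked daily
#' self-reports with the statistical structure the downstream analysis
#' assumes. Each participant's baseline is a mean-reverting
#' (Ornstein-Uhlenbeck) process; trough and peak events are additive
#' raised-cosine excursions with per-day Poisson counts, amplitude
#' `event_amplitude_sd_mult` times the person's baseline SD and uniform
#' duration. Latent daily mood is linear in the injected event counts plus
#' sick/sex effects, a shared per-day shock and noise; energy analogously
#' (without a sex effect). The four Likert items (cheerful, stressed, lonely,
#' energy) are noisy rounded realizations whose reverse-coded composite
#' tracks the latent mood; low mood/energy means a score below 3.
#'
#' The generator is deterministic under a fixed `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `immersion_cohort`: a list with
#'   \describe{
#'     \item{days}{list of [immersion_day()] objects (gaps already injected
#'       when `gap_prob > 0`);}
#'     \item{reports}{tibble of daily self-reports (`participant_id`,
#'       `day_index`, `cheerful`, `stressed`, `lonely`, `energy`, `sick`,
#'       `male`; items `NA` on attrited days);}
#'     \item{truth}{ground truth: injected `events` tibble (kind, start,
#'       duration, amplitude), per-day `latent` tibble (continuous mood and
#'       energy, injected counts) and the generating coefficients.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 2, n_days = 2,
#'                                         hours_per_day_range = c(1, 1)))
#' cohort$reports
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  hz <- config$hz

  n_female <- round(config$frac_female * config$n_participants)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  male <- seq_len(config$n_participants) > n_female

  day_shock <- rnorm(config$n_days, 0, config$day_shock_sd)

  days <- list()
  ev_rows <- list()
  lat_rows <- list()
  rep_rows <- list()

  for (p in seq_len(config$n_participants)) {
    base_mu <- runif(1, config$baseline_mean_range[1], config$baseline_mean_range[2])
    base_sd <- runif(1, config$baseline_sd_range[1], config$baseline_sd_range[2])
    amp <- config$event_amplitude_sd_mult * base_sd

    for (d in seq_len(config$n_days)) {
      hours <- runif(1, config$hours_per_day_range[1], config$hours_per_day_range[2])
      n <- round(hours * 3600 * hz)
      x <- ou_path(n, base_mu, base_sd, config$ou_reversion, hz)

      n_tr <- rpois(1, config$trough_rate_per_day)
      n_pk <- rpois(1, config$peak_rate_per_day)
      kinds <- c(rep("trough", n_tr), rep("peak", n_pk))
      occupied <- logical(n)
      placed_tr <- 0L; placed_pk <- 0L
      for (kind in kinds) {
        dur <- round(runif(1, config$event_duration_range_s[1],
                           config$event_duration_range_s[2]) * hz)
        ok <- FALSE
        for (try in 1:20) {
          st <- sample.int(n - dur + 1L, 1L)
          span <- st:(st + dur - 1L)
          if (!any(occupied[span])) { ok <- TRUE; break }
        }
        if (!ok) next  # crowded day: drop this event (not part of ground truth)
        # keep a one-ramp buffer between events so excursions never merge
        buf <- max(1L, st - config$event_ramp_s * hz):min(n, st + dur - 1L + config$event_ramp_s * hz)
        occupied[buf] <- TRUE
        sgn <- if (kind == "trough") -1 else 1
        x[span] <- x[span] + sgn * amp * event_envelope(dur, config$event_ramp_s * hz)
        if (kind == "trough") placed_tr <- placed_tr + 1L else placed_pk <- placed_pk + 1L
        ev_rows[[length(ev_rows) + 1L]] <- list(
          participant_id = ids[p], day_index = d, kind = kind,
          start_offset_s = (st - 1) / hz, duration_s = dur / hz,
          amplitude = amp)
      }

      day <- immersion_day(ids[p], d, x, start_clock_s = config$start_clock_s, hz = hz)
      if (config$gap_prob > 0) day <- inject_gaps(day, config)
      days[[length(days) + 1L]] <- day

      sick <- rbinom(1, 1, config$sick_prob) == 1
      mood_lat <- config$mood_intercept +
        config$beta_trough * placed_tr + config$beta_peak * placed_pk +
        config$beta_sick * sick + config$beta_male * male[p] +
        day_shock[d] + rnorm(1, 0, config$mood_noise_sd)
      energy_lat <- config$energy_intercept +
        config$beta_trough_energy * placed_tr + config$beta_peak_energy * placed_pk +
        config$beta_sick_energy * sick +
        day_shock[d] + rnorm(1, 0, config$energy_noise_sd)
      mood_lat <- min(5, max(1, mood_lat))
      energy_lat <- min(5, max(1, energy_lat))
      # the stored continuous mood is the expected Likert composite
      # (three mood-shaped items plus the energy item, reverse coding undone)
      mood_cont <- (3 * mood_lat + energy_lat) / 4

      item <- function(target)
        as.integer(pmin(5, pmax(1, round(target + rnorm(1, 0, config$item_noise_sd)))))
      missing_rep <- rbinom(1, 1, config$report_missing_prob) == 1
      if (missing_rep) {
        ch <- st_ <- lo <- en <- NA_integer_
      } else {
        ch <- item(mood_lat); st_ <- item(6 - mood_lat)
        lo <- item(6 - mood_lat); en <- item(energy_lat)
      }
      rep_rows[[length(rep_rows) + 1L]] <- list(
        participant_id = ids[p], day_index = d,
        cheerful = ch, stressed = st_, lonely = lo, energy = en,
        sick = sick, male = male[p])
      lat_rows[[length(lat_rows) + 1L]] <- list(
        participant_id = ids[p], day_index = d,
        mood_continuous = mood_cont, mood_latent = mood_lat,
        energy_latent = energy_lat,
        n_troughs_injected = placed_tr, n_peaks_injected = placed_pk,
        report_missing = missing_rep)
    }
  }

  empty_events <- tibble::tibble(participant_id = character(), day_index = integer(),
                                 kind = character(), start_offset_s = numeric(),
                                 duration_s = numeric(), amplitude = numeric())
  structure(
    list(days = days,
         reports = tibble::as_tibble(data.table::rbindlist(rep_rows)),
         truth = list(
           events = if (length(ev_rows))
             tibble::as_tibble(data.table::rbindlist(ev_rows)) else empty_events,
           latent = tibble::as_tibble(data.table::rbindlist(lat_rows)),
           betas = config[grep("^beta_|intercept$", names(config))]),
         config = config),
    class = "immersion_cohort")
}

#' @export
print.immersion_cohort <- function(x, ...) {
  cat(sprintf("<immersion_cohort> %d participant-days (%d participants), %d injected events\n",
              length(x$days), x$config$n_participants, nrow(x$truth$events)))
  invisible(x)
}

#' Inject missing runs into a gap-free day
#'
#' Starts a missing run at each sample with probability `config$gap_prob`;
#' run lengths are uniform on `config$gap_length_range_s`. Values inside a
#' gap are set to `NA` and flagged unobserved.
#'
#' @param day An [immersion_day()] without gaps.
#' @param config A [cohort_config()] (only the gap fields are used).
#' @return The day with gaps injected.
#' @export
inject_gaps <- function(day, config) {
  n <- length(day$immersion)
  starts <- which(runif(n) < config$gap_prob)
  for (st in starts) {
    len <- round(runif(1, config$gap_length_range_s[1],
                       config$gap_length_range_s[2]) * day$hz)
    span <- st:min(n, st + len - 1L)
    day$observed[span] <- FALSE
  }
  day$immersion[!day$observed] <- NA_real_
  day
}

#' Convert immersion days to a long-format tibble
#'
#' One row per sample: `participant_id`, `day_index`, `offset_s`,
#' `immersion`, `observed`.
#'
#' @param days A list of [immersion_day()] objects (or a single one).
#' @return A tibble.
#' @export
series_to_long <- function(days) {
  if (inherits(days, "immersion_day")) days <- list(days)
  tibble::as_tibble(data.table::rbindlist(lapply(days, function(d) {
    data.table::data.table(
      participant_id = d$participant_id, day_index = d$day_index,
      offset_s = (seq_along(d$immersion) - 1) / d$hz,
      immersion = d$immersion, observed = d$observed)
  })))
}

#' Rebuild immersion days from a long-format table
#'
#' Inverse of [series_to_long()].
#'
#' @param long A data frame with columns `participant_id`, `day_index`,
#'   `offset_s`, `immersion`, `observed`.
#' @param start_clock_s,hz Recording start and sampling rate metadata (not
#'   stored in the long format).
#' @return A list of [immersion_day()] objects.
#' @export
long_to_series <- function(long, start_clock_s = 7 * 3600, hz = 1) {
  long <- as.data.frame(long)
  keys <- unique(long[, c("participant_id", "day_index")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- long[long$participant_id == keys$participant_id[i] &
                  long$day_index == keys$day_index[i], ]
    sub <- sub[order(sub$offset_s), ]
    immersion_day(keys$participant_id[i], keys$day_index[i], sub$immersion,
                  as.logical(sub$observed), start_clock_s = start_clock_s, hz = hz)
  })
}

#' Write a cohort's artifacts as plain CSV
#'
#' Writes `series.csv` (long format), `reports.csv`, and the ground truth
#' (`truth_events.csv`, `truth_latent.csv`).
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("series.csv", "reports.csv",
                            "truth_events.csv", "truth_latent.csv"))
  data.table::fwrite(series_to_long(cohort$days), paths[1])
  data.table::fwrite(cohort$reports, paths[2])
  data.table::fwrite(cohort$truth$events, paths[3])
  data.table::fwrite(cohort$truth$latent, paths[4])
  invisible(paths)
}
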