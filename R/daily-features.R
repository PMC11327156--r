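#' Mood composite from the four Likert items
#'
#' Mood is the mean of cheerful, reverse-coded stressed, reverse-coded
#' lonely, and the energy item, all on a 1-5 scale. Any missing item makes
#' the composite missing (such rows are dropped from the analysis table).
#'
#' @param cheerful,stressed,lonely,energy Integer vectors in 1..5 (vectorized).
#' @return Numeric mood composite in \[1, 5\].
#' @examples
#' compose_mood(5, 1, 1, 5)  # 5
#' compose_mood(2, 4, 4, 2)  # 2: a low-mood day
#' @export
compose_mood <- function(cheerful, stressed, lonely, energy) {
  items <- cbind(cheerful, stressed, lonely, energy)
  if (any(items < 1 | items > 5, na.rm = TRUE))
    stop("compose_mood: Likert items must be in 1..5")
  (cheerful + (6 - stressed) + (6 - lonely) + energy) / 4
}

#' Time-of-day bin of a clock time
#'
#' Half-open bins: morning \[07:00, 11:00), afternoon \[11:00, 15:00),
#' evening \[15:00, 19:00); anything else is `"other"`.
#'
#' @param seconds_since_midnight Numeric vector in \[0, 86400).
#' @return Factor with levels morning, afternoon, evening, other.
#' @export
bin_clock_time <- function(seconds_since_midnight) {
  s <- seconds_since_midnight
  stopifnot(all(s >= 0 & s < 86400))
  h <- s / 3600
  out <- rep("other", length(s))
  out[h >= 7 & h < 11] <- "morning"
  out[h >= 11 & h < 15] <- "afternoon"
  out[h >= 15 & h < 19] <- "evening"
  factor(out, levels = c("morning", "afternoon", "evening", "other"))
}

#' Build the participant-day analysis table
#'
#' Joins detected events, the immersion record and the self-reports into one
#' row per retained participant-day: event counts, mean event duration in
#' minutes (`avg_trough_time_min`, `avg_peak_time_min`), mean depth/height,
#' mean immersion over observed samples, mean start-to-start inter-event
#' gaps in minutes, per-time-of-day-bin counts, day of week, the mood
#' composite and energy item with their low indicators, and sick/male.
#'
#' Aggregates of an empty event set are explicitly missing (`NA`), never
#' zero: a day without troughs has no trough depth. `time_between_*` needs
#' at least two events of that kind.
#'
#' @param events Events tibble from [detect_events_cohort()].
#' @param days The retained, interpolated [immersion_day()] list.
#' @param reports Self-report tibble (`participant_id`, `day_index`,
#'   `cheerful`, `stressed`, `lonely`, `energy`, `sick`, `male`).
#' @param anchor_weekday Weekday of `day_index = 1` (0 = Monday); day of
#'   week is `(day_index - 1 + anchor_weekday) %% 7`.
#' @param drop_incomplete Drop rows whose mood composite is missing
#'   (default); the number dropped is recorded in the
#'   `n_dropped_missing_report` attribute.
#' @return A tibble, one row per retained participant-day.
#' @export
build_daily_features <- function(events, days, reports, anchor_weekday = 0,
                                 drop_incomplete = TRUE) {
  ev_key <- paste(events$participant_id, events$day_index)
  rows <- lapply(days, function(day) {
    ev <- events[ev_key == paste(day$participant_id, day$day_index), ]
    tr <- ev[ev$kind == "trough", ]
    pk <- ev[ev$kind == "peak", ]
    gap_min <- function(e)
      if (nrow(e) >= 2) mean(diff(sort(e$start_offset_s))) / 60 else NA_real_
    avg_or_na <- function(x) if (length(x)) mean(x) else NA_real_
    nbin <- function(e, b) sum(e$start_clock_bin == b)
    list(
      participant_id = day$participant_id,
      day_index = day$day_index,
      day_of_week = (day$day_index - 1 + anchor_weekday) %% 7,
      n_troughs = nrow(tr), n_peaks = nrow(pk),
      avg_trough_time_min = avg_or_na(tr$duration_s) / 60,
      avg_peak_time_min = avg_or_na(pk$duration_s) / 60,
      avg_trough_depth = avg_or_na(tr$mean_depth),
      avg_peak_height = avg_or_na(pk$mean_height),
      avg_immersion = mean(day$immersion[day$observed]),
      time_between_troughs_min = gap_min(tr),
      time_between_peaks_min = gap_min(pk),
      n_troughs_morning = nbin(tr, "morning"),
      n_troughs_afternoon = nbin(tr, "afternoon"),
      n_troughs_evening = nbin(tr, "evening"),
      n_troughs_other = nbin(tr, "other"),
      n_peaks_morning = nbin(pk, "morning"),
      n_peaks_afternoon = nbin(pk, "afternoon"),
      n_peaks_evening = nbin(pk, "evening"),
      n_peaks_other = nbin(pk, "other"),
      observed_hours = observed_hours(day))
  })
  tab <- tibble::as_tibble(data.table::rbindlist(rows))
  rep2 <- reports
  rep2$mood <- compose_mood(rep2$cheerful, rep2$stressed, rep2$lonely, rep2$energy)
  tab <- dplyr::left_join(
    tab,
    rep2[, c("participant_id", "day_index", "mood", "energy", "sick", "male")],
    by = c("participant_id", "day_index"))
  tab$low_mood <- tab$mood < 3
  tab$low_energy <- tab$energy < 3
  n_drop <- sum(is.na(tab$mood))
  if (drop_incomplete) tab <- tab[!is.na(tab$mood), ]
  attr(tab, "n_dropped_missing_report") <- n_drop
  tab
}
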