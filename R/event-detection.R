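#' Event-detection parameters
#'
#' The trough/peak statistic has two tunables: the threshold distance from
#' the person median in SD units, and the minimum run duration. The defaults
#' (1.5 SD for at least 3 minutes) are the calibrated operating point used
#' throughout the analysis.
#'
#' @param sd_multiplier Threshold distance in multiples of the person SD.
#' @param min_duration_s Minimum event duration in seconds (inclusive).
#' @return A list of class `event_params`.
#' @export
event_params <- function(sd_multiplier = 1.5, min_duration_s = 180) {
  stopifnot(sd_multiplier > 0, min_duration_s >= 1)
  structure(list(sd_multiplier = sd_multiplier, min_duration_s = min_duration_s),
            class = "event_params")
}

#' @export
print.event_params <- function(x, ...) {
  cat(sprintf("<event_params> median +/- %.2f SD for >= %g s\n",
              x$sd_multiplier, x$min_duration_s))
  invisible(x)
}

#' Interpolate short recording gaps
#'
#' Unobserved runs strictly shorter than `max_gap_s` are filled by linear
#' interpolation between the flanking observed samples and marked observed;
#' longer runs, and leading/trailing gaps (which have no flanking value on
#' one side), are left untouched. Mirrors the platform behaviour of
#' repairing data lost for less than one minute.
#'
#' @param day An [immersion_day()].
#' @param max_gap_s Gaps of this duration or longer are preserved.
#' @return The repaired day.
#' @export
interpolate_gaps <- function(day, max_gap_s = 60) {
  obs <- day$observed
  if (all(obs)) return(day)
  imm <- day$immersion
  r <- rle(obs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(obs)
  for (i in seq_along(r$values)) {
    if (r$values[i]) next
    len_s <- r$lengths[i] / day$hz
    if (len_s >= max_gap_s) next
    if (starts[i] == 1L || ends[i] == n) next  # no flanking sample
    lo <- starts[i] - 1L; hi <- ends[i] + 1L
    idx <- starts[i]:ends[i]
    imm[idx] <- imm[lo] + (imm[hi] - imm[lo]) * (idx - lo) / (hi - lo)
    obs[idx] <- TRUE
  }
  day$immersion <- imm
  day$observed <- obs
  day
}

#' Exclude days with too little observed data
#'
#' A day is retained iff its observed duration (after interpolation) is at
#' least `min_hours`; the boundary is inclusive.
#'
#' @param days A list of [immersion_day()] objects.
#' @param min_hours Retention threshold in hours.
#' @return A list with `retained` (list of days), `excluded` (list of days)
#'   and `log`, a tibble of every day's observed hours and retention status.
#' @export
exclude_short_days <- function(days, min_hours = 4) {
  hrs <- vapply(days, observed_hours, numeric(1))
  keep <- hrs >= min_hours
  list(retained = days[keep],
       excluded = days[!keep],
       log = tibble::tibble(
         participant_id = vapply(days, `[[`, character(1), "participant_id"),
         day_index = vapply(days, `[[`, integer(1), "day_index"),
         observed_hours = hrs,
         retained = keep))
}

#' Per-person detection thresholds
#'
#' The event statistic is anchored to each participant's own record: the
#' median and sample SD of all observed samples pooled across that
#' participant's retained days.
#'
#' @param days A list of retained, interpolated [immersion_day()] objects
#'   (may span several participants).
#' @return A tibble with one row per participant: `participant_id`,
#'   `median_immersion`, `sd_immersion`, `n_obs`.
#' @export
person_thresholds <- function(days) {
  ids <- vapply(days, `[[`, character(1), "participant_id")
  uids <- unique(ids)
  med <- sdv <- nob <- numeric(length(uids))
  for (i in seq_along(uids)) {
    v <- unlist(lapply(days[ids == uids[i]], function(d) d$immersion[d$observed]),
                use.names = FALSE)
    if (length(v) < 2)
      stop("person_thresholds: participant ", uids[i],
           " has fewer than 2 observed samples")
    s <- sd(v)
    if (s == 0)
      stop("person_thresholds: participant ", uids[i],
           " has a constant series (SD = 0)")
    med[i] <- median(v); sdv[i] <- s; nob[i] <- length(v)
  }
  tibble::tibble(participant_id = uids, median_immersion = med,
                 sd_immersion = sdv, n_obs = nob)
}

empty_events_tbl <- function() {
  tibble::tibble(participant_id = character(), day_index = integer(),
                 kind = character(), start_offset_s = numeric(),
                 duration_s = numeric(), mean_depth = numeric(),
                 mean_height = numeric(), extremum = numeric(),
                 start_clock_bin = character())
}

#' Detect trough and peak events in one day
#'
#' A trough is a maximal run of consecutive observed samples strictly below
#' `median - k * SD` whose duration is at least `min_duration_s`; a peak is
#' the symmetric run strictly above `median + k * SD`. Runs are broken at
#' unobserved samples (sub-minute gaps are expected to have been repaired by
#' [interpolate_gaps()] first; remaining gaps are real discontinuities).
#' Duration is `n_samples / hz`.
#'
#' @param day A retained, interpolated [immersion_day()].
#' @param thresholds A [person_thresholds()] tibble (the row matching the
#'   day's participant is used) or a single-participant row.
#' @param params An [event_params()].
#' @return A tibble of events: kind, start offset, duration, mean depth
#'   (median minus value, troughs) or mean height (value minus median,
#'   peaks), extremum, and the time-of-day bin of the start
#'   ([bin_clock_time()]).
#' @export
detect_events <- function(day, thresholds, params = event_params()) {
  thr <- thresholds[thresholds$participant_id == day$participant_id, ]
  if (nrow(thr) != 1)
    stop("detect_events: no thresholds for participant ", day$participant_id)
  m <- thr$median_immersion
  half <- params$sd_multiplier * thr$sd_immersion
  min_n <- ceiling(params$min_duration_s * day$hz)

  out <- list()
  for (kind in c("trough", "peak")) {
    hit <- if (kind == "trough") {
      day$observed & !is.na(day$immersion) & day$immersion < (m - half)
    } else {
      day$observed & !is.na(day$immersion) & day$immersion > (m + half)
    }
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_n)
    if (!length(sel)) next
    mean_dev <- vapply(sel, function(i) mean(day$immersion[starts[i]:ends[i]]) - m,
                       numeric(1))
    extremum <- vapply(sel, function(i) {
      v <- day$immersion[starts[i]:ends[i]]
      if (kind == "trough") min(v) else max(v)
    }, numeric(1))
    off <- (starts[sel] - 1) / day$hz
    out[[kind]] <- data.frame(
      participant_id = day$participant_id, day_index = day$day_index,
      kind = kind, start_offset_s = off, duration_s = r$lengths[sel] / day$hz,
      mean_depth = if (kind == "trough") -mean_dev else NA_real_,
      mean_height = if (kind == "peak") mean_dev else NA_real_,
      extremum = extremum,
      start_clock_bin = as.character(bin_clock_time((day$start_clock_s + off) %% 86400)),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_events_tbl())
  res <- if (length(out) == 1) out[[1]] else rbind(out[[1]], out[[2]])
  tibble::as_tibble(res[order(res$start_offset_s), ])
}

#' Detect events across a whole cohort
#'
#' @param days List of retained, interpolated [immersion_day()] objects.
#' @param thresholds A [person_thresholds()] tibble covering every
#'   participant in `days`.
#' @param params An [event_params()].
#' @return One events tibble (see [detect_events()]), all days combined.
#' @export
detect_events_cohort <- function(days, thresholds, params = event_params()) {
  res <- lapply(days, detect_events, thresholds = thresholds, params = params)
  res <- res[vapply(res, nrow, integer(1)) > 0]
  if (!length(res)) return(empty_events_tbl())
  tibble::as_tibble(data.table::rbindlist(res))
}

#' Default calibration grid for the event statistic
#'
#' @return A list of [event_params()] candidates: SD multipliers
#'   \{0.5, 1, 1.5, 2, 2.5\} crossed with minimum durations
#'   \{60, 120, 180, 240, 300, 600\} s.
#' @export
default_param_grid <- function() {
  g <- expand.grid(sd_multiplier = c(0.5, 1, 1.5, 2, 2.5),
                   min_duration_s = c(60, 120, 180, 240, 300, 600))
  lapply(seq_len(nrow(g)), function(i)
    event_params(g$sd_multiplier[i], g$min_duration_s[i]))
}

#' Grid-search calibration of the event statistic
#'
#' For each candidate parameter pair, detects events over the whole retained
#' record, counts troughs per participant-day, and computes the Pearson
#' correlation between the daily trough count and the binary low-mood
#' indicator derived from the self-reports. The candidate with the largest
#' absolute correlation wins; ties break toward the larger minimum duration,
#' then the larger SD multiplier (the more conservative definition).
#' Candidates yielding no events (or a constant count) score 0.
#'
#' @param days Retained, interpolated [immersion_day()] objects.
#' @param reports The daily self-report tibble (see [generate_cohort()]).
#' @param grid List of [event_params()] candidates
#'   (default [default_param_grid()]).
#' @param thresholds Optional precomputed [person_thresholds()].
#' @return A list of class `grid_search_report`: `report` (one row per
#'   candidate with its objective) and `best` (the selected
#'   [event_params()]).
#' @export
grid_search_params <- function(days, reports, grid = default_param_grid(),
                               thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- person_thresholds(days)
  mood <- compose_mood(reports$cheerful, reports$stressed, reports$lonely,
                       reports$energy)
  outc <- tibble::tibble(participant_id = reports$participant_id,
                         day_index = reports$day_index,
                         low_mood = as.numeric(mood < 3))
  outc <- outc[!is.na(outc$low_mood), ]
  if (length(unique(outc$low_mood)) < 2)
    stop("grid_search_params: the low-mood indicator is constant")
  key <- tibble::tibble(
    participant_id = vapply(days, `[[`, character(1), "participant_id"),
    day_index = vapply(days, `[[`, integer(1), "day_index"))

  rows <- lapply(grid, function(p) {
    ev <- detect_events_cohort(days, thresholds, p)
    tr <- ev[ev$kind == "trough", ]
    cnt <- dplyr::count(tr, .data$participant_id, .data$day_index, name = "n_troughs")
    tab <- dplyr::left_join(key, cnt, by = c("participant_id", "day_index"))
    tab$n_troughs[is.na(tab$n_troughs)] <- 0L
    tab <- dplyr::inner_join(tab, outc, by = c("participant_id", "day_index"))
    r <- if (sd(tab$n_troughs) == 0) 0 else cor(tab$n_troughs, tab$low_mood)
    tibble::tibble(sd_multiplier = p$sd_multiplier,
                   min_duration_s = p$min_duration_s,
                   objective = ifelse(is.na(r), 0, r))
  })
  report <- dplyr::bind_rows(rows)
  ord <- order(-abs(report$objective), -report$min_duration_s,
               -report$sd_multiplier)
  best_i <- ord[1]
  structure(list(report = report,
                 best = event_params(report$sd_multiplier[best_i],
                                     report$min_duration_s[best_i])),
            class = "grid_search_report")
}

#' @export
print.grid_search_report <- function(x, ...) {
  b <- x$best
  i <- which(x$report$sd_multiplier == b$sd_multiplier &
               x$report$min_duration_s == b$min_duration_s)
  cat(sprintf("<grid_search_report> %d candidates; selected %.2f SD / %g s (|r| = %.3f)\n",
              nrow(x$report), b$sd_multiplier, b$min_duration_s,
              abs(x$report$objective[i])))
  invisible(x)
}
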