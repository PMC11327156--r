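#' Configuration for the synthetic immersion cohort generator
#'
#' Defines every knob of the simulated study: cohort size, recording regime,
#' the person-level baseline process, injected trough/peak events, the daily
#' mood/energy response model, self-report attrition and recording gaps.
#'
#' The defaults are calibrated to the observational regime the pipeline is
#' designed for: 24 participants wearing a smartwatch 8-10 h/day at 1 Hz for
#' 20 days (~72% female), an immersion scale of roughly 0-100 with person
#' baseline SD 6-10 units, injected excursions at Poisson rates of 2.25
#' troughs and 3.28 peaks per day, and daily 1-5 mood/energy responses with
#' ~5% low-mood and ~21% low-energy days.
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param hz Sampling rate in samples/second.
#' @param hours_per_day_range Min/max recording hours per day (uniform draw).
#' @param start_clock_s Recording start, seconds since midnight (default 07:00
#'   so morning/afternoon/evening bins are populated).
#' @param frac_female Proportion of female participants (deterministic count).
#' @param baseline_mean_range,baseline_sd_range Person-level baseline mean and
#'   stationary SD of the mean-reverting (Ornstein-Uhlenbeck) process,
#'   immersion units; each participant draws one value from the range.
#' @param ou_reversion Mean-reversion rate of the baseline process, per
#'   second. 1/ou_reversion is the correlation time; the default 1/300 makes
#'   the signal smooth at the minutes scale, as a physiological index is.
#' @param trough_rate_per_day,peak_rate_per_day Expected injected events per
#'   day (per-day counts are Poisson).
#' @param event_duration_range_s Uniform range of injected event durations.
#' @param event_amplitude_sd_mult Event amplitude in multiples of the
#'   participant's baseline SD.
#' @param event_ramp_s Raised-cosine onset/offset ramp length, seconds.
#' @param beta_trough,beta_peak,beta_sick,beta_male Mood-model coefficients
#'   (mood units per event / per indicator).
#' @param mood_intercept,mood_noise_sd Mood-model intercept and residual SD.
#' @param beta_trough_energy,beta_peak_energy,beta_sick_energy,energy_intercept,energy_noise_sd
#'   Energy-model analogues. Sex enters mood only.
#' @param day_shock_sd SD of an additive per-calendar-day shock shared by all
#'   participants (motivates day fixed effects downstream).
#' @param item_noise_sd SD of per-Likert-item noise around the latent target.
#' @param sick_prob Daily probability of the sick indicator.
#' @param report_missing_prob Probability a day's self-report is missing
#'   (emulates survey attrition).
#' @param gap_prob Per-sample probability that a missing run starts.
#' @param gap_length_range_s Uniform range of missing-run lengths, seconds.
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @param preset One of `"study"` (the calibrated defaults), `"strong"`
#'   (larger planted mood effects at the same low-mood prevalence, for
#'   power/classification experiments) or `"null"` (all mood and energy
#'   coefficients zero: self-reports carry no signal). Explicit arguments
#'   override the preset.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_participants = 24,
                          n_days = 20,
                          hz = 1,
                          hours_per_day_range = c(8, 10),
                          start_clock_s = 7 * 3600,
                          frac_female = 0.72,
                          baseline_mean_range = c(40, 60),
                          baseline_sd_range = c(6, 10),
                          ou_reversion = 1 / 300,
                          trough_rate_per_day = 2.25,
                          peak_rate_per_day = 3.28,
                          event_duration_range_s = c(240, 480),
                          event_amplitude_sd_mult = 4.5,
                          event_ramp_s = 30,
                          beta_trough = -0.15,
                          beta_peak = 0.10,
                          beta_sick = -1.0,
                          beta_male = 0.2,
                          mood_intercept = 4.1,
                          mood_noise_sd = 0.5,
                          beta_trough_energy = -0.12,
                          beta_peak_energy = 0.10,
                          beta_sick_energy = -0.9,
                          energy_intercept = 3.1,
                          energy_noise_sd = 0.6,
                          day_shock_sd = 0.1,
                          item_noise_sd = 0.25,
                          sick_prob = 0.05,
                          report_missing_prob = 0.15,
                          gap_prob = 1e-4,
                          gap_length_range_s = c(15, 90),
                          seed = 1,
                          preset = c("study", "strong", "null")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  cfg$preset <- NULL
  explicit <- names(as.list(match.call()))[-1]

  preset_over <- switch(preset,
    study = list(),
    strong = list(beta_trough = -0.30, beta_peak = 0.20, mood_intercept = 4.45,
                  beta_trough_energy = -0.25, beta_peak_energy = 0.18,
                  energy_intercept = 3.35),
    null = list(beta_trough = 0, beta_peak = 0, beta_sick = 0, beta_male = 0,
                beta_trough_energy = 0, beta_peak_energy = 0,
                beta_sick_energy = 0)
  )
  for (nm in setdiff(names(preset_over), explicit)) cfg[[nm]] <- preset_over[[nm]]

  validate_cohort_config(structure(cfg, class = "cohort_config"))
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  chk <- function(ok, msg) if (!ok) stop("cohort_config: ", msg, call. = FALSE)
  chk(cfg$n_participants >= 1, "n_participants must be >= 1")
  chk(cfg$n_days >= 1, "n_days must be >= 1")
  chk(cfg$hz > 0, "hz must be > 0")
  for (p in c("frac_female", "sick_prob", "report_missing_prob", "gap_prob"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  chk(cfg$trough_rate_per_day >= 0 && cfg$peak_rate_per_day >= 0,
      "event rates must be >= 0")
  chk(all(cfg$event_duration_range_s > 0) && diff(cfg$event_duration_range_s) >= 0,
      "event_duration_range_s must be positive and ordered")
  chk(all(cfg$hours_per_day_range > 0) && diff(cfg$hours_per_day_range) >= 0,
      "hours_per_day_range must be positive and ordered")
  chk(cfg$event_duration_range_s[2] <= cfg$hours_per_day_range[1] * 3600,
      "event duration may not exceed the shortest day length")
  chk(all(cfg$gap_length_range_s > 0) && diff(cfg$gap_length_range_s) >= 0,
      "gap_length_range_s must be positive and ordered")
  chk(cfg$ou_reversion > 0, "ou_reversion must be > 0")
  chk(cfg$event_amplitude_sd_mult > 0, "event_amplitude_sd_mult must be > 0")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d participants x %d days, %g-%g h/day at %g Hz\n",
              x$n_participants, x$n_days, x$hours_per_day_range[1],
              x$hours_per_day_range[2], x$hz))
  cat(sprintf("  events/day: %.2f troughs, %.2f peaks; amplitude %.1f x person SD\n",
              x$trough_rate_per_day, x$peak_rate_per_day, x$event_amplitude_sd_mult))
  cat(sprintf("  mood betas: trough %.3f, peak %.3f, sick %.2f, male %.2f\n",
              x$beta_trough, x$beta_peak, x$beta_sick, x$beta_male))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
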