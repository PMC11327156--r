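#' Run the full simulate-detect-features-stats-ml pipeline
#'
#' Executes the stages in order, writing every artifact as plain CSV/JSON
#' under `out_dir` and recording an attrition ledger (generated days =
#' retained + excluded short days; report rows = complete + missing) plus
#' MD5 hashes of every artifact in `manifest.json`. The run is
#' deterministic: the global `seed` is fanned out to per-stage substreams,
#' so two runs with the same configuration produce identical manifests.
#'
#' @param out_dir Output directory.
#' @param cohort A [cohort_config()] (its own seed is replaced by the
#'   pipeline seed substream).
#' @param params An [event_params()], or `NULL` to calibrate via
#'   [grid_search_params()].
#' @param ml An [ml_config()], or `NULL` to skip the ML stage.
#' @param min_hours Short-day exclusion threshold.
#' @param max_gap_s Gap-interpolation limit.
#' @param seed Global pipeline seed.
#' @param quiet Suppress stage progress messages.
#' @return The manifest (invisibly): stage artifacts, attrition counts,
#'   hashes.
#' @export
run_pipeline <- function(out_dir,
                         cohort = cohort_config(),
                         params = event_params(),
                         ml = ml_config(),
                         min_hours = 4, max_gap_s = 60,
                         seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[moodwatch] ", sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4)
  stage <- "simulate"
  res <- tryCatch({
    say("simulate: %d participants x %d days", cohort$n_participants, cohort$n_days)
    cohort$seed <- seeds[1]
    cohort_data <- generate_cohort(cohort)
    write_cohort_csv(cohort_data, out_dir)

    stage <- "detect"
    days <- lapply(cohort_data$days, interpolate_gaps, max_gap_s = max_gap_s)
    excl <- exclude_short_days(days, min_hours = min_hours)
    if (length(excl$retained) == 0)
      stop("all ", length(days), " days have < ", min_hours,
           " observed hours; nothing to analyse")
    data.table::fwrite(excl$log, file.path(out_dir, "exclusion_log.csv"))
    thr <- person_thresholds(excl$retained)
    if (is.null(params)) {
      say("detect: grid search over %d candidates", length(default_param_grid()))
      gs <- grid_search_params(excl$retained, cohort_data$reports, thresholds = thr)
      data.table::fwrite(gs$report, file.path(out_dir, "grid_search.csv"))
      params <- gs$best
    }
    say("detect: %.2f SD for >= %g s", params$sd_multiplier, params$min_duration_s)
    events <- detect_events_cohort(excl$retained, thr, params)
    data.table::fwrite(events, file.path(out_dir, "events.csv"))

    stage <- "features"
    feats <- build_daily_features(events, excl$retained, cohort_data$reports)
    data.table::fwrite(feats, file.path(out_dir, "daily_features.csv"))
    say("features: %d analysis rows", nrow(feats))

    stage <- "stats"
    assoc <- rbind(association_table(feats, "mood"),
                   association_table(feats, "energy"))
    data.table::fwrite(assoc, file.path(out_dir, "association_stats.csv"))

    stage <- "ml"
    ml_summary <- NULL
    if (!is.null(ml)) {
      ml$seed <- seeds[4]
      report <- run_ml(feats, ml)
      ml_summary <- lapply(report$families, function(f)
        list(family = f$family, tuned_params = as.list(f$tuned_params),
             cv_auc_mean = f$cv_auc_mean, cv_auc_sd = f$cv_auc_sd,
             train = f$train, test = f$test,
             importance = as.list(setNames(f$importance$mean_acc_drop,
                                           f$importance$feature)),
             chance = f$chance[c("mean_auc", "t", "p", "n_redraws")]))
      jsonlite::write_json(ml_summary, file.path(out_dir, "ml_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      metrics <- dplyr::bind_rows(lapply(report$families, function(f)
        tibble::tibble(family = f$family, set = c("train", "test"),
                       auc = c(f$train$auc, f$test$auc),
                       acc = c(f$train$acc, f$test$acc),
                       precision = c(f$train$precision, f$test$precision),
                       recall = c(f$train$recall, f$test$recall),
                       cv_auc_mean = f$cv_auc_mean, cv_auc_sd = f$cv_auc_sd)))
      data.table::fwrite(metrics, file.path(out_dir, "ml_metrics.csv"))
      say("ml: %s", paste(names(report$families), collapse = ", "))
    }

    n_missing <- sum(is.na(cohort_data$reports$cheerful))
    attrition <- list(
      days_generated = length(cohort_data$days),
      days_retained = length(excl$retained),
      days_excluded_short = length(excl$excluded),
      reports_generated = nrow(cohort_data$reports),
      reports_missing = n_missing,
      reports_missing_retained = attr(feats, "n_dropped_missing_report"),
      analysis_rows = nrow(feats))

    artifacts <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
    artifacts <- setdiff(artifacts, file.path(out_dir, "manifest.json"))
    manifest <- list(
      seed = seed,
      params = list(sd_multiplier = params$sd_multiplier,
                    min_duration_s = params$min_duration_s,
                    min_hours = min_hours, max_gap_s = max_gap_s),
      attrition = attrition,
      artifacts = as.list(tools::md5sum(sort(artifacts))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain `cohort:`, `params:`, `ml:`, `min_hours:`,
#' `max_gap_s:` and `seed:` blocks whose entries override the corresponding
#' constructor defaults.
#'
#' @param path Path to a YAML file.
#' @return A list of arguments for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohort_config, raw$cohort)
  if (!is.null(raw$params)) args$params <- do.call(event_params, raw$params)
  # an explicit empty `ml:` block disables the classification stage
  if ("ml" %in% names(raw))
    args["ml"] <- list(if (is.null(raw$ml)) NULL else do.call(ml_config, raw$ml))
  for (nm in c("min_hours", "max_gap_s", "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  args
}
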