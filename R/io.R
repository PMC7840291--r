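TS_FMT <- "%Y-%m-%dT%H:%M:%S%z"

parse_ts <- function(x, what, tz = "UTC") {
  ts <- as.POSIXct(x, format = TS_FMT, tz = tz)
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad)) {
    abort(sprintf("%s: malformed ISO-8601 timestamp at row(s) %s",
                  what, paste(head(bad, 10), collapse = ", ")))
  }
  ts
}

format_ts <- function(ts, tz) format(ts, TS_FMT, tz = tz)

#' Read a GPS fix table
#'
#' CSV with header `participant_id,timestamp,lat,lon`; timestamps are
#' ISO-8601 with a UTC offset (`2023-01-09T08:00:00-0500`). Rows are
#' sorted by participant then time; malformed timestamps, out-of-range
#' coordinates and duplicate (participant, timestamp) pairs are rejected
#' with row numbers.
#'
#' @param path CSV file path.
#' @param tz Timezone used to derive `local_date`.
#' @return Tibble `participant_id`, `timestamp`, `lat`, `lon`, `local_date`.
#' @export
read_fixes <- function(path, tz = "America/New_York") {
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    lat = readr::col_double(),
    lon = readr::col_double()))
  need <- c("participant_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(raw))) {
    abort(paste("fixes file must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort("fixes file is empty")
  bad <- which(is.na(raw$lat) | is.na(raw$lon) |
                 raw$lat < -90 | raw$lat > 90 |
                 raw$lon <= -180 | raw$lon > 180)
  if (length(bad)) {
    abort(sprintf("out-of-range or missing coordinates at row(s) %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  ts <- parse_ts(raw$timestamp, "fixes file")
  out <- tibble::tibble(participant_id = raw$participant_id,
                        timestamp = ts, lat = raw$lat, lon = raw$lon)
  out <- dplyr::arrange(out, .data$participant_id, .data$timestamp)
  dup <- which(duplicated(out[c("participant_id", "timestamp")]))
  if (length(dup)) {
    abort(sprintf("duplicate (participant_id, timestamp) at sorted row(s) %s",
                  paste(head(dup, 10), collapse = ", ")))
  }
  out$local_date <- as.Date(format(out$timestamp, tz = tz))
  out
}

#' Write a GPS fix table
#' @param fixes Fix tibble.
#' @param path Output CSV path.
#' @param tz Timezone whose UTC offset is used when formatting timestamps.
#' @export
write_fixes <- function(fixes, path, tz = "America/New_York") {
  out <- tibble::tibble(participant_id = fixes$participant_id,
                        timestamp = format_ts(fixes$timestamp, tz),
                        lat = fixes$lat, lon = fixes$lon)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an EMA prompt table
#'
#' CSV with header `participant_id,timestamp,window,rating`; empty rating
#' means an unanswered prompt.
#'
#' @inheritParams read_fixes
#' @return Tibble `participant_id`, `timestamp`, `window`, `rating`,
#'   `local_date`.
#' @export
read_prompts <- function(path, tz = "America/New_York") {
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    window = readr::col_character(),
    rating = readr::col_integer()))
  if (nrow(raw) == 0) abort("prompts file is empty")
  bad <- which(!raw$window %in% c("morning", "afternoon", "evening"))
  if (length(bad)) {
    abort(sprintf("unknown prompt window at row(s) %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  bad <- which(!is.na(raw$rating) & (raw$rating < 0 | raw$rating > 10))
  if (length(bad)) {
    abort(sprintf("rating outside 0-10 at row(s) %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  ts <- parse_ts(raw$timestamp, "prompts file")
  tibble::tibble(participant_id = raw$participant_id, timestamp = ts,
                 window = raw$window, rating = raw$rating,
                 local_date = as.Date(format(ts, tz = tz)))
}

#' Write an EMA prompt table
#' @param prompts Prompt tibble.
#' @inheritParams write_fixes
#' @export
write_prompts <- function(prompts, path, tz = "America/New_York") {
  out <- tibble::tibble(participant_id = prompts$participant_id,
                        timestamp = format_ts(prompts$timestamp, tz),
                        window = prompts$window, rating = prompts$rating)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a demographics table
#' @param path CSV with header `participant_id,age,female,lives_alone`.
#' @return Tibble with those columns.
#' @export
read_demographics <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    age = readr::col_double(),
    female = readr::col_integer(),
    lives_alone = readr::col_integer()))
  if (nrow(raw) == 0) abort("demographics file is empty")
  raw
}

#' Assemble a pipeline configuration
#'
#' Bundles the cohort, feature and model tunables together with the seed
#' and optional input paths. When `fixes_path` is `NULL` the pipeline
#' simulates a cohort; otherwise it reads fixes, prompts and
#' demographics from the given CSVs. The resolved configuration is
#' serialised (YAML) next to every output so results are reproducible
#' from config + seed.
#'
#' @param cohort A [cohort_config()].
#' @param params A [feature_params()].
#' @param grand Grand-mean convention for centring.
#' @param min_answered Minimum answered prompts per usable pain day.
#' @param fixes_path,prompts_path,demographics_path Optional input CSVs.
#' @param use_true_homes Use ground-truth homes when simulating (default
#'   FALSE: homes are estimated from overnight fixes as they would be on
#'   real data).
#' @param seed Pipeline seed (applied to the cohort config when simulating).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            params = feature_params(),
                            grand = "person",
                            min_answered = 1L,
                            fixes_path = NULL, prompts_path = NULL,
                            demographics_path = NULL,
                            use_true_homes = FALSE,
                            seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, params = params, grand = grand,
                 min_answered = as.integer(min_answered),
                 fixes_path = fixes_path, prompts_path = prompts_path,
                 demographics_path = demographics_path,
                 use_true_homes = isTRUE(use_true_homes)),
            class = "pipeline_config")
}

#' Run the full simulate/ingest -> extract -> aggregate -> model pipeline
#'
#' Executes every stage and writes `features.csv`, `pain_days.csv`,
#' `panel.csv`, `model_results.csv`, `report.md` and the resolved
#' `config.yaml` (plus the simulated inputs and ground truth when no
#' input files are given) into `out_dir`. Stage failures abort with the
#' failing stage named. Row counts are logged per stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage outputs and paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tz <- config$cohort$tz
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  simulated <- is.null(config$fixes_path)
  if (simulated) {
    cohort <- stage("simulate", generate_cohort(config$cohort))
    fixes <- cohort$fixes
    prompts <- cohort$prompts
    demographics <- cohort$demographics
    write_fixes(fixes, file.path(out_dir, "fixes.csv"), tz = tz)
    write_prompts(prompts, file.path(out_dir, "prompts.csv"), tz = tz)
    readr::write_csv(demographics, file.path(out_dir, "demographics.csv"))
    gt <- dplyr::left_join(cohort$ground_truth$days,
                           cohort$ground_truth$participants,
                           by = "participant_id")
    readr::write_csv(gt, file.path(out_dir, "ground_truth.csv"))
    homes <- if (config$use_true_homes) {
      cohort$ground_truth$participants[c("participant_id", "home_lat", "home_lon")]
    } else {
      stage("estimate-homes", estimate_home(fixes, config$params))
    }
  } else {
    fixes <- stage("read-fixes", read_fixes(config$fixes_path, tz = tz))
    prompts <- stage("read-prompts", read_prompts(config$prompts_path, tz = tz))
    demographics <- stage("read-demographics",
                          read_demographics(config$demographics_path))
    homes <- stage("estimate-homes", estimate_home(fixes, config$params))
  }
  say("input: %d fixes, %d prompts, %d participants",
      nrow(fixes), nrow(prompts), nrow(demographics))

  features <- stage("extract", extract_features(fixes, homes, config$params))
  say("extract: %d participant-days (%d valid)", nrow(features),
      sum(features$valid))
  readr::write_csv(features, file.path(out_dir, "features.csv"))

  pain_days <- stage("pain", aggregate_daily_pain(
    prompts, min_answered = config$min_answered, tz = tz))
  say("pain: %d pain-days (response rate %.2f)", nrow(pain_days),
      attr(pain_days, "response_rate"))
  readr::write_csv(pain_days, file.path(out_dir, "pain_days.csv"))

  panel <- stage("panel", build_panel(features, pain_days, demographics))
  say("panel: %d usable participant-days", nrow(panel))
  readr::write_csv(panel, file.path(out_dir, "panel.csv"))

  results <- stage("analyze", fit_all_features(panel, grand = config$grand))
  readr::write_csv(results, file.path(out_dir, "model_results.csv"))

  report <- c("# Pain and life-space mobility: mixed-model results", "",
              sprintf("Panel: %d participant-days, %d participants.",
                      nrow(panel), length(unique(panel$participant_id))),
              "", "```", format_results_table(results), "```", "")
  writeLines(report, file.path(out_dir, "report.md"))
  yaml::write_yaml(serialize_config(config), file.path(out_dir, "config.yaml"))
  say("analyze: wrote model_results.csv and report.md to %s", out_dir)

  invisible(list(fixes = fixes, prompts = prompts,
                 demographics = demographics, homes = homes,
                 features = features, pain_days = pain_days, panel = panel,
                 results = results, out_dir = out_dir))
}

serialize_config <- function(config) {
  list(cohort = lapply(unclass(config$cohort), function(v)
         if (inherits(v, "Date")) as.character(v) else v),
       params = unclass(config$params),
       grand = config$grand,
       min_answered = config$min_answered,
       fixes_path = config$fixes_path,
       prompts_path = config$prompts_path,
       demographics_path = config$demographics_path,
       use_true_homes = config$use_true_homes,
       package_version = as.character(utils::packageVersion("lifespace")))
}
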