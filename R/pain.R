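#' Label a day's mean pain as low or high
#'
#' Day-level pain means are dichotomised at 2 on the 11-point box scale:
#' low pain below 2, high pain at 2 or above.
#'
#' @param mean_pain Numeric in \[0, 10\] (NA allowed, giving NA).
#' @return Character vector of "low"/"high" (NA preserved).
#' @export
#' @examples
#' label_pain_group(c(0, 1.99, 2, 5))
label_pain_group <- function(mean_pain) {
  ok <- is.na(mean_pain) | (mean_pain >= 0 & mean_pain <= 10)
  if (!all(ok)) abort("`mean_pain` must lie in [0, 10]")
  ifelse(is.na(mean_pain), NA_character_,
         ifelse(mean_pain < 2, "low", "high"))
}

#' Aggregate pain prompts to the day level
#'
#' Averages the answered prompt ratings of each participant-day (up to
#' one answered prompt per morning/afternoon/evening window). Days with
#' no answered prompt get a missing mean and are excluded downstream.
#' The overall answered-prompt rate is attached as attribute
#' `response_rate`.
#'
#' @param prompts Tibble with `participant_id`, `timestamp` (POSIXct),
#'   `window` ("morning"/"afternoon"/"evening"), `rating` (integer 0-10
#'   or NA for an unanswered prompt), and optionally `local_date`.
#' @param min_answered Minimum answered prompts for a usable day mean
#'   (default 1; higher values set the mean to NA on thinner days).
#' @param tz Timezone for day bucketing when `local_date` is absent.
#' @return Tibble `participant_id`, `local_date`, `mean_pain`,
#'   `n_answered`, `group` ("low"/"high"/NA).
#' @export
aggregate_daily_pain <- function(prompts, min_answered = 1L,
                                 tz = "America/New_York") {
  need <- c("participant_id", "timestamp", "window", "rating")
  if (!all(need %in% names(prompts))) {
    abort(paste("`prompts` must contain columns:", paste(need, collapse = ", ")))
  }
  bad <- which(!is.na(prompts$rating) &
                 (prompts$rating < 0 | prompts$rating > 10))
  if (length(bad)) {
    abort(paste("ratings outside 0-10 at row(s):", paste(bad, collapse = ", ")))
  }
  if (!"local_date" %in% names(prompts)) {
    prompts$local_date <- as.Date(format(prompts$timestamp, tz = tz))
  }
  answered <- prompts[!is.na(prompts$rating), ]
  dup <- duplicated(answered[c("participant_id", "local_date", "window")])
  if (any(dup)) {
    d <- answered[dup, ]
    abort(paste0("more than one answered prompt in the same window: ",
                 paste(sprintf("%s %s %s", d$participant_id, d$local_date,
                               d$window), collapse = "; ")))
  }
  out <- prompts |>
    dplyr::group_by(.data$participant_id, .data$local_date) |>
    dplyr::summarise(
      mean_pain = if (sum(!is.na(.data$rating)) >= min_answered)
        mean(.data$rating, na.rm = TRUE) else NA_real_,
      n_answered = sum(!is.na(.data$rating)),
      .groups = "drop") |>
    dplyr::mutate(group = label_pain_group(.data$mean_pain))
  attr(out, "response_rate") <- mean(!is.na(prompts$rating))
  out
}
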