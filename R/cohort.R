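#' Configuration for the synthetic smartwatch cohort
#'
#' Defaults reproduce the study conditions the pipeline is designed for:
#' 19 community-dwelling older adults (age ~ N(73.1, 4.8), 68% female,
#' 21% living alone) wearing the device for N(13.16, 2.94) days (rounded,
#' floored at 1), GPS fixes every 15 minutes, three pain prompts per day
#' answered with probability 0.82, and pain parameters calibrated so that
#' about 40% of day-mean pain values reach 2 or more on the 0-10 box
#' scale. Mobility is home-anchored: overnight fixes sit at home, and
#' daytime travel consists of out-and-back trips whose farthest distance
#' responds linearly to between- and within-person pain.
#'
#' @param n_participants Number of participants (>= 2).
#' @param mean_days,sd_days Wear-period distribution in days.
#' @param fix_interval GPS sampling interval in minutes (must divide 1440).
#' @param prompt_response_rate Probability a prompt is answered.
#' @param prompt_jitter Add prompt-level rounding jitter of -1/0/+1 points
#'   (probabilities 0.25/0.5/0.25, clamped to 0-10)? Disable to study
#'   estimator behaviour with an error-free pain measure.
#' @param pain_grand_mean,pain_between_sd,pain_within_sd Pain-process
#'   parameters, points on the 0-10 scale.
#' @param beta_within,beta_between Named per-feature effect maps in
#'   feature units per pain point. Effects are imposed on the
#'   `excursion_size` entry (the farthest daily trip distance); the other
#'   nine features respond geometrically.
#' @param base_mobility_mean,base_mobility_sd Between-person distribution
#'   of the pain-free daily farthest-trip distance, km.
#' @param mobility_day_sd Day-to-day noise on the intended trip
#'   distance, km.
#' @param gps_noise_sd GPS measurement noise per axis, metres.
#' @param age_mean,age_sd,prop_female,prop_live_alone Demographics.
#' @param region_center Named vector `c(lat=, lon=)`; homes are scattered
#'   within ~0.15 degrees of it.
#' @param tz Timezone of the cohort.
#' @param start_date First wear day (local civil date).
#' @param seed Integer RNG seed; identical configs give identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 19L,
                          mean_days = 13.16, sd_days = 2.94,
                          fix_interval = 15,
                          prompt_response_rate = 0.82,
                          prompt_jitter = TRUE,
                          pain_grand_mean = 1.40,
                          pain_between_sd = 1.2,
                          pain_within_sd = 1.0,
                          beta_within = c(excursion_size = -3.06),
                          beta_between = c(excursion_size = -3.79),
                          base_mobility_mean = 20,
                          base_mobility_sd = 4.5,
                          mobility_day_sd = 2,
                          gps_noise_sd = 10,
                          age_mean = 73.1, age_sd = 4.8,
                          prop_female = 0.68, prop_live_alone = 0.21,
                          region_center = c(lat = 29.65, lon = -82.33),
                          tz = "America/New_York",
                          start_date = as.Date("2023-01-09"),
                          seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              mean_days = mean_days, sd_days = sd_days,
              fix_interval = fix_interval,
              prompt_response_rate = prompt_response_rate,
              prompt_jitter = isTRUE(prompt_jitter),
              pain_grand_mean = pain_grand_mean,
              pain_between_sd = pain_between_sd,
              pain_within_sd = pain_within_sd,
              beta_within = beta_within, beta_between = beta_between,
              base_mobility_mean = base_mobility_mean,
              base_mobility_sd = base_mobility_sd,
              mobility_day_sd = mobility_day_sd,
              gps_noise_sd = gps_noise_sd,
              age_mean = age_mean, age_sd = age_sd,
              prop_female = prop_female, prop_live_alone = prop_live_alone,
              region_center = region_center, tz = tz,
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  num <- cfg[c("mean_days", "sd_days", "fix_interval", "prompt_response_rate",
               "pain_grand_mean", "pain_between_sd", "pain_within_sd",
               "base_mobility_mean", "base_mobility_sd", "mobility_day_sd",
               "gps_noise_sd", "age_mean", "age_sd", "prop_female",
               "prop_live_alone")]
  if (!all(vapply(num, function(v) is.numeric(v) && all(is.finite(v)), TRUE)) ||
      !all(is.finite(cfg$beta_within)) || !all(is.finite(cfg$beta_between)) ||
      !all(is.finite(cfg$region_center))) {
    abort("cohort_config: all numeric fields must be finite")
  }
  probs <- c(cfg$prompt_response_rate, cfg$prop_female, cfg$prop_live_alone)
  if (any(probs < 0 | probs > 1)) abort("cohort_config: probabilities must lie in [0, 1]")
  sds <- c(cfg$sd_days, cfg$pain_between_sd, cfg$pain_within_sd,
           cfg$base_mobility_sd, cfg$mobility_day_sd, cfg$gps_noise_sd,
           cfg$age_sd)
  if (any(sds < 0)) abort("cohort_config: standard deviations must be >= 0")
  if (cfg$fix_interval <= 0 || 1440 %% cfg$fix_interval != 0) {
    abort("cohort_config: fix_interval must be positive and divide 1440 minutes")
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 2) {
    abort("cohort_config: n_participants must be >= 2 (between-person effects are undefined otherwise)")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d participants, ~%.1f (SD %.1f) wear days, fixes every %g min,\n  response rate %.2f, pain N(%.2f; between %.2f, within %.2f), beta_within[excursion_size] = %.2f, seed %d\n",
    x$n_participants, x$mean_days, x$sd_days, x$fix_interval,
    x$prompt_response_rate, x$pain_grand_mean, x$pain_between_sd,
    x$pain_within_sd, x$beta_within[["excursion_size"]], x$seed))
  invisible(x)
}

# Smallest trip distance that clears the 100 m home geofence comfortably.
MIN_TRIP_KM <- 0.1

#' Generate a synthetic smartwatch cohort
#'
#' Simulates GPS fixes, pain prompts and demographics with known
#' ground-truth effects. Each participant gets a home location and a
#' latent person-mean pain; each day a latent day pain
#' `clamp(round(mu_i + eps), 0, 10)` and an intended farthest-trip
#' distance `max(0, base_i + beta_between * (mu_i - grand_mean) +
#' beta_within * (p_day - mu_i) + noise)`. Days are built as 0-3
#' out-and-back trips from home sampled on the fix grid, with dwell
#' segments at trip endpoints and home fixes overnight (8 PM-8 AM window
#' is home-anchored via the trip placement); GPS noise is added to every
#' fix. Three prompts per day (morning/afternoon/evening) carry the day
#' pain, each dropped with probability `1 - prompt_response_rate`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `lifespace_cohort`: `fixes` (participant_id,
#'   timestamp, lat, lon, local_date), `prompts` (participant_id,
#'   timestamp, local_date, window, rating), `demographics`
#'   (participant_id, age, female, lives_alone), and `ground_truth`
#'   (list: `participants` with homes, person-mean pain and base
#'   mobility; `days` with latent pain, intended and realised excursion
#'   distance and trip count; `params`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))

  home_lat <- config$region_center[["lat"]] + runif(n, -0.15, 0.15)
  home_lon <- config$region_center[["lon"]] + runif(n, -0.15, 0.15)
  age <- round(rnorm(n, config$age_mean, config$age_sd))
  female <- rbinom(n, 1, config$prop_female)
  lives_alone <- rbinom(n, 1, config$prop_live_alone)
  mu_pain <- rnorm(n, config$pain_grand_mean, config$pain_between_sd)
  base_mob <- rnorm(n, config$base_mobility_mean, config$base_mobility_sd)
  n_days <- pmax(1L, as.integer(round(rnorm(n, config$mean_days, config$sd_days))))

  bw <- config$beta_within[["excursion_size"]] %||% 0
  bb <- config$beta_between[["excursion_size"]] %||% 0

  slots_per_day <- as.integer(1440 / config$fix_interval)
  minute_of_day <- (seq_len(slots_per_day) - 1) * config$fix_interval
  wake_idx <- which(minute_of_day >= 480 & minute_of_day < 1200)

  fix_list <- vector("list", n)
  gt_days <- vector("list", n)
  prompt_list <- vector("list", n)

  for (i in seq_len(n)) {
    nd <- n_days[i]
    midnights <- as.POSIXct(paste(config$start_date + seq_len(nd) - 1,
                                  "00:00:00"), tz = config$tz)
    eps <- rnorm(nd, 0, config$pain_within_sd)
    p_day <- pmin(10L, pmax(0L, as.integer(round(mu_pain[i] + eps))))
    intended <- pmax(0, base_mob[i] +
                       bb * (mu_pain[i] - config$pain_grand_mean) +
                       bw * (p_day - mu_pain[i]) +
                       rnorm(nd, 0, config$mobility_day_sd))

    day_disp <- vector("list", nd)
    realized <- numeric(nd)
    trips <- integer(nd)
    for (d in seq_len(nd)) {
      bd <- build_day_displacements(intended[d], slots_per_day, wake_idx)
      day_disp[[d]] <- bd$disp
      realized[d] <- bd$realized
      trips[d] <- bd$n_trips
    }
    disp <- do.call(rbind, day_disp)
    ts <- rep(midnights, each = slots_per_day) +
      rep(minute_of_day * 60, times = nd)

    noise_km <- matrix(rnorm(2 * nrow(disp), 0, config$gps_noise_sd / 1000),
                       ncol = 2)
    ll <- unproject_local(disp[, 1] + noise_km[, 1],
                          disp[, 2] + noise_km[, 2],
                          home_lat[i], home_lon[i])
    fix_list[[i]] <- tibble::tibble(
      participant_id = ids[i],
      timestamp = ts,
      lat = ll[, 1], lon = ll[, 2],
      local_date = rep(config$start_date + seq_len(nd) - 1,
                       each = slots_per_day))

    # 3 prompts/day at random times in the 8-12 / 12-16 / 16-20 windows
    win_start <- rep(c(8, 12, 16), times = nd) * 3600
    pr_ts <- rep(midnights, each = 3) + win_start +
      runif(3 * nd, 0, 4 * 3600 - 1)
    day_pain_rep <- rep(p_day, each = 3)
    rating <- day_pain_rep
    if (config$prompt_jitter) {
      jit <- sample(c(-1L, 0L, 1L), 3 * nd, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25))
      rating <- pmin(10L, pmax(0L, rating + jit))
    }
    answered <- runif(3 * nd) < config$prompt_response_rate
    rating[!answered] <- NA_integer_
    prompt_list[[i]] <- tibble::tibble(
      participant_id = ids[i],
      timestamp = pr_ts,
      local_date = rep(config$start_date + seq_len(nd) - 1, each = 3),
      window = rep(c("morning", "afternoon", "evening"), times = nd),
      rating = as.integer(rating))

    gt_days[[i]] <- tibble::tibble(
      participant_id = ids[i],
      local_date = config$start_date + seq_len(nd) - 1,
      latent_pain = as.integer(p_day),
      intended_excursion_km = intended,
      true_excursion_km = realized,
      n_trips = trips)
  }

  structure(
    list(fixes = dplyr::bind_rows(fix_list),
         prompts = dplyr::bind_rows(prompt_list),
         demographics = tibble::tibble(participant_id = ids, age = age,
                                       female = female,
                                       lives_alone = lives_alone),
         ground_truth = list(
           participants = tibble::tibble(
             participant_id = ids, home_lat = home_lat, home_lon = home_lon,
             mu_pain = mu_pain, base_mobility_km = base_mob,
             n_days = n_days),
           days = dplyr::bind_rows(gt_days),
           params = list(beta_within = bw, beta_between = bb,
                         grand_mean = config$pain_grand_mean)),
         config = config),
    class = "lifespace_cohort")
}

# Build one day's fix displacements (km from home) on the slot grid.
# Trips are piecewise-linear out-and-back rays with a dwell at the
# endpoint; the farthest trip reaches exactly `target_km`. Returns the
# displacement matrix, realised farthest distance, and trip count.
build_day_displacements <- function(target_km, slots_per_day, wake_idx) {
  disp <- matrix(0, slots_per_day, 2)
  if (target_km < MIN_TRIP_KM) {
    return(list(disp = disp, realized = 0, n_trips = 0L))
  }
  n_wake <- length(wake_idx)
  n_trips <- sample(1:3, 1, prob = c(0.30, 0.45, 0.25))
  repeat {
    block <- n_wake %/% n_trips
    cap_out <- (block - 3L) %/% 2L  # 2 home margins + >=2 dwell slots
    if (n_trips == 1L || ceiling(target_km / 10) <= cap_out) break
    n_trips <- n_trips - 1L
  }
  dists <- c(target_km,
             if (n_trips > 1) pmax(MIN_TRIP_KM,
                                   runif(n_trips - 1, 0.25, 0.9) * target_km))
  for (j in seq_len(n_trips)) {
    d <- dists[j]
    avail <- block - 2L                     # keep a home fix at both ends
    cap <- max(1L, (avail - 1L) %/% 2L)
    n_out <- min(cap, max(ceiling(d / 10), min(ceiling(d / 3.5), cap)))
    n_dwell <- min(avail - (2L * n_out - 1L), sample(2:5, 1))
    len <- 2L * n_out - 1L + n_dwell
    offset <- if (avail > len) sample.int(avail - len, 1) - 1L else 0L
    theta <- runif(1, 0, 2 * pi)
    fracs <- c(seq_len(n_out) / n_out, rep(1, n_dwell),
               rev(seq_len(n_out - 1)) / n_out)
    rows <- wake_idx[(j - 1L) * block + 1L + offset + seq_len(len)]
    disp[rows, ] <- (fracs * d) %o% c(cos(theta), sin(theta))
  }
  list(disp = disp, realized = max(dists), n_trips = n_trips)
}

#' @export
print.lifespace_cohort <- function(x, ...) {
  cat(sprintf("<lifespace_cohort> %d participants, %d fixes, %d prompts (seed %d)\n",
              nrow(x$demographics), nrow(x$fixes), nrow(x$prompts),
              x$config$seed))
  invisible(x)
}

#' Remove all fixes for a random subset of participants
#'
#' Emulates missing-at-random device failures: the chosen fraction of
#' participants lose their entire GPS stream (their prompts and
#' demographics are untouched). Deterministic under `seed`.
#'
#' @param fixes Fix tibble.
#' @param missing_participant_fraction Fraction in \[0, 1) of
#'   participants to drop.
#' @param seed Integer seed.
#' @return The fix tibble without the dropped participants.
#' @export
drop_gps_days <- function(fixes, missing_participant_fraction, seed = 1L) {
  if (!is.numeric(missing_participant_fraction) ||
      missing_participant_fraction < 0 || missing_participant_fraction >= 1) {
    abort("`missing_participant_fraction` must lie in [0, 1)")
  }
  if (missing_participant_fraction == 0) return(fixes)
  ids <- unique(fixes$participant_id)
  n_drop <- round(length(ids) * missing_participant_fraction)
  if (n_drop == 0) return(fixes)
  set.seed(seed)
  drop <- sample(ids, n_drop)
  fixes[!fixes$participant_id %in% drop, ]
}
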