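# Shared fixtures, all generated in code.

HOME <- c(lat = 29.65, lon = -82.33)

# A day of fixes at given planar displacements (km east/north of home).
make_day <- function(x_km, y_km, home = HOME, start = "2023-01-09 00:00:00",
                     tz = "America/New_York", interval_min = 15) {
  ll <- unproject_local(x_km, y_km, home[["lat"]], home[["lon"]])
  n <- length(x_km)
  tibble::tibble(
    participant_id = "P001",
    timestamp = as.POSIXct(start, tz = tz) + (seq_len(n) - 1) * interval_min * 60,
    lat = ll[, 1], lon = ll[, 2],
    local_date = as.Date(substr(start, 1, 10)))
}

# All-at-home day: n fixes with sub-10 m jitter around home.
make_home_day <- function(n = 96, jitter_m = 8, seed = 1) {
  set.seed(seed)
  make_day(runif(n, -jitter_m, jitter_m) / 1000,
           runif(n, -jitter_m, jitter_m) / 1000)
}

# A pool of ~1000 generated participant-days with homes and ground truth,
# built once per test run and reused across files.
day_pool_env <- new.env(parent = emptyenv())

get_day_pool <- function() {
  if (is.null(day_pool_env$pool)) {
    co <- generate_cohort(cohort_config(n_participants = 80, seed = 424242))
    fx <- co$fixes
    homes <- co$ground_truth$participants[c("participant_id", "home_lat",
                                            "home_lon")]
    key <- paste(fx$participant_id, fx$local_date)
    idx <- split(seq_len(nrow(fx)), factor(key, levels = unique(key)))
    idx <- idx[seq_len(min(1000L, length(idx)))]
    hl <- homes$home_lat[match(fx$participant_id, homes$participant_id)]
    ho <- homes$home_lon[match(fx$participant_id, homes$participant_id)]
    days <- lapply(idx, function(ix) {
      list(tsn = as.numeric(fx$timestamp[ix]), lat = fx$lat[ix],
           lon = fx$lon[ix], home_lat = hl[ix[1]], home_lon = ho[ix[1]],
           participant_id = fx$participant_id[ix[1]],
           local_date = fx$local_date[ix[1]])
    })
    day_pool_env$pool <- list(cohort = co, homes = homes, days = days)
  }
  day_pool_env$pool
}

# Full 10-feature table for the pool (computed once).
get_pool_features <- function() {
  if (is.null(day_pool_env$features)) {
    pool <- get_day_pool()
    day_pool_env$features <- extract_features(pool$cohort$fixes, pool$homes)
  }
  day_pool_env$features
}

# Stationary fixes of a pool day, via the package's motion classifier.
stationary_of_day <- function(day, threshold = 1) {
  n <- length(day$tsn)
  if (n == 1) return(seq_len(n))
  d <- geodesic_km(day$lat[-n], day$lon[-n], day$lat[-1], day$lon[-1])
  sp <- d / (diff(day$tsn) / 3600)
  sp <- c(sp[1], sp)
  which(sp < threshold)
}

# Independent regex oracle for trip counting.
trip_oracle <- function(labels) {
  s <- paste(ifelse(labels == "home", "H", "A"), collapse = "")
  m <- gregexpr("(?<=H)A+(?=H)", s, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# Independent MVEE oracle: cluster::ellipsoidhull (Titterington ascent),
# area of the 2-D ellipsoid hull.
oracle_ellipse_area <- function(pts) {
  eh <- cluster::ellipsoidhull(pts, tol = 1e-9, maxit = 100000)
  pi * eh$d2 * sqrt(det(eh$cov))
}

run_recovery_rep <- function(n_participants, n_days, beta_within, seed,
                             jitter = FALSE) {
  cfg <- cohort_config(n_participants = n_participants, mean_days = n_days,
                       sd_days = 0, prompt_jitter = jitter,
                       beta_within = c(excursion_size = beta_within),
                       seed = seed)
  co <- generate_cohort(cfg)
  homes <- co$ground_truth$participants[c("participant_id", "home_lat",
                                          "home_lon")]
  f <- extract_features(co$fixes, homes, features = "excursion")
  pd <- aggregate_daily_pain(co$prompts)
  panel <- build_panel(f, pd, co$demographics)
  fit <- fit_feature_model(panel, "excursion_size")
  cf <- fit$coefficients[fit$coefficients$term == "pain_within", ]
  list(est = cf$estimate, lo = cf$conf.low, hi = cf$conf.high, p = cf$p)
}
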