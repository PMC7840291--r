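test_that("config validation guards the documented invariants", {
  expect_error(cohort_config(n_participants = 1), ">= 2")
  expect_error(cohort_config(prompt_response_rate = 1.2), "probabilities")
  expect_error(cohort_config(pain_within_sd = -1), "standard deviations")
  expect_error(cohort_config(mean_days = Inf), "finite")
  expect_error(cohort_config(fix_interval = 0), "fix_interval")
  expect_error(cohort_config(fix_interval = 7), "fix_interval")
})

test_that("identical configs give identical cohorts", {
  a <- generate_cohort(cohort_config(n_participants = 5, seed = 33))
  b <- generate_cohort(cohort_config(n_participants = 5, seed = 33))
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$prompts, b$prompts)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$ground_truth$days, b$ground_truth$days)
  c <- generate_cohort(cohort_config(n_participants = 5, seed = 34))
  expect_false(identical(a$fixes, c$fixes))
})

test_that("full response rate yields exactly three answered prompts per day", {
  co <- generate_cohort(cohort_config(n_participants = 4,
                                      prompt_response_rate = 1, seed = 2))
  pd <- aggregate_daily_pain(co$prompts)
  expect_true(all(pd$n_answered == 3))
  expect_equal(attr(pd, "response_rate"), 1)
})

test_that("null effects leave intended mobility unrelated to pain", {
  co <- generate_cohort(cohort_config(
    n_participants = 25, beta_within = c(excursion_size = 0),
    beta_between = c(excursion_size = 0), seed = 12))
  gt <- co$ground_truth$days
  sl <- coef(lm(intended_excursion_km ~ latent_pain, data = gt))[["latent_pain"]]
  expect_lt(abs(sl), 0.4)
})

test_that("fix streams are home-anchored on the configured grid", {
  cfg <- cohort_config(n_participants = 3, seed = 8)
  co <- generate_cohort(cfg)
  fx <- co$fixes
  # one fix every 15 minutes for each wear day
  per_day <- table(fx$participant_id, as.character(fx$local_date))
  expect_true(all(per_day[per_day > 0] == 96))
  # overnight fixes sit at home (within GPS noise)
  homes <- co$ground_truth$participants
  h <- as.integer(format(fx$timestamp, "%H", tz = cfg$tz))
  night <- fx[h < 8 | h >= 20, ]
  hl <- homes$home_lat[match(night$participant_id, homes$participant_id)]
  ho <- homes$home_lon[match(night$participant_id, homes$participant_id)]
  expect_lt(max(geodesic_km(night$lat, night$lon, hl, ho)), 0.1)
})

test_that("ground-truth excursions match the extracted feature within GPS noise", {
  pool <- get_day_pool()
  feats <- get_pool_features()
  gt <- pool$cohort$ground_truth$days
  m <- dplyr::inner_join(feats, gt, by = c("participant_id", "local_date"))
  tol_km <- 3 * pool$cohort$config$gps_noise_sd / 1000 + 0.01
  expect_lt(max(abs(m$excursion_size - m$true_excursion_km)), tol_km)
  # realised trip counts match too
  expect_equal(m$n_trips.x, as.numeric(m$n_trips.y))
})

test_that("device-failure dropout removes whole participants, deterministically", {
  co <- generate_cohort(cohort_config(n_participants = 28, seed = 4))
  expect_identical(drop_gps_days(co$fixes, 0), co$fixes)
  kept <- drop_gps_days(co$fixes, 9 / 28, seed = 6)
  expect_equal(length(unique(kept$participant_id)), 19)
  # dropped participants lose every fix
  gone <- setdiff(unique(co$fixes$participant_id), unique(kept$participant_id))
  expect_length(gone, 9)
  expect_identical(drop_gps_days(co$fixes, 9 / 28, seed = 6), kept)
  expect_error(drop_gps_days(co$fixes, 1), "\\[0, 1\\)")
})
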