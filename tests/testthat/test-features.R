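test_that("motion classification applies the backward time derivative", {
  # identical fixes: all stationary with zero speed
  d <- make_day(rep(0, 5), rep(0, 5))
  m <- classify_motion(d$timestamp, d$lat, d$lon)
  expect_equal(m$speed_kmh, rep(0, 5))
  expect_true(all(m$label == "stationary"))
  # 1 km in 30 min = 2 km/h: moving; first fix inherits the second's speed
  d2 <- make_day(c(0, 1), c(0, 0), interval_min = 30)
  m2 <- classify_motion(d2$timestamp, d2$lat, d2$lon)
  expect_equal(m2$speed_kmh, c(2, 2), tolerance = 1e-4)
  expect_true(all(m2$label == "moving"))
  # single fix: stationary
  d3 <- make_day(0.5, 0.5)
  expect_equal(classify_motion(d3$timestamp, d3$lat, d3$lon)$label,
               "stationary")
  expect_error(classify_motion(rep(d$timestamp[1], 2), c(0, 0), c(0, 0)),
               "strictly increasing")
})

test_that("excursion features reproduce the out-and-back day", {
  # home -> 5 km east -> home
  d <- make_day(c(0, 5, 0), c(0, 0, 0))
  ex <- excursion_features(d$lat, d$lon, HOME[["lat"]], HOME[["lon"]])
  expect_equal(ex$excursion_size, 5, tolerance = 1e-3)
  expect_equal(ex$excursion_span, 0) # only one away fix
  expect_equal(ex$total_distance, 10, tolerance = 1e-3)
})

test_that("homebound day gives near-zero excursion features", {
  d <- make_home_day()
  ex <- excursion_features(d$lat, d$lon, HOME[["lat"]], HOME[["lon"]])
  expect_lt(ex$excursion_size, 0.02)
  expect_equal(ex$excursion_span, 0)
  expect_lt(ex$total_distance, 2)
})

test_that("home/away labelling is inclusive at the radius and order-invariant", {
  pts <- make_day(c(0, 0.099, 0.101, 0.100), c(0, 0, 0, 0))
  lab <- home_away_labels(pts$lat, pts$lon, HOME[["lat"]], HOME[["lon"]])
  expect_equal(lab, c("home", "home", "away", "home"))
  perm <- c(3, 1, 4, 2)
  expect_equal(home_away_labels(pts$lat[perm], pts$lon[perm],
                                HOME[["lat"]], HOME[["lon"]]), lab[perm])
})

test_that("trip counting matches the definitional sequences and regex oracle", {
  expect_equal(count_trips(c("home", "away", "away", "home")), 1)
  expect_equal(count_trips(rep("home", 6)), 0)
  expect_equal(count_trips(c("home", "away", "home", "away", "away", "home")), 2)
  # away runs truncated by the day boundary are not trips
  expect_equal(count_trips(c("away", "home")), 0)
  expect_equal(count_trips(c("home", "away")), 0)
  expect_equal(count_trips("away"), 0)
  set.seed(5)
  for (r in 1:500) {
    lab <- sample(c("home", "away"), sample(1:30, 1), replace = TRUE,
                  prob = c(runif(1, 0.2, 0.8), 1))
    expect_equal(count_trips(lab), trip_oracle(lab))
  }
})

test_that("homestay is the home-fix fraction", {
  expect_equal(homestay(rep("home", 10)), 1)
  expect_equal(homestay(rep("away", 7)), 0)
  expect_equal(homestay(c("home", "away", "home", "away")), 0.5)
})

test_that("dwell entropy has its closed forms and bounds", {
  expect_equal(dwell_entropy(1), 0)
  expect_equal(dwell_entropy(c(0.5, 0.5)), log(2))
  expect_equal(dwell_entropy(rep(0.25, 4)), log(4))
  expect_equal(dwell_entropy(c(0.5, 0.5), base = 2), 1)
  expect_error(dwell_entropy(c(0, 1)), "\\(0, 1\\]")
  expect_error(dwell_entropy(c(0.3, 0.3)), "sum to 1")
  set.seed(8)
  for (r in 1:50) {
    k <- sample(1:6, 1)
    p <- rgamma(k, 1) + 0.01
    p <- p / sum(p)
    h <- dwell_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
})

test_that("adaptive k-means satisfies the inclusion radius and finds groups", {
  # all fixes within 500 m of their centroid: one cluster
  d <- make_home_day(n = 20)
  cl <- adaptive_kmeans(d$lat, d$lon)
  expect_equal(cl$k, 1)
  expect_equal(cl$dwell_share, 1)
  # two tight groups 5 km apart: two clusters matching group identity
  x <- c(rnorm(5, 0, 0.01), rnorm(5, 5, 0.01))
  d2 <- make_day(x, rep(0, 10))
  cl2 <- adaptive_kmeans(d2$lat, d2$lon)
  expect_equal(cl2$k, 2)
  expect_equal(length(unique(cl2$assignment[1:5])), 1)
  expect_equal(length(unique(cl2$assignment[6:10])), 1)
  expect_false(cl2$assignment[1] == cl2$assignment[6])
  expect_equal(sum(cl2$dwell_share), 1)
  # determinism
  cl3 <- adaptive_kmeans(d2$lat, d2$lon)
  expect_identical(cl2$assignment, cl3$assignment)
})

test_that("homebound day composes to the limit-case feature record", {
  d <- make_home_day()
  f <- extract_daily_features(d$timestamp, d$lat, d$lon,
                              HOME[["lat"]], HOME[["lon"]])
  expect_equal(f$homestay, 1)
  expect_equal(f$n_trips, 0)
  expect_equal(f$n_clusters, 1)
  expect_equal(f$entropy, 0)
  expect_lt(f$ellipse_area, 1e-3)
  expect_lt(f$excursion_size, 0.02)
  expect_true(f$valid)
  expect_named(f, c(lifespace_feature_names(), "n_fixes", "valid"))
})

test_that("short days are flagged invalid but still computed", {
  d <- make_day(c(0, 2, 0), c(0, 0, 0))
  f <- extract_daily_features(d$timestamp, d$lat, d$lon,
                              HOME[["lat"]], HOME[["lon"]])
  expect_false(f$valid)
  expect_equal(f$n_fixes, 3)
  expect_equal(f$excursion_size, 2, tolerance = 1e-3)
})

test_that("scaling away displacements never shrinks the extent features", {
  pool <- get_day_pool()
  day <- pool$days[[which.max(vapply(pool$days, function(d)
    max(geodesic_km(d$lat, d$lon, d$home_lat, d$home_lon)), 0))]]
  p <- project_local(day$lat, day$lon, day$home_lat, day$home_lon)
  base <- extract_daily_features(as.POSIXct(day$tsn, origin = "1970-01-01",
                                            tz = "UTC"),
                                 day$lat, day$lon, day$home_lat, day$home_lon,
                                 features = c("excursion", "ellipse"))
  for (c_scale in c(1.5, 2.5)) {
    ll <- unproject_local(p[, 1] * c_scale, p[, 2] * c_scale,
                          day$home_lat, day$home_lon)
    f <- extract_daily_features(as.POSIXct(day$tsn, origin = "1970-01-01",
                                           tz = "UTC"),
                                ll[, 1], ll[, 2], day$home_lat, day$home_lon,
                                features = c("excursion", "ellipse"))
    expect_gte(f$excursion_size, base$excursion_size)
    expect_gte(f$excursion_span, base$excursion_span)
    expect_gte(f$total_distance, base$total_distance)
    expect_gte(f$ellipse_major, base$ellipse_major)
  }
})

test_that("extract_features validates input and derives local dates", {
  pool <- get_day_pool()
  fx <- pool$cohort$fixes[1:200, ]
  expect_error(extract_features(fx[0, ], pool$homes), "empty")
  expect_error(extract_features(fx["lat"], pool$homes), "must contain")
  dup <- rbind(fx, fx[1, ])
  expect_error(extract_features(dup, pool$homes), "duplicate")
  # without local_date the same result is derived from tz
  f1 <- extract_features(fx, pool$homes)
  f2 <- extract_features(fx[setdiff(names(fx), "local_date")], pool$homes)
  expect_equal(f1, f2)
})

test_that("home estimation recovers the true home from overnight fixes", {
  pool <- get_day_pool()
  ids <- pool$homes$participant_id[1:4]
  fx <- pool$cohort$fixes[pool$cohort$fixes$participant_id %in% ids, ]
  est <- estimate_home(fx)
  truth <- pool$homes[match(est$participant_id, pool$homes$participant_id), ]
  err_m <- 1000 * geodesic_km(est$home_lat, est$home_lon,
                              truth$home_lat, truth$home_lon)
  expect_lt(max(err_m), 50)
})
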