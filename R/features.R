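#' Feature-extraction parameters
#'
#' Tunables for daily life-space feature extraction, with the study
#' defaults: a 100 m home geofence, a 500 m cluster-inclusion radius, a
#' 1 km/h stationary/moving speed threshold, natural-log entropy, and a
#' minimum of 10 fixes for a day to be flagged valid.
#'
#' @param home_radius_m Home geofence radius in metres (inclusive).
#' @param cluster_radius_m Cluster-inclusion radius in metres: every
#'   stationary fix must lie within this distance of its centroid.
#' @param speed_threshold_kmh Speed below which a fix is stationary.
#' @param entropy_base Logarithm base for dwell entropy (default natural).
#' @param min_fixes_per_day Fewer fixes than this flags the day invalid
#'   (features are still computed).
#' @param mvee_tol,mvee_max_iter Convergence controls passed to
#'   [min_enclosing_ellipse()].
#' @param kmeans_seed Seed for the adaptive k-means stage.
#' @param tz Timezone used to bucket fixes into local civil days when the
#'   fix table carries no `local_date` column.
#' @return A list of class `feature_params`.
#' @export
feature_params <- function(home_radius_m = 100,
                           cluster_radius_m = 500,
                           speed_threshold_kmh = 1,
                           entropy_base = exp(1),
                           min_fixes_per_day = 10L,
                           mvee_tol = 1e-7,
                           mvee_max_iter = 10000L,
                           kmeans_seed = 1L,
                           tz = "America/New_York") {
  stopifnot(home_radius_m >= 0, cluster_radius_m > 0,
            speed_threshold_kmh > 0, entropy_base > 0, entropy_base != 1,
            min_fixes_per_day >= 1)
  structure(list(home_radius_m = home_radius_m,
                 cluster_radius_m = cluster_radius_m,
                 speed_threshold_kmh = speed_threshold_kmh,
                 entropy_base = entropy_base,
                 min_fixes_per_day = as.integer(min_fixes_per_day),
                 mvee_tol = mvee_tol,
                 mvee_max_iter = as.integer(mvee_max_iter),
                 kmeans_seed = as.integer(kmeans_seed),
                 tz = tz),
            class = "feature_params")
}

#' Classify fixes as stationary or moving
#'
#' Speed at each fix is the backward time derivative: the great-circle
#' distance from the previous fix divided by elapsed time. The first fix
#' of a day has no backward interval and inherits the second fix's speed;
#' a single-fix day has speed 0. A fix is stationary when its speed is
#' below `speed_threshold_kmh` (default 1 km/h), otherwise moving.
#'
#' @param timestamps POSIXct, strictly increasing.
#' @param lat,lon Numeric, degrees.
#' @param speed_threshold_kmh Threshold in km/h.
#' @return A tibble with `speed_kmh` and `label` ("stationary"/"moving").
#' @export
classify_motion <- function(timestamps, lat, lon, speed_threshold_kmh = 1) {
  n <- length(timestamps)
  stopifnot(length(lat) == n, length(lon) == n, n >= 1)
  if (n == 1) {
    speed <- 0
  } else {
    dt_h <- diff(as.numeric(timestamps)) / 3600
    if (any(dt_h <= 0)) abort("timestamps must be strictly increasing")
    d <- geodesic_km(lat[-n], lon[-n], lat[-1], lon[-1])
    speed <- c(NA_real_, d / dt_h)
    speed[1] <- speed[2]
  }
  tibble::tibble(
    speed_kmh = speed,
    label = ifelse(speed < speed_threshold_kmh, "stationary", "moving"))
}

#' Label fixes as home or away
#'
#' A fix is "home" when its great-circle distance to the home location is
#' at most `home_radius_m` (inclusive), otherwise "away".
#'
#' @param lat,lon Fix coordinates, degrees.
#' @param home_lat,home_lon Home coordinates, degrees.
#' @param home_radius_m Geofence radius in metres.
#' @return Character vector of "home"/"away" labels.
#' @export
home_away_labels <- function(lat, lon, home_lat, home_lon, home_radius_m = 100) {
  d_km <- geodesic_km(lat, lon, home_lat, home_lon)
  ifelse(d_km * 1000 <= home_radius_m, "home", "away")
}

#' Count home -> away -> home trips
#'
#' A trip is a maximal run of "away" labels immediately preceded and
#' followed by a "home" label within the same day. Away runs truncated by
#' the start or end of the day are not counted.
#'
#' @param labels Character vector of "home"/"away" labels, in time order.
#' @return Integer trip count.
#' @export
#' @examples
#' count_trips(c("home", "away", "away", "home")) # 1
count_trips <- function(labels) {
  stopifnot(length(labels) >= 1, all(labels %in% c("home", "away")))
  r <- rle(labels)
  k <- length(r$values)
  if (k < 3) return(0L)
  away <- which(r$values == "away")
  sum(away > 1 & away < k)
}

#' Homestay fraction
#'
#' The ratio of fixes within the home radius to the total number of
#' fixes: 1 when the whole day is spent at home, 0 when none of it is.
#'
#' @param labels Character vector of "home"/"away" labels.
#' @return Fraction in \[0, 1\].
#' @export
homestay <- function(labels) {
  stopifnot(length(labels) >= 1, all(labels %in% c("home", "away")))
  mean(labels == "home")
}

#' Dwell-time entropy across location clusters
#'
#' Shannon entropy `H = -sum(p_i * log(p_i))` of the proportions of
#' stationary time spent in each cluster. Zero when all time is spent at
#' a single location; at most `log(k)` for `k` clusters. Proportions must
#' be strictly positive (clusters are only created when occupied) and sum
#' to one.
#'
#' @param p Numeric vector of dwell proportions, each in (0, 1], summing to 1.
#' @param base Logarithm base (default natural: entropy in nats).
#' @return Entropy value (>= 0).
#' @export
#' @examples
#' dwell_entropy(c(0.5, 0.5)) # log(2)
dwell_entropy <- function(p, base = exp(1)) {
  if (!is.numeric(p) || length(p) < 1 || anyNA(p)) {
    abort("`p` must be a numeric vector without missing values")
  }
  if (any(p <= 0) || any(p > 1)) {
    abort("dwell proportions must lie in (0, 1]: zero-share clusters are not allowed")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort("dwell proportions must sum to 1 (tolerance 1e-9)")
  }
  -sum(p * log(p, base = base))
}

#' Excursion features of one day
#'
#' Excursion size is the farthest great-circle distance from home reached
#' during the day; excursion span the farthest pairwise distance among
#' away-from-home fixes (0 with fewer than two such fixes); total
#' distance the sum of consecutive fix-to-fix distances.
#'
#' @param lat,lon Fix coordinates in time order, degrees.
#' @param home_lat,home_lon Home coordinates.
#' @param home_radius_m Radius defining "away from home" for the span.
#' @param d_home_km Optional precomputed distances from home (km).
#' @return A list with `excursion_size`, `excursion_span`,
#'   `total_distance`, all in km.
#' @export
excursion_features <- function(lat, lon, home_lat, home_lon,
                               home_radius_m = 100, d_home_km = NULL) {
  n <- length(lat)
  stopifnot(n >= 1, length(lon) == n)
  if (is.null(d_home_km)) d_home_km <- geodesic_km(lat, lon, home_lat, home_lon)
  size <- max(d_home_km)
  total <- if (n == 1) 0 else sum(geodesic_km(lat[-n], lon[-n], lat[-1], lon[-1]))
  away <- which(d_home_km * 1000 > home_radius_m)
  span <- if (length(away) < 2) 0 else max_pairwise_km(lat[away], lon[away])
  list(excursion_size = size, excursion_span = span, total_distance = total)
}

# Maximum pairwise great-circle distance. The maximising pair lies on the
# convex hull of the locally projected points, so only hull vertices are
# compared when the set is large.
max_pairwise_km <- function(lat, lon) {
  n <- length(lat)
  if (n > 12) {
    p <- project_local(lat, lon, mean(lat), mean(lon))
    h <- tryCatch(grDevices::chull(p[, 1], p[, 2]), error = function(e) seq_len(n))
    if (length(h) >= 2) {
      lat <- lat[h]
      lon <- lon[h]
      n <- length(h)
    }
  }
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  max(hav_km(lat[i], lon[i], lat[j], lon[j]))
}

# Numeric-only feature worker shared by extract_daily_features() and
# extract_features(); returns the ten features in canonical order.
day_features_core <- function(tsn, lat, lon, d_home, params, want) {
  n <- length(tsn)
  out <- rep(NA_real_, 10)

  dcons <- if (n > 1 && any(c("excursion", "cluster") %in% want)) {
    hav_km(lat[-n], lon[-n], lat[-1], lon[-1])
  } else numeric(0)

  if ("excursion" %in% want) {
    out[1] <- max(d_home)
    away <- which(d_home * 1000 > params$home_radius_m)
    out[2] <- if (length(away) < 2) 0 else max_pairwise_km(lat[away], lon[away])
    out[3] <- if (n == 1) 0 else sum(dcons)
  }
  if ("ellipse" %in% want) {
    ef <- ellipse_features(lat, lon, tol = params$mvee_tol,
                           max_iter = params$mvee_max_iter)
    out[4:6] <- c(ef$ellipse_area, ef$ellipse_minor, ef$ellipse_major)
  }
  if ("trip" %in% want) {
    home <- d_home * 1000 <= params$home_radius_m
    r <- rle(home)
    k <- length(r$values)
    out[7] <- if (k < 3) 0 else sum(!r$values[-c(1, k)])
    out[8] <- mean(home)
  }
  if ("cluster" %in% want) {
    speed <- if (n == 1) 0 else {
      s <- dcons / (diff(tsn) / 3600)
      c(s[1], s)
    }
    stat <- which(speed < params$speed_threshold_kmh)
    if (length(stat) >= 1) {
      cl <- adaptive_kmeans(lat[stat], lon[stat],
                            cluster_radius_m = params$cluster_radius_m,
                            seed = params$kmeans_seed)
      out[9] <- cl$k
      out[10] <- dwell_entropy(cl$dwell_share, base = params$entropy_base)
    } else {
      out[9] <- 0
      out[10] <- 0
    }
  }
  out
}

#' Ellipsoid-hull features of one day
#'
#' Projects the day's fixes to a local planar frame about their centroid,
#' computes the minimum-area enclosing ellipse, and returns its area and
#' axis diameters.
#'
#' @inheritParams excursion_features
#' @param tol,max_iter Passed to [min_enclosing_ellipse()].
#' @return A list with `ellipse_area` (km^2), `ellipse_minor` and
#'   `ellipse_major` (full diameters, km).
#' @export
ellipse_features <- function(lat, lon, tol = 1e-7, max_iter = 10000L) {
  stopifnot(length(lat) >= 1, length(lon) == length(lat))
  p <- project_local(lat, lon, mean(lat), mean(lon))
  e <- min_enclosing_ellipse(p, tol = tol, max_iter = max_iter)
  list(ellipse_area = e$area,
       ellipse_minor = 2 * e$semi_minor,
       ellipse_major = 2 * e$semi_major)
}

#' Adaptive k-means clustering of stationary fixes
#'
#' Starts with one cluster and increases k until every stationary fix
#' lies within `cluster_radius_m` of its assigned centroid (the
#' inclusion criterion). For each k, k-means is run on locally projected
#' coordinates with deterministic farthest-point seeding, so results are
#' reproducible. Distances to centroids are checked geodesically.
#'
#' @param lat,lon Coordinates of stationary fixes, degrees.
#' @param cluster_radius_m Inclusion radius in metres.
#' @param max_k Upper bound on k (default: number of distinct points,
#'   which always satisfies the criterion).
#' @param seed Integer seed for the k-means stage.
#' @return A list with `k`, `centroids` (tibble `lat`, `lon`),
#'   `assignment` (integer per fix), and `dwell_share` (per-cluster
#'   proportion of stationary fixes, each in (0, 1], summing to 1).
#' @export
adaptive_kmeans <- function(lat, lon, cluster_radius_m = 500, max_k = NULL,
                            seed = 1L) {
  n <- length(lat)
  stopifnot(n >= 1, length(lon) == n)
  p <- project_local(lat, lon, mean(lat), mean(lon))
  uniq <- p[!duplicated(p), , drop = FALSE]
  n_uniq <- nrow(uniq)
  max_k <- min(max_k %||% n_uniq, n_uniq)

  for (k in seq_len(max_k)) {
    if (k == n_uniq) {
      # each distinct point its own cluster: radius criterion trivially met
      assignment <- match(paste(p[, 1], p[, 2]), paste(uniq[, 1], uniq[, 2]))
      centers <- uniq
    } else {
      centers0 <- farthest_point_centers(uniq, k)
      set.seed(seed)
      km <- suppressWarnings(
        stats::kmeans(p, centers = centers0, iter.max = 300L,
                      algorithm = "Lloyd"))
      assignment <- km$cluster
      centers <- km$centers
      occupied <- sort(unique(assignment))
      if (length(occupied) < nrow(centers)) {
        centers <- centers[occupied, , drop = FALSE]
        assignment <- match(assignment, occupied)
      }
    }
    cent_ll <- unproject_local(centers[, 1], centers[, 2], mean(lat), mean(lon))
    d_m <- 1000 * geodesic_km(lat, lon,
                              cent_ll[assignment, 1], cent_ll[assignment, 2])
    if (all(d_m <= cluster_radius_m)) {
      share <- tabulate(assignment, nbins = nrow(centers)) / n
      return(list(k = nrow(centers),
                  centroids = tibble::tibble(lat = cent_ll[, 1],
                                             lon = cent_ll[, 2]),
                  assignment = as.integer(assignment),
                  dwell_share = share))
    }
  }
  abort("adaptive k-means failed to satisfy the inclusion radius within `max_k` clusters")
}

# Deterministic farthest-point seeding: first the point farthest from the
# centroid, then repeatedly the point farthest from the chosen set. Ties
# resolve to the lowest row index (which.max).
farthest_point_centers <- function(u, k) {
  ctr <- colMeans(u)
  dmin <- (u[, 1] - ctr[1])^2 + (u[, 2] - ctr[2])^2
  idx <- which.max(dmin)
  dmin <- (u[, 1] - u[idx, 1])^2 + (u[, 2] - u[idx, 2])^2
  while (length(idx) < k) {
    j <- which.max(dmin)
    idx <- c(idx, j)
    dmin <- pmin(dmin, (u[, 1] - u[j, 1])^2 + (u[, 2] - u[j, 2])^2)
  }
  u[idx, , drop = FALSE]
}

#' Extract the ten life-space features for one participant-day
#'
#' Composes motion classification, excursion, ellipsoid-hull, clustering
#' and trip/homestay computations into a single daily record. Days with
#' fewer than `min_fixes_per_day` fixes are computed anyway but flagged
#' `valid = FALSE` so they can be excluded from modelling.
#'
#' @param timestamps POSIXct fixes of one local day, strictly increasing.
#' @param lat,lon Fix coordinates, degrees.
#' @param home_lat,home_lon Home location, degrees.
#' @param params A [feature_params()] list.
#' @param features Which feature families to compute: any of
#'   `"excursion"`, `"ellipse"`, `"cluster"`, `"trip"`. Families left out
#'   are returned as `NA` (useful when only a subset is needed at scale).
#' @return A one-row tibble with the ten features plus `n_fixes`, `valid`.
#' @export
extract_daily_features <- function(timestamps, lat, lon, home_lat, home_lon,
                                   params = feature_params(),
                                   features = c("excursion", "ellipse",
                                                "cluster", "trip")) {
  features <- match.arg(features, several.ok = TRUE)
  n <- length(timestamps)
  stopifnot(n >= 1, length(lat) == n, length(lon) == n)
  d_home <- geodesic_km(lat, lon, home_lat, home_lon)
  vals <- day_features_core(as.numeric(timestamps), lat, lon, d_home,
                            params, features)
  out <- as.list(setNames(vals, lifespace_feature_names()))
  tibble::as_tibble(c(out, list(n_fixes = n,
                                valid = n >= params$min_fixes_per_day)))
}

#' Extract daily life-space features for a whole fix table
#'
#' Splits a fix table into participant-days and applies
#' [extract_daily_features()] to each. Fixes are sorted by participant
#' and time; duplicate timestamps within a participant are rejected.
#'
#' @param fixes Tibble with `participant_id`, `timestamp` (POSIXct),
#'   `lat`, `lon`, and optionally `local_date` (computed from `params$tz`
#'   when absent).
#' @param homes Tibble with `participant_id`, `home_lat`, `home_lon`.
#' @param params A [feature_params()] list.
#' @inheritParams extract_daily_features
#' @return Tibble with one row per participant-day: `participant_id`,
#'   `local_date`, the ten features, `n_fixes`, `valid`.
#' @export
extract_features <- function(fixes, homes, params = feature_params(),
                             features = c("excursion", "ellipse",
                                          "cluster", "trip")) {
  features <- match.arg(features, several.ok = TRUE)
  need <- c("participant_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(fixes))) {
    abort(paste("`fixes` must contain columns:", paste(need, collapse = ", ")))
  }
  if (nrow(fixes) == 0) abort("`fixes` is empty")
  if (!all(c("participant_id", "home_lat", "home_lon") %in% names(homes))) {
    abort("`homes` must contain participant_id, home_lat, home_lon")
  }
  fixes <- dplyr::arrange(fixes, .data$participant_id, .data$timestamp)
  nr <- nrow(fixes)
  tsn <- as.numeric(fixes$timestamp)
  if (nr > 1 && any(fixes$participant_id[-1] == fixes$participant_id[-nr] &
                    tsn[-1] == tsn[-nr])) {
    abort("duplicate (participant_id, timestamp) fixes")
  }
  if (!"local_date" %in% names(fixes)) {
    fixes$local_date <- as.Date(format(fixes$timestamp, tz = params$tz))
  }
  missing_home <- setdiff(unique(fixes$participant_id), homes$participant_id)
  if (length(missing_home)) {
    abort(paste("no home location for participant(s):",
                paste(missing_home, collapse = ", ")))
  }
  hidx <- match(fixes$participant_id, homes$participant_id)
  hlat <- homes$home_lat[hidx]
  hlon <- homes$home_lon[hidx]

  lat <- fixes$lat
  lon <- fixes$lon
  d_home <- hav_km(lat, lon, hlat, hlon)

  key <- paste(fixes$participant_id, as.integer(fixes$local_date), sep = "\r")
  groups <- split(seq_len(nrow(fixes)), factor(key, levels = unique(key)))
  ng <- length(groups)
  first <- vapply(groups, `[`, 0L, 1L)
  feat <- matrix(NA_real_, ng, 10)
  n_fixes <- integer(ng)
  for (g in seq_len(ng)) {
    ix <- groups[[g]]
    n_fixes[g] <- length(ix)
    feat[g, ] <- day_features_core(tsn[ix], lat[ix], lon[ix], d_home[ix],
                                   params, features)
  }
  out <- tibble::as_tibble(setNames(as.data.frame(feat),
                                    lifespace_feature_names()))
  dplyr::bind_cols(
    tibble::tibble(participant_id = fixes$participant_id[first],
                   local_date = fixes$local_date[first]),
    out,
    tibble::tibble(n_fixes = n_fixes,
                   valid = n_fixes >= params$min_fixes_per_day))
}

#' Estimate home locations from overnight fixes
#'
#' Homes were known to the original study but are generally not recorded
#' in a raw fix stream. This helper estimates each participant's home as
#' the centroid of the modal night-time (midnight to 6 AM local) location
#' cluster; participants with no night fixes fall back to the medoid-like
#' median of all their fixes.
#'
#' @param fixes Fix tibble (see [extract_features()]).
#' @param params A [feature_params()] list (`tz` and `cluster_radius_m` used).
#' @return Tibble `participant_id`, `home_lat`, `home_lon`.
#' @export
estimate_home <- function(fixes, params = feature_params()) {
  stopifnot(nrow(fixes) > 0)
  hours <- as.integer(format(fixes$timestamp, "%H", tz = params$tz))
  night <- hours < 6
  one_home <- function(ix) {
    jx <- ix[night[ix]]
    if (length(jx) < 5) jx <- ix
    if (length(jx) > 400) jx <- jx[seq(1, length(jx), length.out = 400)]
    cl <- adaptive_kmeans(fixes$lat[jx], fixes$lon[jx],
                          cluster_radius_m = params$cluster_radius_m,
                          seed = params$kmeans_seed)
    modal <- which.max(cl$dwell_share)
    c(cl$centroids$lat[modal], cl$centroids$lon[modal])
  }
  ids <- unique(fixes$participant_id)
  est <- vapply(split(seq_len(nrow(fixes)), fixes$participant_id)[as.character(ids)],
                one_home, numeric(2))
  tibble::tibble(participant_id = ids,
                 home_lat = est[1, ], home_lon = est[2, ])
}
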