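# Synthetic deployment generator.
#
# Emulates a LoRa-WAN tracker deployment so the whole pipeline can be
# exercised without field data: static reference trackers (indoor trackers
# see degraded GPS through the building; outdoor trackers see clear sky)
# and collared animals moving as a two-state (rest/active) minute-resolution
# Markov chain with a correlated random walk during active bouts.  Position
# error is isotropic Gaussian calibrated by the radius containing 95% of
# fixes (R95 = sigma * sqrt(-2 ln 0.05)); rare gross outliers displace a fix
# by a log-uniform distance.  Every generator draws from the current RNG
# stream; simulate_study() seeds it once from the scenario, making the full
# file set a deterministic function of the scenario.

.sim_zone <- function(sc) {
  z <- floor((sc$site_lon + 180) / 6) + 1
  paste0(z, if (sc$site_lat >= 0) "N" else "S")
}

.sim_origin <- function(sc) {
  latlon_to_utm(sc$site_lat, sc$site_lon, .sim_zone(sc))
}

.sim_fix_minutes <- function(sc) {
  seq(0L, sc$days * 1440L - sc$gps_interval_min, by = sc$gps_interval_min)
}

.sim_start <- function(start_date) {
  as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
}

# per-axis noise; Student-t option (variance-matched) stresses the z-filter
.axis_noise <- function(n, sigma, df) {
  if (is.finite(df)) {
    stats::rt(n, df) * sigma * sqrt((df - 2) / df)
  } else {
    stats::rnorm(n, 0, sigma)
  }
}

.inject_outliers <- function(e, n, prob, range_m) {
  m <- length(e)
  hit <- stats::runif(m) < prob
  k <- sum(hit)
  if (k > 0) {
    r <- exp(stats::runif(k, log(range_m[1]), log(range_m[2])))
    th <- stats::runif(k, 0, 2 * pi)
    e[hit] <- e[hit] + r * cos(th)
    n[hit] <- n[hit] + r * sin(th)
  }
  list(easting = e, northing = n)
}

.motion_frame <- function(sc, tracker_id, start, mi) {
  minutes <- seq(sc$motion_interval_min, sc$days * 1440L,
                 by = sc$motion_interval_min)
  data.frame(tracker_id = tracker_id,
             timestamp = .sim_start(start) + minutes * 60,
             motion_index = as.integer(mi),
             stringsAsFactors = FALSE)
}

.spurious_mi <- function(mi, sc) {
  if (sc$spurious_mi_prob > 0) {
    hit <- stats::runif(length(mi)) < sc$spurious_mi_prob & mi == 0
    mi[hit] <- pmax(1L, stats::rpois(sum(hit), sc$mi_active_mean))
  }
  mi
}

.fixes_frame <- function(sc, tracker_id, start, minutes, easting, northing) {
  zone <- .sim_zone(sc)
  keep <- stats::runif(length(minutes)) >= sc$fix_dropout_prob
  ll <- utm_to_latlon(easting[keep], northing[keep], zone)
  data.frame(tracker_id = tracker_id,
             timestamp = .sim_start(start) + minutes[keep] * 60,
             lat = ll$lat, lon = ll$lon, stringsAsFactors = FALSE)
}

#' Simulate a static reference tracker
#'
#' True position fixed; reported fixes are truth plus isotropic position
#' noise (indoor or outdoor error scale per `placement`) and occasional gross
#' outliers; the Motion Index is 0 at every interval (unless
#' `spurious_mi_prob > 0`).  Draws from the current RNG stream.
#'
#' @param scenario a [sim_scenario()].
#' @param placement `"Indoor"` or `"Outdoor"`.
#' @param tracker_id tracker label for the emitted records.
#' @param offset_m numeric length-2 easting/northing offset (m) of the
#'   tracker's true position from the site origin.
#' @param start first calendar day, default the scenario's static phase.
#' @return list with data frames `fixes` (geographic coordinates), `motion`,
#'   and `truth` (`tracker_id`, `date`, `true_path_m`, all 0).
#' @export
simulate_static <- function(scenario, placement = c("Outdoor", "Indoor"),
                            tracker_id = "S01", offset_m = c(0, 0),
                            start = scenario$static_start) {
  placement <- match.arg(placement)
  sc <- scenario
  sigma <- if (placement == "Indoor") sc$sigma_indoor_m else sc$sigma_outdoor_m
  org <- .sim_origin(sc)
  minutes <- .sim_fix_minutes(sc)
  m <- length(minutes)
  e <- org$easting + offset_m[1] + .axis_noise(m, sigma, sc$noise_df)
  n <- org$northing + offset_m[2] + .axis_noise(m, sigma, sc$noise_df)
  en <- .inject_outliers(e, n, sc$outlier_prob, sc$outlier_range_m)
  fixes <- .fixes_frame(sc, tracker_id, start, minutes, en$easting,
                        en$northing)
  mi <- .spurious_mi(integer(sc$days * 1440L %/% sc$motion_interval_min), sc)
  list(fixes = fixes,
       motion = .motion_frame(sc, tracker_id, start, mi),
       truth = data.frame(tracker_id = tracker_id,
                          date = as.Date(start) + 0:(sc$days - 1),
                          true_path_m = 0, stringsAsFactors = FALSE))
}

#' Simulate a collared animal
#'
#' Minute-resolution two-state Markov chain (rest/active).  During an active
#' minute the true position advances by a gamma-distributed step along a
#' heading that drifts as a Gaussian random walk (a correlated random walk),
#' and the Motion Index is Poisson; during rest the position is fixed and
#' the Motion Index is 0.  GPS fixes report the true position plus
#' outdoor-grade noise every `gps_interval_min`.  The per-day true path
#' length is returned as ground truth for recovery tests.  Draws from the
#' current RNG stream.
#'
#' @inheritParams simulate_static
#' @param start first calendar day, default the scenario's animal phase.
#' @return list with `fixes`, `motion`, and `truth` (per-day true path, m).
#' @export
simulate_animal <- function(scenario, tracker_id = "A01",
                            offset_m = c(0, 0),
                            start = scenario$animal_start) {
  sc <- scenario
  T_min <- sc$days * 1440L
  # state chain: 0 = rest, 1 = active; start at the stationary distribution
  p_act <- if (sc$p_rest_to_active + sc$p_active_to_rest > 0) {
    sc$p_rest_to_active / (sc$p_rest_to_active + sc$p_active_to_rest)
  } else 0
  state <- integer(T_min)
  state[1] <- stats::rbinom(1, 1, p_act)
  u <- stats::runif(T_min)
  for (t in 2:T_min) {
    state[t] <- if (state[t - 1] == 1) {
      if (u[t] < sc$p_active_to_rest) 0L else 1L
    } else {
      if (u[t] < sc$p_rest_to_active) 1L else 0L
    }
  }
  # step_shape = Inf degenerates to a constant step length
  len <- if (is.infinite(sc$step_shape)) {
    rep(sc$step_mean_m_per_min, T_min)
  } else {
    stats::rgamma(T_min, shape = sc$step_shape,
                  scale = sc$step_mean_m_per_min / sc$step_shape)
  }
  step <- ifelse(state == 1, len, 0)
  heading <- cumsum(stats::rnorm(T_min, 0, sc$turn_sd_rad)) +
    stats::runif(1, 0, 2 * pi)
  org <- .sim_origin(sc)
  # position at the end of minute t (index t + 1; index 1 = origin)
  pos_e <- org$easting + offset_m[1] + c(0, cumsum(step * cos(heading)))
  pos_n <- org$northing + offset_m[2] + c(0, cumsum(step * sin(heading)))
  minutes <- .sim_fix_minutes(sc)
  e <- pos_e[minutes + 1L] + .axis_noise(length(minutes), sc$sigma_outdoor_m,
                                         sc$noise_df)
  n <- pos_n[minutes + 1L] + .axis_noise(length(minutes), sc$sigma_outdoor_m,
                                         sc$noise_df)
  en <- .inject_outliers(e, n, sc$outlier_prob, sc$outlier_range_m)
  fixes <- .fixes_frame(sc, tracker_id, start, minutes, en$easting,
                        en$northing)
  mi <- integer(T_min)
  act <- state == 1
  mi[act] <- stats::rpois(sum(act), sc$mi_active_mean)
  mi <- .spurious_mi(mi, sc)
  if (sc$motion_interval_min > 1) {
    grp <- rep(seq_len(T_min %/% sc$motion_interval_min),
               each = sc$motion_interval_min, length.out = T_min)
    mi <- as.integer(rowsum(mi, grp))
  }
  day_of_min <- rep(seq_len(sc$days), each = 1440L)
  truth <- data.frame(tracker_id = tracker_id,
                      date = as.Date(start) + 0:(sc$days - 1),
                      true_path_m = as.numeric(rowsum(step, day_of_min)),
                      stringsAsFactors = FALSE)
  list(fixes = fixes,
       motion = .motion_frame(sc, tracker_id, start, mi),
       truth = truth)
}

#' Simulate the full deployment
#'
#' Generates the complete file set — GPS fixes, motion records, placement
#' manifest, and per tracker-day ground-truth path lengths — for a staged
#' deployment of `n_outdoor` + `n_indoor` static trackers followed by
#' `n_animal` collared animals, seeded once from `scenario$rng_seed`.
#'
#' @param scenario a [sim_scenario()].
#' @param out_dir optional directory; when given, `fixes.csv`, `motion.csv`,
#'   `manifest.csv` and `truth.csv` are written there with the package
#'   writers (same dialect the readers consume).
#' @return list with data frames `fixes`, `motion`, `manifest`, `truth`, and
#'   (when `out_dir` is given) `files`, a named vector of paths.
#' @export
simulate_study <- function(scenario, out_dir = NULL) {
  sc <- scenario
  set.seed(sc$rng_seed)
  parts <- list()
  if (sc$n_outdoor > 0) {
    for (i in seq_len(sc$n_outdoor)) {
      # spaced along a fence line running east of the gateway
      parts[[length(parts) + 1]] <- c(
        simulate_static(sc, "Outdoor", sprintf("O%02d", i),
                        offset_m = c(100 * i, 0)),
        placement = "Outdoor")
    }
  }
  if (sc$n_indoor > 0) {
    for (i in seq_len(sc$n_indoor)) {
      # clustered inside the feed-mill office
      parts[[length(parts) + 1]] <- c(
        simulate_static(sc, "Indoor", sprintf("I%02d", i),
                        offset_m = c(5 * i, 60)),
        placement = "Indoor")
    }
  }
  if (sc$n_animal > 0) {
    for (i in seq_len(sc$n_animal)) {
      parts[[length(parts) + 1]] <- c(
        simulate_animal(sc, sprintf("A%02d", i),
                        offset_m = c(50 * i, -400)),
        placement = "Animal")
    }
  }
  fixes <- do.call(rbind, lapply(parts, `[[`, "fixes"))
  motion <- do.call(rbind, lapply(parts, `[[`, "motion"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  fixes <- fixes[order(fixes$tracker_id, fixes$timestamp), ]
  motion <- motion[order(motion$tracker_id, motion$timestamp), ]
  rownames(fixes) <- rownames(motion) <- rownames(truth) <- NULL
  manifest <- data.frame(
    tracker_id = vapply(parts, function(p) p$fixes$tracker_id[1], ""),
    placement = vapply(parts, `[[`, "", "placement"),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$tracker_id), ]
  rownames(manifest) <- NULL
  out <- list(fixes = fixes, motion = motion, manifest = manifest,
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(fixes = file.path(out_dir, "fixes.csv"),
               motion = file.path(out_dir, "motion.csv"),
               manifest = file.path(out_dir, "manifest.csv"),
               truth = file.path(out_dir, "truth.csv"))
    write_fixes(fixes, files[["fixes"]])
    write_motion(motion, files[["motion"]])
    write_manifest(manifest, files[["manifest"]])
    tr <- truth
    tr$date <- as.character(tr$date)
    tr$true_path_m <- .num_chr(tr$true_path_m)
    utils::write.csv(tr, files[["truth"]], row.names = FALSE, quote = FALSE)
    out$files <- files
  }
  out
}
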