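# Shared fixture builders and independent oracles.

.t0 <- as.POSIXct("2020-12-25 00:00:00", tz = "UTC")

# projected/annotated fix table built directly in planar coordinates
make_fixes <- function(easting, northing, minutes = NULL, tracker = "t1",
                       start = .t0, cum_mi = NULL) {
  n <- length(easting)
  if (is.null(minutes)) minutes <- seq(0, by = 15, length.out = n)
  df <- data.frame(tracker_id = tracker, timestamp = start + minutes * 60,
                   lat = NA_real_, lon = NA_real_,
                   easting = as.numeric(easting),
                   northing = as.numeric(northing),
                   utm_zone = "13N", stringsAsFactors = FALSE)
  if (!is.null(cum_mi)) {
    df$cum_mi <- as.integer(cum_mi)
    df$outlier_easting <- FALSE
    df$outlier_northing <- FALSE
  }
  df
}

# geographic fix table around the default site
make_geo_fixes <- function(n, tracker = "t1", start = .t0, jitter_m = 5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  org <- lorawalk::latlon_to_utm(36.45, -103.15, "13N")
  e <- org$easting + rnorm(n, 0, jitter_m)
  no <- org$northing + rnorm(n, 0, jitter_m)
  ll <- lorawalk::utm_to_latlon(e, no, "13N")
  data.frame(tracker_id = tracker, timestamp = start + seq_len(n) * 900 - 900,
             lat = ll$lat, lon = ll$lon, stringsAsFactors = FALSE)
}

make_motion <- function(minutes, counts, tracker = "t1", start = .t0) {
  data.frame(tracker_id = tracker, timestamp = start + minutes * 60,
             motion_index = as.integer(counts), stringsAsFactors = FALSE)
}

empty_motion <- function() {
  data.frame(tracker_id = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             motion_index = integer(0), stringsAsFactors = FALSE)
}

# brute-force oracle for the inter-fix cumulative Motion Index: O(n*m)
# double loop over the half-open windows (prev, cur]
brute_cum_mi <- function(fix_times, motion_times, motion_counts,
                         day_timezone = "UTC") {
  n <- length(fix_times)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1) {
      same_day <- format(motion_times, "%Y-%m-%d", tz = day_timezone) ==
        format(fix_times[1], "%Y-%m-%d", tz = day_timezone)
      sel <- same_day & motion_times <= fix_times[1]
      if (any(sel)) out[1] <- sum(motion_counts[sel])
    } else {
      sel <- motion_times > fix_times[i - 1] & motion_times <= fix_times[i]
      out[i] <- sum(motion_counts[sel])
    }
  }
  out
}

# tiny scenario for fast end-to-end tests
tiny_scenario <- function(...) {
  lorawalk::sim_scenario(n_animal = 2, n_indoor = 2, n_outdoor = 2,
                         days = 2, ...)
}
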