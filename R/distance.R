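# Daily distance-walked algorithms.
#
# Three estimators of meters walked per tracker-day, all of them sums of
# planar (Pythagorean) distances between consecutive fixes within a calendar
# day:
#   RawDist           - every successful fix, erroneous locations included
#   CorrectedDist     - fixes surviving the per-day z-score outlier filter
#   CorrectedDist_Act - additionally drops fixes whose inter-fix cumulative
#                       Motion Index is 0 (no accelerometer motion), so a
#                       stationary tracker reads 0 m
# The step between one day's last fix and the next day's first fix is
# discarded: the daily sum indexes consecutive positions within a day only.

.algorithms <- c("RawDist", "CorrectedDist", "CorrectedDist_Act")

#' Planar distance between two consecutive fixes
#'
#' @param a,b projected fixes (one-row data frames or lists with `easting`
#'   and `northing` in meters).
#' @return distance in meters, non-negative and symmetric.
#' @examples
#' step_distance(list(easting = 0, northing = 0),
#'               list(easting = 3, northing = 4))  # 5
#' @export
step_distance <- function(a, b) {
  sqrt((a$easting - b$easting)^2 + (a$northing - b$northing)^2)
}

#' Distance walked within one tracker-day
#'
#' Sums the planar distance over consecutive fix pairs.  Fewer than 2 fixes
#' yields 0 (the degenerate-day rule; see [compute_all()] for the `"na"`
#' alternative).
#'
#' @param day_fixes time-ordered projected fixes for a single tracker-day.
#' @return meters walked (scalar, >= 0).
#' @export
daily_distance <- function(day_fixes) {
  n <- nrow(day_fixes)
  if (n < 2) return(0)
  if (length(unique(day_fixes$tracker_id)) > 1)
    stop("daily_distance() requires fixes from a single tracker")
  tt <- as.numeric(day_fixes$timestamp)
  if (is.unsorted(tt))
    stop("daily_distance() requires time-ordered fixes")
  sum(sqrt(diff(day_fixes$easting)^2 + diff(day_fixes$northing)^2))
}

#' Compute all three daily distance algorithms
#'
#' Runs the full fix-processing chain — UTM projection, Motion Index
#' annotation, per tracker-day z-score flags — then evaluates RawDist,
#' CorrectedDist and CorrectedDist_Act on identical tracker-day partitions.
#'
#' @param fixes GPS fixes from [read_fixes()] (geographic coordinates).
#' @param motion motion records from [read_motion()].
#' @param manifest placement manifest from [read_manifest()]; every tracker
#'   in `fixes` must be present.
#' @param config a [pipeline_config()].
#' @return data frame with one row per tracker-day-algorithm: `tracker_id`,
#'   `date` (calendar day in `config$day_timezone`), `placement`,
#'   `algorithm`, `distance_m`, `n_fixes_total`, `n_fixes_used`.
#' @export
compute_all <- function(fixes, motion, manifest,
                        config = pipeline_config()) {
  lookup_placement(unique(fixes$tracker_id), manifest)  # fatal if missing
  proj <- project_to_utm(fixes, config$utm_zone)
  ann <- cumulate_motion(proj, motion, config$day_timezone)
  ann <- add_outlier_flags(ann, config)
  day <- format(ann$timestamp, "%Y-%m-%d", tz = config$day_timezone)
  key <- paste(ann$tracker_id, day, sep = "\r")
  groups <- split(seq_len(nrow(ann)), key)

  rows <- lapply(groups, function(idx) {
    g <- ann[idx, , drop = FALSE]
    n_total <- nrow(g)
    corrected <- apply_filter(g, drop_outliers = TRUE)
    act <- apply_filter(g, drop_outliers = TRUE, drop_motionless = TRUE)
    used <- c(RawDist = n_total, CorrectedDist = nrow(corrected),
              CorrectedDist_Act = nrow(act))
    dist <- c(.dist_or_degenerate(g, config),
              .dist_or_degenerate(corrected, config),
              .dist_or_degenerate(act, config))
    data.frame(tracker_id = g$tracker_id[1],
               date = as.Date(format(g$timestamp[1], "%Y-%m-%d",
                                     tz = config$day_timezone)),
               algorithm = .algorithms,
               distance_m = dist,
               n_fixes_total = n_total,
               n_fixes_used = unname(used),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$placement <- lookup_placement(out$tracker_id, manifest)
  out <- out[order(out$tracker_id, out$date,
                   match(out$algorithm, .algorithms)),
             c("tracker_id", "date", "placement", "algorithm", "distance_m",
               "n_fixes_total", "n_fixes_used")]
  rownames(out) <- NULL
  out
}

.dist_or_degenerate <- function(g, config) {
  if (nrow(g) < 2) {
    if (config$degenerate_day == "na") return(NA_real_) else return(0)
  }
  daily_distance(g)
}
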