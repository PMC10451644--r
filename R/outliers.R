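# Per tracker-day z-score screening of erroneous GPS positions.
#
# Within one tracker-day, easting and northing are standardized separately;
# a fix whose |z| exceeds the threshold (default 4.5) on either axis is
# flagged erroneous.  Flags are computed in a single pass on the full day
# (no recomputation after removal), which keeps the operator deterministic
# and idempotent.  Note the sample z-score bound |z| <= (n-1)/sqrt(n): at
# threshold 4.5 no fix can be flagged on a day with fewer than 23 fixes.

#' Flag outliers in one tracker-day by axis-wise z-scores
#'
#' @param day_fixes annotated fixes for a single tracker and calendar day.
#' @param threshold positive number; flag where `|z| > threshold`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @param min_fixes days with fewer fixes than this get no flags.
#' @param day_timezone IANA zone defining the calendar day (used only to
#'   verify the single-day precondition).
#' @return `day_fixes` with `outlier_easting` / `outlier_northing` set; input
#'   order preserved.  Days with `sd == 0` on an axis, or with fewer than
#'   `min_fixes` fixes, get no flags on that axis.
#' @export
zscore_flag <- function(day_fixes, threshold = 4.5,
                        sd_type = c("sample", "population"),
                        min_fixes = 2L, day_timezone = "UTC") {
  sd_type <- match.arg(sd_type)
  stopifnot(threshold > 0)
  if (nrow(day_fixes) == 0) return(day_fixes)
  if (length(unique(day_fixes$tracker_id)) > 1)
    stop("zscore_flag() requires fixes from a single tracker")
  day <- format(day_fixes$timestamp, "%Y-%m-%d", tz = day_timezone)
  if (length(unique(day)) > 1)
    stop("zscore_flag() requires fixes from a single calendar day")
  day_fixes$outlier_easting <- .axis_flags(day_fixes$easting, threshold,
                                           sd_type, min_fixes)
  day_fixes$outlier_northing <- .axis_flags(day_fixes$northing, threshold,
                                            sd_type, min_fixes)
  day_fixes
}

.axis_flags <- function(v, threshold, sd_type, min_fixes) {
  n <- length(v)
  if (n < max(2L, min_fixes)) return(rep(FALSE, n))
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) return(rep(FALSE, n))
  abs((v - mean(v)) / s) > threshold
}

#' Flag outliers across a whole fix table
#'
#' Applies [zscore_flag()] independently to every tracker-day group.
#'
#' @param fixes annotated fixes (any number of trackers/days).
#' @param config a [pipeline_config()].
#' @return `fixes` with outlier flags set; row order preserved.
#' @export
add_outlier_flags <- function(fixes, config = pipeline_config()) {
  if (nrow(fixes) == 0) return(fixes)
  day <- format(fixes$timestamp, "%Y-%m-%d", tz = config$day_timezone)
  key <- paste(fixes$tracker_id, day, sep = "\r")
  for (idx in split(seq_len(nrow(fixes)), key)) {
    fixes[idx, ] <- zscore_flag(fixes[idx, , drop = FALSE],
                                threshold = config$z_threshold,
                                sd_type = config$sd_type,
                                min_fixes = config$min_fixes_per_day,
                                day_timezone = config$day_timezone)
  }
  fixes
}

#' Remove flagged and/or motionless fixes
#'
#' @param fixes annotated fixes with flags and `cum_mi` computed.
#' @param drop_motionless drop fixes with `cum_mi == 0`?
#' @param drop_outliers drop fixes flagged on either axis?
#' @return the filtered subset, relative order preserved, with attributes
#'   `n_dropped_outlier` and `n_dropped_motionless` counting each reason
#'   (a fix matching both reasons is counted in both but removed once).
#' @export
apply_filter <- function(fixes, drop_motionless = FALSE,
                         drop_outliers = FALSE) {
  out_flag <- fixes$outlier_easting | fixes$outlier_northing
  still <- is_motionless(fixes)
  drop <- (drop_outliers & out_flag) | (drop_motionless & still)
  res <- fixes[!drop, , drop = FALSE]
  attr(res, "n_dropped_outlier") <- if (drop_outliers) sum(out_flag) else 0L
  attr(res, "n_dropped_motionless") <- if (drop_motionless) sum(still) else 0L
  res
}
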