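# GPS / accelerometer fusion: cumulative Motion Index per inter-fix window.
#
# Trackers report a Motion Index (MI) — a count of accelerometer shock events
# — once per minute, and a GPS position every 15 minutes.  For distance
# correction each successful fix is annotated with the MI accumulated since
# the previous successful fix of the same tracker, so an MI of zero marks a
# fix interval in which the device never moved.

#' Annotate fixes with cumulative Motion Index
#'
#' For each fix after a tracker's first, `cum_mi` is the sum of
#' `motion_index` over motion records in the half-open window
#' `(previous fix, current fix]`; the half-open convention makes the windows
#' tile time so no record is counted twice.  A tracker's first fix gets the
#' sum over same-calendar-day records at or before its timestamp, or `NA` if
#' none exist.  Missing motion coverage in a window yields 0 (the device
#' reports on motion events; silence is indistinguishable from stillness).
#'
#' @param fixes projected fixes sorted by `(tracker_id, timestamp)`.
#' @param motion motion records as from [read_motion()].
#' @param day_timezone IANA zone defining the calendar day used for the
#'   first-fix lookback window.
#' @return `fixes` with integer `cum_mi` and logical `outlier_easting`,
#'   `outlier_northing` columns appended (flags initialized `FALSE`).
#' @export
cumulate_motion <- function(fixes, motion, day_timezone = "UTC") {
  stopifnot(!is.unsorted(order(fixes$tracker_id, fixes$timestamp)))
  unknown <- setdiff(unique(motion$tracker_id), unique(fixes$tracker_id))
  if (length(unknown) > 0) {
    warning("motion records for tracker(s) with no fixes ignored: ",
            paste(unknown, collapse = ", "))
    motion <- motion[!motion$tracker_id %in% unknown, , drop = FALSE]
  }
  cum_mi <- rep(NA_integer_, nrow(fixes))
  for (tid in unique(fixes$tracker_id)) {
    fi <- which(fixes$tracker_id == tid)
    ft <- as.numeric(fixes$timestamp[fi])
    if (is.unsorted(ft, strictly = TRUE))
      stop("fix timestamps not strictly increasing for tracker ", tid)
    mi <- motion[motion$tracker_id == tid, , drop = FALSE]
    n <- length(fi)
    if (nrow(mi) == 0) {
      cum_mi[fi] <- c(NA_integer_, rep(0L, n - 1))
      next
    }
    mt <- as.numeric(mi$timestamp)
    # window index: record j belongs to (ft[w], ft[w+1]]; w = 0 means at or
    # before the first fix, w = n means after the last fix (ignored)
    w <- findInterval(mt, ft, left.open = TRUE)
    sums <- rep(0, n)
    inwin <- w >= 1 & w <= n - 1
    if (any(inwin)) {
      agg <- rowsum(mi$motion_index[inwin], w[inwin])
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    # first fix: same-day lookback
    first_day <- format(fixes$timestamp[fi[1]], "%Y-%m-%d", tz = day_timezone)
    pre <- w == 0 & format(mi$timestamp, "%Y-%m-%d",
                           tz = day_timezone) == first_day
    sums[1] <- if (any(pre)) sum(mi$motion_index[pre]) else NA_integer_
    cum_mi[fi] <- as.integer(sums)
  }
  fixes$cum_mi <- cum_mi
  fixes$outlier_easting <- FALSE
  fixes$outlier_northing <- FALSE
  fixes
}

#' Is a fix motionless?
#'
#' A fix is motionless when its cumulative Motion Index is present and zero.
#' A missing `cum_mi` (a tracker's first fix with no prior motion coverage)
#' is conservatively treated as not motionless: retaining such a point can
#' still be corrected by the outlier filter, while dropping it cannot be
#' undone.
#'
#' @param fix an annotated fix table (or any object with a `cum_mi` field).
#' @return logical vector, one element per fix.
#' @export
is_motionless <- function(fix) {
  cm <- fix$cum_mi
  !is.na(cm) & cm == 0
}
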