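# Delimited-text readers and writers for tracker uplink tables.
#
# All files are UTF-8 delimited text (comma by default) with a header row and
# ISO-8601 UTC timestamps.  A configurable column-name map ("dialect") lets
# real device exports and synthetic files share one reader.

.default_fix_dialect <- c(tracker_id = "tracker_id", timestamp = "timestamp",
                          lat = "lat", lon = "lon")
.default_motion_dialect <- c(tracker_id = "tracker_id",
                             timestamp = "timestamp",
                             motion_index = "motion_index")

.parse_utc <- function(x) {
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = fmt)
  }
  out  # NA where no format matched; callers reject those rows
}

.format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# full-precision decimal serialization so read-back round-trips exactly
.num_chr <- function(x) {
  out <- formatC(x, format = "g", digits = 17, width = 1)
  out[is.na(x)] <- NA_character_
  out
}

.read_delim <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    encoding = "UTF-8")
}

.require_columns <- function(raw, dialect, path) {
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read GPS fix records
#'
#' Reads a delimited file of GPS position reports, validates coordinates,
#' drops exact duplicate rows and (per tracker) duplicate timestamps, and
#' returns records sorted by tracker then timestamp.
#'
#' @param path file path.
#' @param dialect named character vector mapping the canonical column names
#'   `tracker_id`, `timestamp`, `lat`, `lon` to the column names used in the
#'   file.
#' @param sep field delimiter, default comma.
#' @return data frame with columns `tracker_id` (character), `timestamp`
#'   (POSIXct, UTC), `lat`, `lon` (numeric degrees), sorted by
#'   `(tracker_id, timestamp)`.  Attributes `n_rejected` and `n_duplicates`
#'   count rows dropped for being malformed/out-of-range and duplicated.
#' @export
read_fixes <- function(path, dialect = .default_fix_dialect, sep = ",") {
  dialect <- c(dialect, .default_fix_dialect[setdiff(names(.default_fix_dialect),
                                                     names(dialect))])
  raw <- .read_delim(path, sep)
  .require_columns(raw, dialect, path)
  df <- data.frame(tracker_id = raw[[dialect[["tracker_id"]]]],
                   timestamp = .parse_utc(raw[[dialect[["timestamp"]]]]),
                   lat = suppressWarnings(as.numeric(raw[[dialect[["lat"]]]])),
                   lon = suppressWarnings(as.numeric(raw[[dialect[["lon"]]]])),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$timestamp) | is.na(df$lat) | is.na(df$lon) |
    abs(df$lat) > 90 | abs(df$lon) > 180 | !nzchar(df$tracker_id)
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(n_rejected, " malformed or out-of-range fix row(s) rejected in ",
            path)
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df)
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$tracker_id, df$timestamp), , drop = FALSE]
  # duplicate timestamps within a tracker: keep first report
  ts_dup <- duplicated(df[c("tracker_id", "timestamp")])
  if (any(ts_dup)) {
    warning(sum(ts_dup), " fix(es) with duplicated tracker timestamps ",
            "dropped (first report kept)")
    n_dup <- n_dup + sum(ts_dup)
    df <- df[!ts_dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rejected
  attr(df, "n_duplicates") <- n_dup
  df
}

#' Read Motion Index records
#'
#' Reads per-interval accelerometer shock counts (Motion Index, MI).
#'
#' @inheritParams read_fixes
#' @param dialect named map for `tracker_id`, `timestamp`, `motion_index`.
#' @return data frame with `tracker_id`, `timestamp` (POSIXct UTC) and
#'   integer `motion_index >= 0`, sorted by `(tracker_id, timestamp)`, with
#'   `n_rejected` / `n_duplicates` attributes as in [read_fixes()].
#' @export
read_motion <- function(path, dialect = .default_motion_dialect, sep = ",") {
  dialect <- c(dialect,
               .default_motion_dialect[setdiff(names(.default_motion_dialect),
                                               names(dialect))])
  raw <- .read_delim(path, sep)
  .require_columns(raw, dialect, path)
  df <- data.frame(tracker_id = raw[[dialect[["tracker_id"]]]],
                   timestamp = .parse_utc(raw[[dialect[["timestamp"]]]]),
                   motion_index = suppressWarnings(
                     as.integer(raw[[dialect[["motion_index"]]]])),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$timestamp) | is.na(df$motion_index) | df$motion_index < 0 |
    !nzchar(df$tracker_id)
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(n_rejected, " malformed motion row(s) rejected in ", path)
    df <- df[!bad, , drop = FALSE]
  }
  dup <- duplicated(df)
  df <- df[!dup, , drop = FALSE]
  df <- df[order(df$tracker_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rejected
  attr(df, "n_duplicates") <- sum(dup)
  df
}

.placements <- c("Animal", "Indoor", "Outdoor")

#' Read the tracker placement manifest
#'
#' @inheritParams read_fixes
#' @return data frame with `tracker_id` and `placement` (one of `"Animal"`,
#'   `"Indoor"`, `"Outdoor"`); every tracker appears exactly once.
#' @export
read_manifest <- function(path, sep = ",") {
  raw <- .read_delim(path, sep)
  .require_columns(raw, c(tracker_id = "tracker_id", placement = "placement"),
                   path)
  df <- data.frame(tracker_id = raw$tracker_id, placement = raw$placement,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$tracker_id))
    stop("manifest assigns more than one placement to a tracker")
  bad <- !df$placement %in% .placements
  if (any(bad))
    stop("manifest has unknown placement(s): ",
         paste(unique(df$placement[bad]), collapse = ", "))
  df
}

#' Look up placements for a set of trackers
#'
#' @param tracker_ids character vector.
#' @param manifest data frame from [read_manifest()].
#' @return character vector of placements, same length as `tracker_ids`.
#'   Errors if any tracker is absent from the manifest.
#' @export
lookup_placement <- function(tracker_ids, manifest) {
  idx <- match(tracker_ids, manifest$tracker_id)
  if (anyNA(idx)) {
    stop("tracker(s) missing from the placement manifest: ",
         paste(unique(tracker_ids[is.na(idx)]), collapse = ", "))
  }
  manifest$placement[idx]
}

#' Write / read back daily distance records
#'
#' Serializes a daily-distance table to delimited text with full numeric
#' precision so `read_daily_distances(write_daily_distances(x)) == x`.
#'
#' @param daily data frame with columns `tracker_id`, `date`, `placement`,
#'   `algorithm`, `distance_m`, `n_fixes_total`, `n_fixes_used`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daily_distances <- function(daily, path) {
  cols <- c("tracker_id", "date", "placement", "algorithm", "distance_m",
            "n_fixes_total", "n_fixes_used")
  stopifnot(all(cols %in% names(daily)))
  out <- daily[cols]
  out$date <- as.character(out$date)
  out$distance_m <- .num_chr(out$distance_m)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot open ", path,
                                           " for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_distances
#' @export
read_daily_distances <- function(path) {
  raw <- .read_delim(path)
  data.frame(tracker_id = raw$tracker_id,
             date = as.Date(raw$date),
             placement = raw$placement,
             algorithm = raw$algorithm,
             distance_m = as.numeric(raw$distance_m),
             n_fixes_total = as.integer(raw$n_fixes_total),
             n_fixes_used = as.integer(raw$n_fixes_used),
             stringsAsFactors = FALSE)
}

#' Write tracker input tables
#'
#' Writers matching the dialect the readers consume; used by the simulator so
#' synthetic and real data flow through identical file formats.
#'
#' @param fixes,motion,manifest data frames shaped as returned by
#'   [read_fixes()], [read_motion()], [read_manifest()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(tracker_id = fixes$tracker_id,
                    timestamp = .format_utc(fixes$timestamp),
                    lat = .num_chr(fixes$lat),
                    lon = .num_chr(fixes$lon))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
write_motion <- function(motion, path) {
  out <- data.frame(tracker_id = motion$tracker_id,
                    timestamp = .format_utc(motion$timestamp),
                    motion_index = motion$motion_index)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[c("tracker_id", "placement")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
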