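# Transverse Mercator (UTM) projection on the WGS84 ellipsoid.
#
# GPS receivers report WGS84 geographic coordinates; planar metric easting /
# northing are required for distance arithmetic.  The NAD83 datum used by
# desktop GIS differs from WGS84 by < 2 m in the continental US, well below
# tracker position error, so a single WGS84 transverse-Mercator projection is
# used for both (see the methods vignette).
#
# Implementation: Krueger series in the transverse Mercator expansion
# parameter n = f/(2-f), carried to n^6 (Karney 2011, "Transverse Mercator
# with an accuracy of a few nanometers").  Round-trip accuracy is far below
# 1e-6 degrees everywhere a UTM zone is valid.

.wgs84 <- list(a = 6378137.0, f = 1 / 298.257223563)

# series coefficients, computed once at load
.tm_env <- new.env(parent = emptyenv())

.tm_setup <- function() {
  f <- .wgs84$f
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  .tm_env$e <- sqrt(f * (2 - f))
  .tm_env$A <- .wgs84$a / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256)
  .tm_env$alpha <- c(
    n / 2 - 2 / 3 * n2 + 5 / 16 * n3 + 41 / 180 * n4 - 127 / 288 * n5 + 7891 / 37800 * n6,
    13 / 48 * n2 - 3 / 5 * n3 + 557 / 1440 * n4 + 281 / 630 * n5 - 1983433 / 1935360 * n6,
    61 / 240 * n3 - 103 / 140 * n4 + 15061 / 26880 * n5 + 167603 / 181440 * n6,
    49561 / 161280 * n4 - 179 / 168 * n5 + 6601661 / 7257600 * n6,
    34729 / 80640 * n5 - 3418889 / 1995840 * n6,
    212378941 / 319334400 * n6)
  .tm_env$beta <- c(
    n / 2 - 2 / 3 * n2 + 37 / 96 * n3 - 1 / 360 * n4 - 81 / 512 * n5 + 96199 / 604800 * n6,
    1 / 48 * n2 + 1 / 15 * n3 - 437 / 1440 * n4 + 46 / 105 * n5 - 1118711 / 3870720 * n6,
    17 / 480 * n3 - 37 / 840 * n4 - 209 / 4480 * n5 + 5569 / 90720 * n6,
    4397 / 161280 * n4 - 11 / 504 * n5 - 830251 / 7257600 * n6,
    4583 / 161280 * n5 - 108847 / 3991680 * n6,
    20648693 / 638668800 * n6)
  invisible(NULL)
}

.tm <- function() {
  if (is.null(.tm_env$A)) .tm_setup()
  .tm_env
}

.utm_k0 <- 0.9996
.utm_false_easting <- 5e5
.utm_false_northing_south <- 1e7

#' Parse a UTM zone designation
#'
#' Accepts `"13N"`, `"13S"`, `"13 n"`, or a bare integer (northern hemisphere
#' assumed) and returns a normalized list.
#'
#' @param zone UTM zone as string or integer.
#' @return list with integer `zone` (1-60) and `hemisphere` ("N" or "S").
#' @export
parse_utm_zone <- function(zone) {
  if (is.list(zone) && !is.null(zone$zone)) return(zone)
  if (is.numeric(zone)) {
    z <- as.integer(zone); h <- "N"
  } else {
    s <- toupper(trimws(as.character(zone)))
    m <- regmatches(s, regexec("^([0-9]{1,2})\\s*([NS]?)$", s))[[1]]
    if (length(m) == 0) stop("cannot parse UTM zone: ", zone)
    z <- as.integer(m[2])
    h <- if (nzchar(m[3])) m[3] else "N"
  }
  if (is.na(z) || z < 1 || z > 60) stop("UTM zone out of range: ", zone)
  list(zone = z, hemisphere = h)
}

.utm_central_meridian <- function(zone) -183 + 6 * zone

#' Project geographic coordinates to UTM
#'
#' Projects a table of GPS fixes (WGS84 decimal degrees) to planar UTM
#' easting/northing in meters, preserving row order and all other columns.
#'
#' @param fixes data frame with numeric `lat` and `lon` columns (see
#'   [read_fixes()]); other columns pass through untouched.
#' @param zone UTM zone designation, e.g. `"13N"` (see [parse_utm_zone()]).
#' @return the input with `easting`, `northing` (meters) and `utm_zone`
#'   (character, e.g. `"13N"`) columns appended.
#' @examples
#' f <- data.frame(tracker_id = "t1",
#'                 timestamp = as.POSIXct("2020-12-25 12:00:00", tz = "UTC"),
#'                 lat = 36.45, lon = -103.15)
#' project_to_utm(f, "13N")
#' @export
project_to_utm <- function(fixes, zone = "13N") {
  z <- parse_utm_zone(zone)
  stopifnot(is.numeric(fixes$lat), is.numeric(fixes$lon))
  if (any(!is.finite(fixes$lat)) || any(!is.finite(fixes$lon)) ||
      any(abs(fixes$lat) > 90) || any(abs(fixes$lon) > 180)) {
    stop("geographically invalid coordinates passed to project_to_utm()")
  }
  xy <- latlon_to_utm(fixes$lat, fixes$lon, z)
  fixes$easting <- xy$easting
  fixes$northing <- xy$northing
  fixes$utm_zone <- paste0(z$zone, z$hemisphere)
  fixes
}

#' Forward UTM projection of coordinate vectors
#'
#' @param lat,lon numeric vectors, WGS84 decimal degrees.
#' @param zone UTM zone designation.
#' @return list with numeric vectors `easting` and `northing` (meters).
#' @export
latlon_to_utm <- function(lat, lon, zone = "13N") {
  z <- parse_utm_zone(zone)
  tm <- .tm()
  phi <- lat * pi / 180
  lam <- (lon - .utm_central_meridian(z$zone)) * pi / 180
  e <- tm$e
  s <- sin(phi)
  # conformal latitude
  tau <- tan(phi)
  sigma <- sinh(e * atanh(e * s))
  taup <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2)
  xi_p <- atan2(taup, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(taup^2 + cos(lam)^2))
  xi <- xi_p; eta <- eta_p
  for (j in 1:6) {
    xi <- xi + tm$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + tm$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  easting <- .utm_false_easting + .utm_k0 * tm$A * eta
  northing <- .utm_k0 * tm$A * xi
  if (z$hemisphere == "S") northing <- northing + .utm_false_northing_south
  list(easting = easting, northing = northing)
}

#' Inverse UTM projection of coordinate vectors
#'
#' @param easting,northing numeric vectors, meters.
#' @param zone UTM zone designation.
#' @return list with numeric vectors `lat` and `lon` in WGS84 decimal degrees.
#' @export
utm_to_latlon <- function(easting, northing, zone = "13N") {
  z <- parse_utm_zone(zone)
  tm <- .tm()
  if (z$hemisphere == "S") northing <- northing - .utm_false_northing_south
  xi <- northing / (.utm_k0 * tm$A)
  eta <- (easting - .utm_false_easting) / (.utm_k0 * tm$A)
  xi_p <- xi; eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - tm$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - tm$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  taup <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  e <- tm$e
  # invert the conformal-latitude map by Newton iteration on tau = tan(phi)
  tau <- taup / (1 - e^2)
  for (i in 1:6) {
    sigma <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    ft <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2) - taup
    dft <- (sqrt((1 + sigma^2) * (1 + tau^2)) - sigma * tau) *
      (1 - e^2) * sqrt(1 + tau^2) / (1 + (1 - e^2) * tau^2)
    tau <- tau - ft / dft
  }
  phi <- atan(tau)
  list(lat = phi * 180 / pi,
       lon = .utm_central_meridian(z$zone) + lam * 180 / pi)
}
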