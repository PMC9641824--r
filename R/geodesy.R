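#' Rhumb-line (loxodrome) distance between two points
#'
#' Length of the constant-bearing path between two coordinates on a sphere of
#' radius 6371 km. Tracking studies of migratory birds use this "beeline"
#' measure for day-to-day displacement because the bird's compass course, not
#' the great circle, is the natural reference path.
#'
#' All arguments are recycled to a common length, so vectors of coordinate
#' pairs can be processed in one call.
#'
#' @param lat1,lon1 Origin latitude/longitude, decimal degrees.
#' @param lat2,lon2 Destination latitude/longitude, decimal degrees.
#' @param radius_km Sphere radius in kilometres.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' rhumb_distance(0, 0, 0, 1)    # one equatorial degree, ~111.195 km
#' rhumb_distance(29.55, 34.95, 55, 35)
#' @export
rhumb_distance <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  both_polar <- abs(lat1) == 90 & abs(lat2) == 90 &
    wrap_angle(lon1 - lon2) != 0 & lat1 != lat2
  if (any(both_polar, na.rm = TRUE)) {
    abort("rhumb line between opposite poles with differing longitude is undefined")
  }
  phi1 <- lat1 * pi / 180
  phi2 <- lat2 * pi / 180
  dphi <- phi2 - phi1
  dlam <- wrap_angle(lon2 - lon1) * pi / 180
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  q <- ifelse(abs(dpsi) > 1e-12, dphi / dpsi, cos(phi1))
  sqrt(dphi^2 + (q * dlam)^2) * radius_km
}

#' Rhumb-line bearing between two points
#'
#' Constant course angle, clockwise from true north, of the loxodrome from
#' `a` to `b`.
#'
#' @inheritParams rhumb_distance
#' @return Bearings in degrees within `[0, 360)`.
#' @examples
#' rhumb_bearing(0, 0, 10, 0)  # due north: 0
#' rhumb_bearing(0, 0, 0, 10)  # due east: 90
#' @export
rhumb_bearing <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  same <- lat1 == lat2 & wrap_angle(lon2 - lon1) == 0
  if (any(same, na.rm = TRUE)) {
    abort("bearing between coincident points is undefined")
  }
  phi1 <- lat1 * pi / 180
  phi2 <- lat2 * pi / 180
  dlam <- wrap_angle(lon2 - lon1) * pi / 180
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  (atan2(dlam, dpsi) * 180 / pi) %% 360
}

#' Rhumb-line destination point
#'
#' Point reached from `(lat, lon)` after travelling `distance_km` on the
#' constant bearing `bearing_deg`. Used by the track generator so that the
#' daily beeline recomputed by the segmentation stage is exact.
#'
#' @param lat,lon Start coordinates, decimal degrees.
#' @param bearing_deg Course in degrees clockwise from north.
#' @param distance_km Travel distance in kilometres.
#' @inheritParams rhumb_distance
#' @return A list with numeric vectors `lat` and `lon`.
#' @export
rhumb_destination <- function(lat, lon, bearing_deg, distance_km,
                              radius_km = EARTH_RADIUS_KM) {
  check_latlon(lat, lon)
  phi1 <- lat * pi / 180
  theta <- bearing_deg * pi / 180
  delta <- distance_km / radius_km
  dphi <- delta * cos(theta)
  phi2 <- phi1 + dphi
  # clamp numerically at the poles
  phi2 <- pmin(pmax(phi2, -pi / 2 + 1e-10), pi / 2 - 1e-10)
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  q <- ifelse(abs(dpsi) > 1e-12, (phi2 - phi1) / dpsi, cos(phi1))
  dlam <- delta * sin(theta) / q
  lon2 <- wrap_angle(lon + dlam * 180 / pi)
  list(lat = phi2 * 180 / pi, lon = lon2)
}

#' Smallest absolute difference between two compass directions
#'
#' @param a,b Bearings in degrees.
#' @return Angular separation in degrees, within `[0, 180]`.
#' @examples
#' turning_angle(10, 350)  # 20
#' @export
turning_angle <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Is a compass bearing in the northern sector?
#'
#' The northward sector used by the arrival rule is the union
#' `(270, 360) U [0, 90)`, i.e. courses crossing north.
#'
#' @param bearing_deg Bearings in degrees.
#' @return Logical vector.
#' @export
is_northern <- function(bearing_deg) {
  b <- bearing_deg %% 360
  b > 270 | b < 90
}

# wrap to (-180, 180]
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    abort("coordinates must be finite")
  }
  if (any(lat < -90 | lat > 90)) {
    abort("latitude must lie in [-90, 90]")
  }
  invisible(NULL)
}
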