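#' Sunrise and sunset times
#'
#' Computes sunrise and sunset instants (UTC) for calendar dates and
#' positions using the NOAA fractional-year solar-position approximation,
#' with the conventional sun-centre altitude of -0.833 degrees (refraction
#' plus solar radius). Accuracy is within a couple of minutes, which is far
#' below the hourly fix-subsampling grid it feeds.
#'
#' @param date A `Date` vector (the local solar date of interest).
#' @param lat,lon Position in decimal degrees; recycled against `date`.
#' @return A tibble with columns `date`, `sunrise`, `sunset` (`POSIXct`,
#'   UTC). Under polar day the full civil day is returned; under polar night
#'   `sunrise == sunset` (an empty daylight window).
#' @export
solar_times <- function(date, lat, lon) {
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(as.Date(date), n)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)

  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

  phi <- lat * pi / 180
  zen <- (90 + 0.833) * pi / 180
  cos_ha <- (cos(zen) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")

  ha_deg <- acos(pmin(pmax(cos_ha, -1), 1)) * 180 / pi
  rise_min <- 720 - 4 * (lon + ha_deg) - eqtime
  set_min <- 720 - 4 * (lon - ha_deg) - eqtime
  # polar day: daylight covers the civil day; polar night: empty window
  rise_min[cos_ha < -1] <- 0
  set_min[cos_ha < -1] <- 1440
  rise_min[cos_ha > 1] <- 720
  set_min[cos_ha > 1] <- 720

  tibble::tibble(
    date = date,
    sunrise = midnight + rise_min * 60,
    sunset = midnight + set_min * 60
  )
}

# local solar date of a UTC instant at a given longitude
solar_date <- function(timestamp, lon) {
  as.Date(timestamp + lon / 15 * 3600, tz = "UTC")
}
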