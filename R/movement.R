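#' Segmentation configuration
#'
#' Thresholds governing day classification and endpoint detection. The
#' defaults encode the field rules for a soaring raptor on spring migration:
#' a day is migratory when its total path exceeds 40 km and/or its roost-to-
#' roost beeline exceeds 19 km; arrival at the breeding/summer area is a
#' cessation of long-distance (> 50 km) northward (azimuth in
#' (270, 360) U [0, 90)) daily movement together with a turning angle above
#' 100 degrees relative to the previous day.
#'
#' @param migratory_total_km Total daily path threshold (km) for a migratory
#'   day.
#' @param migratory_beeline_km Roost-to-roost beeline threshold (km).
#' @param arrival_longdist_km Daily beeline above which a day still counts as
#'   long-distance movement for the arrival rule (km).
#' @param arrival_turn_deg Turning-angle threshold (degrees) for arrival.
#' @param subsample_interval_min Daylight subsampling grid spacing (minutes).
#' @param arrival_lookahead_days Number of subsequent days that must contain
#'   no further northern long-distance day for an arrival candidate to stand
#'   (an automatic surrogate for visual track inspection).
#' @param death_window_h Length (hours) of the stationary/flatline window
#'   that signals death.
#' @param death_displacement_km Maximum displacement (km) within the death
#'   window.
#' @param death_acc_epsilon Absolute activity-variance ceiling used when no
#'   migratory-day activity baseline is available; otherwise the ceiling is
#'   `death_acc_frac` times the migratory-day mean.
#' @param death_acc_frac Fraction of the migratory-day mean activity variance
#'   below which the signal is considered flatline.
#' @param endpoint_tie One of `"death"`, `"arrival"`: which endpoint wins if
#'   both rules fire on the same day.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(migratory_total_km = 40,
                                migratory_beeline_km = 19,
                                arrival_longdist_km = 50,
                                arrival_turn_deg = 100,
                                subsample_interval_min = 60,
                                arrival_lookahead_days = 5,
                                death_window_h = 24,
                                death_displacement_km = 0.5,
                                death_acc_epsilon = 0.01,
                                death_acc_frac = 0.01,
                                endpoint_tie = c("death", "arrival")) {
  cfg <- list(
    migratory_total_km = migratory_total_km,
    migratory_beeline_km = migratory_beeline_km,
    arrival_longdist_km = arrival_longdist_km,
    arrival_turn_deg = arrival_turn_deg,
    subsample_interval_min = subsample_interval_min,
    arrival_lookahead_days = arrival_lookahead_days,
    death_window_h = death_window_h,
    death_displacement_km = death_displacement_km,
    death_acc_epsilon = death_acc_epsilon,
    death_acc_frac = death_acc_frac,
    endpoint_tie = match.arg(endpoint_tie)
  )
  num <- vapply(cfg[1:10], is.numeric, logical(1))
  if (!all(num) || any(unlist(cfg[1:10]) <= 0)) {
    abort("all segmentation thresholds must be positive numbers")
  }
  structure(cfg, class = "segmentation_config")
}

#' Read a Movebank-style GPS fix table
#'
#' @param path CSV file with one row per fix.
#' @param columns Named character vector mapping the canonical names
#'   (`individual_id`, `timestamp`, `lat`, `lon`, `acc_var`) to the file's
#'   column names.
#' @return A tibble of fixes, timestamps parsed as UTC `POSIXct`, sorted by
#'   individual and time.
#' @export
read_gps_fixes <- function(path,
                           columns = c(individual_id = "individual_id",
                                       timestamp = "timestamp",
                                       lat = "lat", lon = "lon",
                                       acc_var = "acc_var")) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(columns[c("individual_id", "timestamp", "lat", "lon")]),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("fix file lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    individual_id = as.character(raw[[columns[["individual_id"]]]]),
    timestamp = as.POSIXct(raw[[columns[["timestamp"]]]], tz = "UTC"),
    lat = as.numeric(raw[[columns[["lat"]]]]),
    lon = as.numeric(raw[[columns[["lon"]]]]),
    acc_var = if (columns[["acc_var"]] %in% names(raw)) {
      as.numeric(raw[[columns[["acc_var"]]]])
    } else {
      NA_real_
    }
  )
  dplyr::arrange(out, .data$individual_id, .data$timestamp)
}

#' Subsample fixes to a daylight grid
#'
#' Retains at most one fix per grid slot of `subsample_interval_min` minutes
#' anchored at local sunrise, keeping only fixes between sunrise and sunset
#' computed at the individual's median position for that local solar day.
#' Each grid time receives its nearest fix; a stream that is already on the
#' grid passes through unchanged.
#'
#' @param fixes Tibble with columns `individual_id`, `timestamp` (UTC
#'   `POSIXct`), `lat`, `lon` and optionally `acc_var`.
#' @param config A [segmentation_config()].
#' @return The subsampled fix tibble with an added `solar_date` column.
#' @export
subsample_daylight <- function(fixes, config = segmentation_config()) {
  if (nrow(fixes) == 0) {
    return(dplyr::mutate(fixes, solar_date = as.Date(character())))
  }
  check_fixes(fixes)
  interval <- config$subsample_interval_min * 60
  fixes |>
    dplyr::mutate(solar_date = solar_date(.data$timestamp, .data$lon)) |>
    dplyr::group_by(.data$individual_id, .data$solar_date) |>
    dplyr::group_modify(function(day, key) {
      st <- solar_times(key$solar_date, median(day$lat), median(day$lon))
      day <- dplyr::filter(day, .data$timestamp >= st$sunrise,
                           .data$timestamp <= st$sunset)
      if (nrow(day) == 0) return(day)
      mins <- as.numeric(difftime(day$timestamp, st$sunrise, units = "secs"))
      slot <- round(mins / interval)
      day |>
        dplyr::mutate(.slot = slot,
                      .off = abs(mins - slot * interval)) |>
        dplyr::group_by(.data$.slot) |>
        dplyr::slice_min(.data$.off, n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::select(-".slot", -".off")
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("solar_date", .after = dplyr::last_col()) |>
    dplyr::arrange(.data$individual_id, .data$timestamp)
}

#' Per-day movement metrics
#'
#' Collapses (subsampled) fixes into one row per individual and local solar
#' day: total path length, roost-to-roost beeline and its azimuth, and the
#' turning angle relative to the previous day's azimuth. The roosting sites
#' are taken as the first and last retained daylight fix of the day.
#'
#' @param fixes Fix tibble; if it lacks a `solar_date` column it is passed
#'   through [subsample_daylight()] first.
#' @inheritParams subsample_daylight
#' @return A tibble with one `DailySegment` row per individual-day:
#'   `individual_id`, `date`, roost coordinates, `total_distance_km`,
#'   `beeline_km`, `azimuth_deg`, `turning_angle_deg`, `n_fixes`,
#'   `mean_acc_var`, `degenerate`.
#' @export
daily_metrics <- function(fixes, config = segmentation_config()) {
  if (!"solar_date" %in% names(fixes)) {
    fixes <- subsample_daylight(fixes, config)
  }
  if (nrow(fixes) == 0) {
    abort("no daylight fixes to segment")
  }
  seg <- fixes |>
    dplyr::group_by(.data$individual_id, date = .data$solar_date) |>
    dplyr::summarise(
      roost_start_lat = .data$lat[1], roost_start_lon = .data$lon[1],
      roost_end_lat = dplyr::last(.data$lat), roost_end_lon = dplyr::last(.data$lon),
      total_distance_km = if (dplyr::n() >= 2) {
        sum(rhumb_distance(.data$lat[-dplyr::n()], .data$lon[-dplyr::n()],
                           .data$lat[-1], .data$lon[-1]))
      } else 0,
      n_fixes = dplyr::n(),
      mean_acc_var = if (all(is.na(.data$acc_var))) NA_real_ else {
        mean(.data$acc_var, na.rm = TRUE)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$n_fixes < 2,
      beeline_km = ifelse(.data$degenerate, 0,
                          rhumb_distance(.data$roost_start_lat, .data$roost_start_lon,
                                         .data$roost_end_lat, .data$roost_end_lon)),
      azimuth_deg = ifelse(.data$beeline_km > 1e-9,
                           suppressWarnings(safe_bearing(.data$roost_start_lat,
                                                         .data$roost_start_lon,
                                                         .data$roost_end_lat,
                                                         .data$roost_end_lon)),
                           NA_real_)
    ) |>
    dplyr::arrange(.data$individual_id, .data$date) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(
      turning_angle_deg = turning_angle(.data$azimuth_deg,
                                        dplyr::lag(.data$azimuth_deg))
    ) |>
    dplyr::ungroup()
  dplyr::select(seg, "individual_id", "date",
                "roost_start_lat", "roost_start_lon",
                "roost_end_lat", "roost_end_lon",
                "total_distance_km", "beeline_km", "azimuth_deg",
                "turning_angle_deg", "n_fixes", "mean_acc_var", "degenerate")
}

safe_bearing <- function(lat1, lon1, lat2, lon2) {
  out <- rep(NA_real_, length(lat1))
  ok <- !(lat1 == lat2 & wrap_angle(lon2 - lon1) == 0)
  if (any(ok)) {
    out[ok] <- rhumb_bearing(lat1[ok], lon1[ok], lat2[ok], lon2[ok])
  }
  out
}

#' Classify days as migratory or stopover
#'
#' A day is migratory when its total path exceeds the 40-km threshold and/or
#' its roost-to-roost beeline exceeds the 19-km threshold; otherwise it is a
#' stopover day.
#'
#' @param segments Output of [daily_metrics()].
#' @inheritParams subsample_daylight
#' @return `segments` with an added `day_class` factor
#'   (`migratory`/`stopover`).
#' @export
classify_days <- function(segments, config = segmentation_config()) {
  dplyr::mutate(segments, day_class = factor(
    ifelse(.data$total_distance_km > config$migratory_total_km |
             .data$beeline_km > config$migratory_beeline_km,
           "migratory", "stopover"),
    levels = c("migratory", "stopover")
  ))
}

#' Detect the migration endpoint of a track
#'
#' Scans one individual's classified day segments and raw fixes for the
#' first endpoint:
#' * **arrival** — the first day whose beeline is at most
#'   `arrival_longdist_km` *or* whose azimuth falls outside the northern
#'   sector, *and* whose turning angle exceeds `arrival_turn_deg`, provided
#'   no northern long-distance day occurs within the following
#'   `arrival_lookahead_days` days;
#' * **death** — the first window of `death_window_h` hours during which
#'   every fix stays within `death_displacement_km` of the window start and
#'   all activity variance lies below the flatline ceiling;
#' * **loss** — the fix stream ends with neither condition met.
#'
#' @param segments Classified segments for one individual
#'   ([classify_days()]).
#' @param fixes Raw (or subsampled) fixes for the same individual.
#' @inheritParams subsample_daylight
#' @return One-row tibble: `individual_id`, `endpoint`
#'   (`arrival`/`death`/`loss`), `endpoint_date`, `endpoint_lat`,
#'   `endpoint_lon`.
#' @export
detect_endpoint <- function(segments, fixes, config = segmentation_config()) {
  id <- unique(as.character(segments$individual_id))
  if (length(id) > 1) abort("detect_endpoint() works on a single individual")
  if (nrow(segments) == 0) {
    ts <- if (nrow(fixes)) min(fixes$timestamp) else as.POSIXct(NA)
    return(tibble::tibble(individual_id = if (length(id)) id else unique(as.character(fixes$individual_id)),
                          endpoint = "loss",
                          endpoint_date = as.Date(ts, tz = "UTC"),
                          endpoint_lat = NA_real_, endpoint_lon = NA_real_))
  }
  segments <- dplyr::arrange(segments, .data$date)
  fixes <- dplyr::arrange(fixes, .data$timestamp)

  arrival <- detect_arrival(segments, config)
  death <- detect_death(segments, fixes, config)

  pick <- function(a, b) {
    if (is.null(a$date) && is.null(b$date)) return(NULL)
    if (is.null(a$date)) return(b)
    if (is.null(b$date)) return(a)
    if (a$date < b$date) a
    else if (b$date < a$date) b
    else if (config$endpoint_tie == "death") {
      if (a$endpoint == "death") a else b
    } else {
      if (a$endpoint == "arrival") a else b
    }
  }
  hit <- pick(arrival, death)
  if (is.null(hit)) {
    last_fix <- fixes[nrow(fixes), ]
    return(tibble::tibble(individual_id = id, endpoint = "loss",
                          endpoint_date = as.Date(last_fix$timestamp, tz = "UTC"),
                          endpoint_lat = NA_real_, endpoint_lon = NA_real_))
  }
  tibble::tibble(individual_id = id, endpoint = hit$endpoint,
                 endpoint_date = hit$date,
                 endpoint_lat = hit$lat, endpoint_lon = hit$lon)
}

detect_arrival <- function(segments, config) {
  n <- nrow(segments)
  if (n < 2) return(list(date = NULL))
  longdist_north <- segments$beeline_km > config$arrival_longdist_km &
    !is.na(segments$azimuth_deg) & is_northern(segments$azimuth_deg)
  for (d in 2:n) {
    # a cessation of long-distance northward movement presupposes that such
    # movement happened: birds that never departed cannot "arrive"
    if (!any(longdist_north[seq_len(d - 1)])) next
    ceased <- segments$beeline_km[d] <= config$arrival_longdist_km ||
      is.na(segments$azimuth_deg[d]) ||
      !is_northern(segments$azimuth_deg[d])
    turn <- !is.na(segments$turning_angle_deg[d]) &&
      segments$turning_angle_deg[d] > config$arrival_turn_deg
    if (ceased && turn) {
      ahead <- segments$date > segments$date[d] &
        segments$date <= segments$date[d] + config$arrival_lookahead_days
      if (!any(longdist_north[ahead])) {
        return(list(endpoint = "arrival", date = segments$date[d],
                    lat = segments$roost_end_lat[d - 1],
                    lon = segments$roost_end_lon[d - 1]))
      }
    }
  }
  list(date = NULL)
}

detect_death <- function(segments, fixes, config) {
  if (nrow(fixes) < 2 || all(is.na(fixes$acc_var))) return(list(date = NULL))
  mig_mean <- segments |>
    dplyr::filter(.data$day_class == "migratory") |>
    dplyr::pull(.data$mean_acc_var)
  eps <- if (length(mig_mean) && any(!is.na(mig_mean))) {
    config$death_acc_frac * mean(mig_mean, na.rm = TRUE)
  } else {
    config$death_acc_epsilon
  }
  window <- config$death_window_h * 3600
  n <- nrow(fixes)
  flat <- !is.na(fixes$acc_var) & fixes$acc_var < eps
  for (i in seq_len(n)) {
    if (!flat[i]) next
    in_win <- which(fixes$timestamp >= fixes$timestamp[i] &
                      fixes$timestamp <= fixes$timestamp[i] + window)
    if (as.numeric(difftime(fixes$timestamp[max(in_win)],
                            fixes$timestamp[i], units = "secs")) < window * 0.99) {
      next  # stream too short to certify a full window
    }
    disp <- rhumb_distance(fixes$lat[i], fixes$lon[i],
                           fixes$lat[in_win], fixes$lon[in_win])
    if (all(flat[in_win]) && all(disp < config$death_displacement_km)) {
      return(list(endpoint = "death",
                  date = solar_date(fixes$timestamp[i], fixes$lon[i]),
                  lat = fixes$lat[n], lon = fixes$lon[n]))
    }
  }
  list(date = NULL)
}

#' Segment a multi-individual fix table end to end
#'
#' Convenience wrapper: daylight subsampling, daily metrics, day
#' classification and endpoint detection for every individual in the table.
#'
#' @param fixes Fix tibble for one or more individuals.
#' @inheritParams subsample_daylight
#' @return An object of class `track_segmentation`: a list with `segments`
#'   (classified day table), `outcomes` (one endpoint row per individual)
#'   and the `config` used. `tidy()` returns the segment table, `glance()`
#'   the per-individual outcome summary.
#' @export
segment_track <- function(fixes, config = segmentation_config()) {
  check_fixes(fixes)
  sub <- subsample_daylight(fixes, config)
  segments <- classify_days(daily_metrics(sub, config), config)
  outcomes <- segments |>
    dplyr::group_split(.data$individual_id) |>
    purrr::map(function(seg) {
      id <- seg$individual_id[1]
      detect_endpoint(seg, dplyr::filter(fixes, .data$individual_id == id), config)
    }) |>
    dplyr::bind_rows()
  structure(list(segments = segments, outcomes = outcomes, config = config),
            class = "track_segmentation")
}

#' Migration distance accounting for one segmented track
#'
#' Sums daily path lengths over migratory days before the endpoint
#' (the post-stopover migration distance), and computes the beeline-based
#' total migration distance (wintering grounds to the stopover capture site
#' plus capture site to breeding grounds) when both remote sites are known.
#' For tracks ending in death it also reports the distance from the capture
#' site to the death location and the number of days survived.
#'
#' @param segments Classified day segments for one individual.
#' @param outcome One-row endpoint tibble from [detect_endpoint()].
#' @param capture_point,winter_point,breeding_point Length-2 numeric
#'   `c(lat, lon)`; the last two may be `NULL`.
#' @return One-row tibble of class `migration_summary` fields.
#' @export
migration_summary <- function(segments, outcome, capture_point,
                              winter_point = NULL, breeding_point = NULL) {
  segments <- dplyr::arrange(segments, .data$date)
  pre <- dplyr::filter(segments, .data$date < outcome$endpoint_date |
                         (outcome$endpoint == "loss" &
                            .data$date <= outcome$endpoint_date))
  n_mig <- sum(pre$day_class == "migratory")
  n_stop <- sum(pre$day_class == "stopover")
  post_eilat <- sum(pre$total_distance_km[pre$day_class == "migratory"])

  total_mig <- NA_real_
  if (!is.null(winter_point) && !is.null(breeding_point)) {
    total_mig <- rhumb_distance(winter_point[1], winter_point[2],
                                capture_point[1], capture_point[2]) +
      rhumb_distance(capture_point[1], capture_point[2],
                     breeding_point[1], breeding_point[2])
  } else if (!is.null(breeding_point) && outcome$endpoint != "arrival") {
    warn("breeding point given for a non-arrival track; total distance left missing")
  }

  dist_death <- NA_real_
  days_death <- NA_real_
  if (outcome$endpoint == "death") {
    dist_death <- rhumb_distance(capture_point[1], capture_point[2],
                                 outcome$endpoint_lat, outcome$endpoint_lon)
    days_death <- as.numeric(outcome$endpoint_date - min(segments$date))
  }

  tibble::tibble(
    individual_id = outcome$individual_id,
    endpoint = outcome$endpoint,
    n_migratory_days = n_mig,
    n_stopover_days = n_stop,
    post_eilat_distance_km = post_eilat,
    total_migration_distance_km = total_mig,
    distance_until_death_km = dist_death,
    days_until_death = days_death
  )
}

check_fixes <- function(fixes) {
  need <- c("individual_id", "timestamp", "lat", "lon")
  missing_cols <- setdiff(need, names(fixes))
  if (length(missing_cols)) {
    abort(paste0("fix table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ord <- fixes |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$timestamp, strictly = TRUE),
                     .groups = "drop")
  if (!all(ord$ok)) {
    abort("timestamps must be strictly increasing within each individual")
  }
  invisible(NULL)
}
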