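#' Track simulation scenario
#'
#' Describes one synthetic spring-migration track leaving a stopover site
#' northbound: a run of migratory days interleaved with stopover runs,
#' terminated by one of three endpoints (arrival at the summer area, death,
#' or loss of transmitter connection). Defaults emulate a soaring raptor
#' departing the Eilat stopover in April.
#'
#' @param seed Integer RNG seed for this track.
#' @param start_lat,start_lon Stopover (capture) site, decimal degrees.
#' @param start_date First tracked day (`Date`).
#' @param n_migratory_days Number of migratory days before the endpoint.
#' @param stopover_run_lengths Integer vector: lengths of stopover runs
#'   interleaved into the migratory phase. Runs longer than the arrival
#'   lookahead window would themselves satisfy the arrival rule, so lengths
#'   must stay below it.
#' @param stopover_after Migratory-day indices after which each stopover run
#'   is inserted (recycled/validated against `stopover_run_lengths`); `NULL`
#'   picks positions at random.
#' @param daily_step_km Mean migratory-day beeline displacement (km); must
#'   exceed the 40-km migratory-day threshold.
#' @param heading_deg Mean migratory azimuth; must lie in the northern
#'   sector (270, 360) U [0, 90) when `endpoint = "arrival"`.
#' @param heading_sd_deg Day-to-day SD of the migratory azimuth.
#' @param fix_interval_min Fix spacing in minutes.
#' @param endpoint One of `"arrival"`, `"death"`, `"loss"`.
#' @param n_post_days Days of post-arrival local wandering to simulate
#'   (arrival endpoint only).
#' @param n_death_days Days of flatline fixes appended after death.
#' @param n_predeath_stopover_days Stopover days spent at the start site
#'   before a death endpoint (death-at-stopover tracks).
#' @param stopover_spread_km Radius (km) of the area a bird wanders around
#'   its stopover anchor roost; roost-to-roost displacements stay well below
#'   the 19-km migratory threshold.
#' @return A list of class `track_scenario`.
#' @export
track_scenario <- function(seed = 1,
                           start_lat = 29.55, start_lon = 34.95,
                           start_date = as.Date("2019-04-10"),
                           n_migratory_days = 20,
                           stopover_run_lengths = c(2, 3),
                           stopover_after = NULL,
                           daily_step_km = 150,
                           heading_deg = 10,
                           heading_sd_deg = 15,
                           fix_interval_min = 60,
                           endpoint = c("arrival", "death", "loss"),
                           n_post_days = 3,
                           n_death_days = 3,
                           n_predeath_stopover_days = 0,
                           stopover_spread_km = 5) {
  endpoint <- match.arg(endpoint)
  if (daily_step_km <= 40) {
    abort("daily_step_km must exceed the 40-km migratory-day threshold")
  }
  if (endpoint == "arrival" && !is_northern(heading_deg)) {
    abort("arrival endpoint requires a northern heading (the arrival rule could never fire)")
  }
  if (length(stopover_run_lengths) && any(stopover_run_lengths >= 5)) {
    abort("stopover runs must be shorter than the arrival lookahead window")
  }
  if (n_predeath_stopover_days > 0 && n_migratory_days > 0) {
    abort(paste0("pre-death stopover days model birds that die before ",
                 "departing; use n_migratory_days = 0 (a pause after ",
                 "migration is behaviourally an arrival)"))
  }
  structure(list(
    seed = as.integer(seed), start_lat = start_lat, start_lon = start_lon,
    start_date = as.Date(start_date),
    n_migratory_days = n_migratory_days,
    stopover_run_lengths = stopover_run_lengths,
    stopover_after = stopover_after,
    daily_step_km = daily_step_km,
    heading_deg = heading_deg, heading_sd_deg = heading_sd_deg,
    fix_interval_min = fix_interval_min,
    endpoint = endpoint,
    n_post_days = n_post_days, n_death_days = n_death_days,
    n_predeath_stopover_days = n_predeath_stopover_days,
    stopover_spread_km = stopover_spread_km
  ), class = "track_scenario")
}

#' Simulate one GPS track with known ground truth
#'
#' Migratory days travel `daily_step_km` (log-normally jittered, floored at
#' 45 km) along a rhumb line at a wrapped-normal heading around
#' `heading_deg`; intermediate fixes sit on that rhumb with small lateral
#' jitter so the within-day path always exceeds the beeline. Stopover days
#' wander locally with a roost-to-roost displacement below 19 km. Endpoints:
#' arrival appends a sharp-turn short day followed by local wandering; death
#' appends near-stationary days whose activity variance flatlines below 1%
#' of the migratory-day mean; loss truncates the stream mid-migration with
#' no behavioural change. Fixes are emitted on a fixed daylight window
#' (05:00-15:00 UTC), inside civil daylight throughout the simulated
#' latitudes in April-May.
#'
#' @param scenario A [track_scenario()].
#' @param individual_id Identifier attached to every fix.
#' @return A list with `fixes` (tibble: `individual_id`, `timestamp`, `lat`,
#'   `lon`, `acc_var`) and `truth` (list: per-day `labels` tibble, `endpoint`,
#'   `endpoint_date`, `endpoint_lat`/`endpoint_lon`, scenario echo).
#' @export
simulate_track <- function(scenario, individual_id = "bird_01") {
  stopifnot(inherits(scenario, "track_scenario"))
  set.seed(scenario$seed)
  sc <- scenario

  # --- day plan ------------------------------------------------------------
  plan <- rep("migratory", sc$n_migratory_days)
  if (length(sc$stopover_run_lengths) > 0 && sc$n_migratory_days > 1) {
    after <- sc$stopover_after
    if (is.null(after)) {
      after <- sort(sample(seq_len(sc$n_migratory_days - 1),
                           length(sc$stopover_run_lengths)))
    }
    for (k in rev(seq_along(sc$stopover_run_lengths))) {
      pos <- which(cumsum(plan == "migratory") == after[k])[1]
      plan <- append(plan, rep("stopover", sc$stopover_run_lengths[k]),
                     after = pos)
    }
  }
  if (sc$endpoint == "death" && sc$n_predeath_stopover_days > 0) {
    plan <- c(plan, rep("stopover", sc$n_predeath_stopover_days))
  }
  n_before <- length(plan)
  if (sc$endpoint == "arrival") {
    plan <- c(plan, "arrival_day", rep("post", sc$n_post_days))
  } else if (sc$endpoint == "death") {
    plan <- c(plan, rep("dead", sc$n_death_days))
  }

  # --- walk the plan -------------------------------------------------------
  lat <- sc$start_lat; lon <- sc$start_lon
  heading_prev <- sc$heading_deg
  anchor <- NULL    # roost a stopover run wanders around
  fix_rows <- vector("list", length(plan))
  labels <- character(length(plan))
  dates <- sc$start_date + seq_along(plan) - 1
  arrival_roost <- NULL

  for (d in seq_along(plan)) {
    kind <- plan[d]
    if (!kind %in% c("stopover", "post")) anchor <- NULL
    if (kind == "migratory") {
      bearing <- clamp_northern(rnorm(1, sc$heading_deg, sc$heading_sd_deg))
      step <- max(45, sc$daily_step_km * exp(rnorm(1, 0, 0.1)))
      day <- simulate_day_fixes(lat, lon, bearing, step, dates[d],
                                sc$fix_interval_min,
                                acc_range = c(0.8, 1.2), jitter_km = 2)
      heading_prev <- bearing
      labels[d] <- "migratory"
    } else if (kind %in% c("stopover", "post")) {
      if (is.null(anchor)) anchor <- c(lat, lon)
      day <- simulate_stopover_day(lat, lon, anchor, sc$stopover_spread_km,
                                   dates[d], sc$fix_interval_min)
      labels[d] <- "stopover"
    } else if (kind == "arrival_day") {
      arrival_roost <- c(lat, lon)
      bearing <- (heading_prev + 180 + runif(1, -30, 30)) %% 360
      step <- runif(1, 3, 10)
      day <- simulate_day_fixes(lat, lon, bearing, step, dates[d],
                                sc$fix_interval_min,
                                acc_range = c(0.2, 0.5), jitter_km = 0.5)
      labels[d] <- "stopover"
    } else { # dead
      day <- simulate_day_fixes(lat, lon, 0, 0, dates[d],
                                sc$fix_interval_min,
                                acc_range = c(1e-4, 1e-3), jitter_km = 0.005)
      labels[d] <- "stopover"
    }
    fix_rows[[d]] <- day$fixes
    lat <- day$end_lat; lon <- day$end_lon
  }

  fixes <- dplyr::bind_rows(fix_rows)
  fixes$individual_id <- individual_id
  fixes <- dplyr::relocate(fixes, "individual_id")

  truth <- list(
    labels = tibble::tibble(date = dates, day_class = labels),
    endpoint = sc$endpoint,
    endpoint_date = switch(sc$endpoint,
      arrival = dates[n_before + 1],
      death = dates[n_before + 1],
      loss = dates[length(dates)]
    ),
    endpoint_lat = switch(sc$endpoint,
      arrival = arrival_roost[1], death = lat, loss = NA_real_),
    endpoint_lon = switch(sc$endpoint,
      arrival = arrival_roost[2], death = lon, loss = NA_real_),
    n_days_before_endpoint = n_before,
    scenario = sc
  )
  list(fixes = fixes, truth = truth)
}

# keep a migratory heading inside the northern sector (and away from its
# edges so subsampling jitter cannot push a daily azimuth across them)
clamp_northern <- function(b) {
  b <- ((b + 180) %% 360) - 180   # (-180, 180], north = 0
  pmax(pmin(b, 80), -80) %% 360
}

# one stopover day: the roost moves to a random point within
# `spread_km` of the run's anchor roost, keeping displacements far below
# the 19-km migratory threshold however long the run lasts
simulate_stopover_day <- function(lat, lon, anchor, spread_km, date,
                                  interval_min) {
  end <- rhumb_destination(anchor[1], anchor[2], runif(1, 0, 360),
                           runif(1, 0.1, 1) * spread_km)
  step <- rhumb_distance(lat, lon, end$lat, end$lon)
  bearing <- if (step > 1e-6) rhumb_bearing(lat, lon, end$lat, end$lon) else 0
  simulate_day_fixes(lat, lon, bearing, step, date, interval_min,
                     acc_range = c(0.2, 0.5), jitter_km = 0.5)
}

# one day of fixes along a rhumb line from (lat, lon): `step` km at
# `bearing`, hourly-ish spacing in a fixed daylight UTC window, lateral
# jitter on interior fixes so total path > beeline
simulate_day_fixes <- function(lat, lon, bearing, step, date, interval_min,
                               acc_range, jitter_km) {
  t0 <- as.POSIXct(paste(date, "05:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(date, "15:00:00"), tz = "UTC")
  times <- seq(t0, t1, by = interval_min * 60)
  n <- length(times)
  frac <- seq(0, 1, length.out = n)
  if (step > 0) {
    pos <- rhumb_destination(lat, lon, bearing, frac * step)
  } else {
    pos <- list(lat = rep(lat, n), lon = rep(lon, n))
  }
  # lateral jitter, interior fixes only, so roosts stay on the rhumb
  if (n > 2) {
    off <- runif(n - 2, 0.2, 1) * jitter_km * sample(c(-1, 1), n - 2, TRUE)
    perp <- (bearing + 90) %% 360
    moved <- rhumb_destination(pos$lat[2:(n - 1)], pos$lon[2:(n - 1)],
                               perp, off)
    pos$lat[2:(n - 1)] <- moved$lat
    pos$lon[2:(n - 1)] <- moved$lon
  }
  list(
    fixes = tibble::tibble(
      timestamp = times, lat = pos$lat, lon = pos$lon,
      acc_var = runif(n, acc_range[1], acc_range[2])
    ),
    end_lat = pos$lat[n], end_lon = pos$lon[n]
  )
}
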