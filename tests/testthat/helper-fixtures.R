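# Small in-code fixtures and independent oracles shared across test files.

# wide count tibble from a plain matrix
counts_tbl <- function(mat, is_control = rep(FALSE, nrow(mat))) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("t", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(mat), is_control = is_control),
    tibble::as_tibble(mat)
  )
}

# four-leaf toy tree used in the diversity examples
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
}

# hand-built fix table: one individual, hourly daylight fixes along given
# day-by-day displacement legs (km) at given bearings
toy_fixes <- function(legs_km, bearings_deg, start = c(29.55, 34.95),
                      start_date = as.Date("2019-04-10"), n_per_day = 11) {
  lat <- start[1]; lon <- start[2]
  rows <- list()
  for (d in seq_along(legs_km)) {
    t0 <- as.POSIXct(paste(start_date + d - 1, "05:00:00"), tz = "UTC")
    times <- t0 + 3600 * (seq_len(n_per_day) - 1)
    frac <- seq(0, 1, length.out = n_per_day)
    pos <- rhumb_destination(lat, lon, bearings_deg[d], frac * legs_km[d])
    rows[[d]] <- tibble::tibble(
      individual_id = "b1", timestamp = times,
      lat = pos$lat, lon = pos$lon, acc_var = 1
    )
    lat <- pos$lat[n_per_day]; lon <- pos$lon[n_per_day]
  }
  dplyr::bind_rows(rows)
}

# independent loxodrome length: piecewise constant-bearing polyline with
# n_steps equal latitude increments (numerical integration oracle)
loxodrome_numeric <- function(lat1, lon1, lat2, lon2, n_steps = 1e5,
                              radius_km = 6371) {
  theta <- rhumb_bearing(lat1, lon1, lat2, lon2) * pi / 180
  phi <- seq(lat1, lat2, length.out = n_steps + 1) * pi / 180
  if (abs(lat2 - lat1) < 1e-12) {
    # pure parallel: arc length along the latitude circle
    dlam <- abs(lon2 - lon1) * pi / 180
    return(radius_km * dlam * cos(lat1 * pi / 180))
  }
  dphi <- diff(phi)
  sum(abs(dphi) / abs(cos(theta))) * radius_km
}

# Welch t oracle from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Fisher one-sided (control-enriched) p by exhaustive hypergeometric sum
fisher_oracle <- function(a, n_ctrl, b, n_true) {
  k <- a + b
  sum(vapply(a:min(k, n_ctrl), function(x) {
    stats::dhyper(x, n_ctrl, n_true, k)
  }, numeric(1)))
}

# quick default-free community for metric tests
tiny_community <- function(seed, n_f = 8, n_m = 8, n_taxa = 40,
                           depth = c(2000, 3000), ...) {
  md <- add_condition(simulate_metadata(n_f, n_m, seed = seed))
  com <- simulate_community(community_scenario(
    seed = seed + 1, n_taxa = n_taxa, depth_range = depth,
    n_low_depth = 0, n_pcr_failed = 0, n_controls = 0,
    n_contaminants = 0, n_offtarget = 0, ...
  ), md)
  list(md = md, com = com)
}
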