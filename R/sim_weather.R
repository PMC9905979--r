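#' Simulate the gridded weather world and precipitation stations
#'
#' Generates hourly near-surface fields (u- and v-wind, temperature,
#' surface pressure, total cloud cover) on a regular lat-lon grid over the
#' configured seasons, plus a set of stations reporting binary hourly
#' rain.  Each field is the sum of a domain-mean AR(1) "synoptic" latent,
#' AR(1) north-south and east-west gradient latents and small white
#' cell-level noise; pressure is a bounded random walk; cloud cover is a
#' logistic transform of a smooth latent; rain is Bernoulli with a
#' log-odds that increases with the local cloud latent.
#'
#' @param config A [sim_config()].
#' @return Object of class `weather_world`: grid vectors `lat`, `lon`,
#'   hourly `time` (UTC, per-season blocks), arrays `u`, `v`, `t2m`, `sp`,
#'   `tcc` with dim `(time, lat, lon)`, a `stations` data.frame and a
#'   binary `rain` matrix `(time, station)`.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$weather
  bb <- config$bbox
  lat <- seq(bb["lat_min"], bb["lat_max"], by = config$grid_step)
  lon <- seq(bb["lon_min"], bb["lon_max"], by = config$grid_step)
  time <- world_time_axis(config)
  nt <- length(time); nla <- length(lat); nlo <- length(lon)
  if (nt == 0) stop("configuration error: empty weather window")

  set.seed(config$seed)
  latn <- (lat - mean(lat)) / (diff(range(lat)) / 2)
  lonn <- (lon - mean(lon)) / (diff(range(lon)) / 2)
  blocks <- attr(time, "block_len")

  field <- function(mean_val, sd_val) {
    A <- ar1_blocks(blocks, w$ar, sd_val)
    B <- ar1_blocks(blocks, w$ar, w$grad_sd * sd_val)
    C <- ar1_blocks(blocks, w$ar, w$grad_sd * sd_val)
    f <- mean_val + outer(A, rep(1, nla * nlo)) +
      outer(B, rep(latn, times = nlo)) +
      outer(C, rep(lonn, each = nla)) +
      matrix(stats::rnorm(nt * nla * nlo, 0, w$cell_sd), nt)
    array(f, c(nt, nla, nlo))
  }

  u <- field(w$u_mean, w$u_sd)
  v <- field(w$v_mean, w$v_sd)

  hour_of_day <- as.integer(format(time, "%H", tz = "UTC"))
  diurnal <- w$t_diurnal * sin(2 * pi * (hour_of_day - 9) / 24)
  t2m <- field(w$t_mean, w$t_sd)
  t2m <- t2m + array(rep(diurnal, nla * nlo), c(nt, nla, nlo))

  P <- ar1_blocks(blocks, w$p_ar, w$p_innov / sqrt(max(1e-12, 1 - w$p_ar^2)),
                  stationary = FALSE)
  P <- pmin(w$p_halfrange, pmax(-w$p_halfrange, P))
  Pg <- ar1_blocks(blocks, w$ar, w$grad_sd * 100)
  sp <- w$p_mean + outer(P, rep(1, nla * nlo)) +
    outer(Pg, rep(latn, times = nlo)) +
    matrix(stats::rnorm(nt * nla * nlo, 0, 5), nt)
  sp <- array(sp, c(nt, nla, nlo))

  Ac <- ar1_blocks(blocks, w$cloud_ar, w$cloud_lat_sd)
  Bc <- ar1_blocks(blocks, w$cloud_ar, w$grad_sd * w$cloud_lat_sd)
  cl_latent <- w$cloud_mean_logit + outer(Ac, rep(1, nla * nlo)) +
    outer(Bc, rep(latn, times = nlo)) +
    matrix(stats::rnorm(nt * nla * nlo, 0, 0.1), nt)
  cl_latent <- array(cl_latent, c(nt, nla, nlo))
  tcc <- stats::plogis(cl_latent)

  stations <- make_stations(config, w$n_stations)
  li <- vapply(stations$lat, function(x) which.min(abs(lat - x)), integer(1))
  lj <- vapply(stations$lon, function(x) which.min(abs(lon - x)), integer(1))
  rain <- matrix(0L, nt, nrow(stations))
  for (s in seq_len(nrow(stations))) {
    lat_s <- cl_latent[, li[s], lj[s]]
    p <- stats::plogis(stats::qlogis(w$rain_base) +
                         w$rain_cloud_slope * (lat_s - w$cloud_mean_logit))
    rain[, s] <- stats::rbinom(nt, 1L, p)
  }

  structure(list(lat = lat, lon = lon, time = time,
                 u = u, v = v, t2m = t2m, sp = sp, tcc = tcc,
                 cloud_latent = cl_latent,
                 stations = stations, rain = rain, config = config),
            class = "weather_world")
}

#' Hourly time axis over all configured seasons
#' @keywords internal
world_time_axis <- function(config) {
  blocks <- lapply(config$years, function(y) {
    from <- as.POSIXct(paste0(y, "-", config$season_start, " 00:00:00"),
                       tz = "UTC")
    to <- as.POSIXct(paste0(y, "-", config$season_end, " 23:00:00"),
                     tz = "UTC")
    if (to <= from) stop("configuration error: empty season window")
    seq(from, to, by = 3600)
  })
  time <- do.call(c, blocks)
  attr(time, "tzone") <- "UTC"
  attr(time, "block_len") <- lengths(blocks)
  time
}

#' Concatenated per-block AR(1) series
#'
#' Stationary AR(1) with marginal s.d. `sd_marg` (or, with
#' `stationary = FALSE`, a random walk style series started at 0 with
#' innovation s.d. `sd_marg * sqrt(1 - phi^2)`).  Blocks (seasons) are
#' independent.
#' @keywords internal
ar1_blocks <- function(block_len, phi, sd_marg, stationary = TRUE) {
  sd_innov <- sd_marg * sqrt(max(1e-12, 1 - phi^2))
  unlist(lapply(block_len, function(n) {
    e <- stats::rnorm(n, 0, sd_innov)
    x <- numeric(n)
    x[1] <- if (stationary) stats::rnorm(1, 0, sd_marg) else 0
    if (n > 1) for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
    x
  }), use.names = FALSE)
}

#' Precipitation stations for the synthetic world
#'
#' One station at each capture site (guaranteeing coverage within 20 km)
#' and the remainder spread along the coastline.
#' @keywords internal
make_stations <- function(config, n_stations) {
  caps <- capture_sites()
  n_coast <- max(0, n_stations - nrow(caps))
  poly <- coast_polyline()
  pts <- interpolate_polyline(poly, spacing_km = 5)
  idx <- seq(1, length(pts$lat), length.out = n_coast)
  st <- data.frame(lat = c(caps$lat, pts$lat[round(idx)]),
                   lon = c(caps$lon, pts$lon[round(idx)]))
  st$station_id <- sprintf("S%02d", seq_len(nrow(st)))
  st[, c("station_id", "lat", "lon")]
}

#' Capture (tagging) sites of the synthetic study
#' @keywords internal
capture_sites <- function() {
  data.frame(site = c("south", "north"),
             lat = c(54.53, 54.84), lon = c(8.88, 8.78))
}

#' Sample the weather grid at a point and hour
#'
#' Nearest-cell lookup (no interpolation) with an exact hour match, the
#' convention used for reanalysis grid extraction.
#'
#' @param world A `weather_world`.
#' @param lat,lon Point in decimal degrees.
#' @param hour `POSIXct` on the full hour.
#' @return Named list `u`, `v`, `t2m`, `sp`, `tcc`.
#' @export
sample_grid <- function(world, lat, lon, hour) {
  half <- world$config$grid_step / 2 + 1e-9
  if (lat < min(world$lat) - half || lat > max(world$lat) + half ||
      lon < min(world$lon) - half || lon > max(world$lon) + half)
    stop("coverage error: point outside weather grid")
  ti <- match(as.numeric(hour), as.numeric(world$time))
  if (is.na(ti)) stop("coverage error: hour outside weather time range")
  i <- which.min(abs(world$lat - lat))
  j <- which.min(abs(world$lon - lon))
  list(u = world$u[ti, i, j], v = world$v[ti, i, j],
       t2m = world$t2m[ti, i, j], sp = world$sp[ti, i, j],
       tcc = world$tcc[ti, i, j])
}

#' Binary rain at the nearest station
#'
#' Rain value of the nearest precipitation station by great-circle
#' distance, provided it lies within `max_km`; `NA` otherwise (the
#' consuming row is flagged, not errored).  Ties are broken towards the
#' lower `station_id`.
#'
#' @param world A `weather_world`.
#' @param lat,lon Point in decimal degrees.
#' @param hour `POSIXct` on the full hour.
#' @param max_km Maximum station distance (default 20 km).
#' @return 0, 1 or `NA_integer_`.
#' @export
nearest_rain <- function(world, lat, lon, hour, max_km = 20) {
  st <- world$stations
  d <- haversine_km(lat, lon, st$lat, st$lon)
  ord <- order(d, st$station_id)
  if (d[ord[1]] >= max_km) return(NA_integer_)
  ti <- match(as.numeric(hour), as.numeric(world$time))
  if (is.na(ti)) return(NA_integer_)
  as.integer(world$rain[ti, ord[1]])
}

#' Batched covariate samples at one location over many hours
#'
#' Vectorized equivalent of repeated [weather_sample()] calls for a fixed
#' point: grid values, 24-h changes and station rain for a vector of
#' hours.  Hours outside the time axis yield `NA` rows (flagged by the
#' caller), as do rows whose 24-h reference is unavailable.
#'
#' @inheritParams sample_grid
#' @param hours `POSIXct` vector on full hours.
#' @param rain_max_km Maximum station distance for the rain lookup.
#' @return `data.table` with one row per hour.
#' @export
sample_point_series <- function(world, lat, lon, hours, rain_max_km = 20) {
  half <- world$config$grid_step / 2 + 1e-9
  if (lat < min(world$lat) - half || lat > max(world$lat) + half ||
      lon < min(world$lon) - half || lon > max(world$lon) + half)
    stop("coverage error: point outside weather grid")
  i <- which.min(abs(world$lat - lat))
  j <- which.min(abs(world$lon - lon))
  tnum <- as.numeric(world$time)
  ti <- match(as.numeric(hours), tnum)
  tp <- match(as.numeric(hours) - 86400, tnum)
  pick <- function(arr, k) ifelse(is.na(k), NA_real_, arr[cbind(k, i, j)])
  st <- world$stations
  d <- haversine_km(lat, lon, st$lat, st$lon)
  ord <- order(d, st$station_id)
  s <- if (d[ord[1]] < rain_max_km) ord[1] else NA_integer_
  rain <- if (is.na(s)) rep(NA_integer_, length(ti)) else
    ifelse(is.na(ti), NA_integer_, world$rain[cbind(ti, rep(s, length(ti)))])
  data.table::data.table(
    u = pick(world$u, ti), v = pick(world$v, ti),
    t2m = pick(world$t2m, ti), sp = pick(world$sp, ti),
    tcc = pick(world$tcc, ti), rain = as.integer(rain),
    du24 = pick(world$u, ti) - pick(world$u, tp),
    dv24 = pick(world$v, ti) - pick(world$v, tp),
    dt24 = pick(world$t2m, ti) - pick(world$t2m, tp),
    dp24 = pick(world$sp, ti) - pick(world$sp, tp))
}

#' Full covariate sample at a location-time, including 24-h changes
#'
#' The unit of weather annotation: grid values at the hour plus the
#' differences to the same cell 24 h earlier, and station rain.
#'
#' @inheritParams sample_grid
#' @param rain_max_km Maximum station distance for the rain lookup.
#' @return One-row `data.frame` with `u, v, t2m, sp, tcc, rain, du24,
#'   dv24, dt24, dp24`.
#' @export
weather_sample <- function(world, lat, lon, hour, rain_max_km = 20) {
  now <- sample_grid(world, lat, lon, hour)
  prev_hour <- hour - 86400
  prev <- tryCatch(sample_grid(world, lat, lon, prev_hour),
                   error = function(e) NULL)
  rain <- nearest_rain(world, lat, lon, hour, max_km = rain_max_km)
  data.frame(u = now$u, v = now$v, t2m = now$t2m, sp = now$sp, tcc = now$tcc,
             rain = rain,
             du24 = if (is.null(prev)) NA_real_ else now$u - prev$u,
             dv24 = if (is.null(prev)) NA_real_ else now$v - prev$v,
             dt24 = if (is.null(prev)) NA_real_ else now$t2m - prev$t2m,
             dp24 = if (is.null(prev)) NA_real_ else now$sp - prev$sp)
}
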