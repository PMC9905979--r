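#' Simulate raw tag detections from bird histories
#'
#' Converts the true histories into a Motus-style detection table.  At
#' stopover, a tag yields short detection runs at the capture-site
#' receiver every few hours.  In flight, the trajectory is sampled every
#' `flight_step_s` seconds along the route waypoints at constant
#' airspeed; whenever the bird is within the detection radius of a
#' receiver a run of burst-interval-spaced transmissions is emitted, each
#' burst detected with probability `det_prob`.  A landed bird dwells for
#' two hours at the receiver nearest its landing location.  False
#' positives are injected as a Poisson process per receiver-hour with tag
#' IDs drawn from the deployed-tag list.  Timestamps carry a small
#' (sub-burst-interval) jitter.
#'
#' @param histories Output of [simulate_decisions()].
#' @param receivers Output of [make_receivers()].
#' @param world A `weather_world` (time axis; wind for optional drift).
#' @param config The [sim_config()].
#' @return `data.table` with `tag_id`, `ts` (POSIXct UTC), `receiver_id`,
#'   `is_noise`, sorted by time.
#' @export
simulate_detections <- function(histories, receivers, world, config) {
  set.seed(config$seed + 2L)
  if (nrow(histories) == 0)
    return(data.table::data.table(tag_id = character(), ts = as.POSIXct(character(), tz = "UTC"),
                                  receiver_id = character(), is_noise = logical()))
  bi_all <- histories$burst_interval_s
  radius <- config$detection_radius_km
  out <- vector("list", nrow(histories) + 1L)

  nb <- config$run_n_bursts

  for (k in seq_len(nrow(histories))) {
    h <- histories[k, ]
    bi <- h$burst_interval_s
    horizon <- min(
      as.numeric(h$tag_fail_ts),
      as.numeric(as.POSIXct(paste0(h$year, "-", config$season_end, " 23:00:00"),
                            tz = "UTC")), na.rm = TRUE)
    run_t0 <- numeric(0); run_rec <- character(0)

    # stopover runs at the capture-site receiver (if one is in range)
    drec <- haversine_km(h$capture_lat, h$capture_lon, receivers$lat, receivers$lon)
    cap_rec <- receivers$receiver_id[which.min(drec)]
    stop_until <- min(if (!is.na(h$departure_ts)) as.numeric(h$departure_ts) else Inf,
                      horizon)
    if (min(drec) > radius) stop_until <- -Inf
    if (stop_until > as.numeric(h$capture_ts) + 3600) {
      st <- seq(as.numeric(h$capture_ts) + 3600, stop_until,
                by = config$stopover_every_h * 3600)
      run_t0 <- c(run_t0, st); run_rec <- c(run_rec, rep(cap_rec, length(st)))
    }

    # flight trajectory
    if (isTRUE(h$has_flight) && !is.na(h$departure_ts) &&
        as.numeric(h$departure_ts) < horizon) {
      path <- route_path(h$capture_lat, h$capture_lon, h$route)
      stop_at <- if (isTRUE(h$landed)) path$end_index else length(path$lat)
      wp <- flight_positions(path, stop_at, config$airspeed_ms,
                             config$flight_step_s, as.numeric(h$departure_ts))
      if (config$wind_drift) wp <- apply_wind_drift(wp, world, h, config)
      ok <- wp$t <= horizon
      wp <- lapply(wp, `[`, ok)
      if (length(wp$t)) {
        # nearest receiver per waypoint (vectorized over waypoints)
        dmat <- vapply(seq_len(nrow(receivers)), function(j)
          haversine_km(wp$lat, wp$lon, receivers$lat[j], receivers$lon[j]),
          numeric(length(wp$t)))
        dmat <- matrix(dmat, nrow = length(wp$t))
        jm <- max.col(-dmat, ties.method = "first")
        dmin <- dmat[cbind(seq_along(jm), jm)]
        inr <- dmin <= radius
        run_t0 <- c(run_t0, wp$t[inr])
        run_rec <- c(run_rec, receivers$receiver_id[jm[inr]])
      }
      # landing dwell: two hours of runs at the nearest receiver
      if (isTRUE(h$landed) && as.numeric(h$landing_ts) < horizon) {
        d <- haversine_km(h$flight_end_lat, h$flight_end_lon,
                          receivers$lat, receivers$lon)
        jmd <- which.min(d)
        dw_end <- min(as.numeric(h$landing_ts) + 7200, horizon)
        if (d[jmd] > radius) dw_end <- -Inf
        if (dw_end > as.numeric(h$landing_ts) + 300) {
          dw <- seq(as.numeric(h$landing_ts) + 300, dw_end, by = 900)
          run_t0 <- c(run_t0, dw)
          run_rec <- c(run_rec, rep(receivers$receiver_id[jmd], length(dw)))
        }
      }
    }
    if (length(run_t0)) {
      nr <- length(run_t0)
      tt <- rep(run_t0, each = nb) + rep(seq_len(nb) - 1, nr) * bi +
        stats::runif(nr * nb, -0.2, 0.2)
      keep <- stats::runif(nr * nb) < config$det_prob
      if (any(keep))
        out[[k]] <- data.table::data.table(
          tag_id = h$bird_id, ts = tt[keep],
          receiver_id = rep(run_rec, each = nb)[keep], is_noise = FALSE)
    }
  }

  # false positives: Poisson per receiver over the study hours
  n_hours <- length(world$time)
  n_fp <- stats::rpois(nrow(receivers), config$fp_rate * n_hours)
  if (sum(n_fp) > 0) {
    fp_rec <- rep(receivers$receiver_id, n_fp)
    fp_t <- as.numeric(world$time[sample.int(n_hours, sum(n_fp), replace = TRUE)]) +
      stats::runif(sum(n_fp), 0, 3600)
    fp_tag <- histories$bird_id[sample.int(nrow(histories), sum(n_fp),
                                           replace = TRUE)]
    out[[nrow(histories) + 1L]] <-
      data.table::data.table(tag_id = fp_tag, ts = fp_t,
                             receiver_id = fp_rec, is_noise = TRUE)
  }

  det <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(det) == 0)
    return(data.table::data.table(tag_id = character(), ts = as.POSIXct(character(), tz = "UTC"),
                                  receiver_id = character(), is_noise = logical()))
  det[, ts := as.POSIXct(ts, tz = "UTC", origin = "1970-01-01")]
  data.table::setorder(det, ts, tag_id, receiver_id)
  det[]
}

#' Timed positions along a route at constant airspeed
#' @keywords internal
flight_positions <- function(path, stop_at, airspeed_ms, step_s, t0) {
  lat <- path$lat[1:stop_at]; lon <- path$lon[1:stop_at]
  if (length(lat) < 2) return(list(t = t0, lat = lat, lon = lon))
  leg <- haversine_km(lat[-length(lat)], lon[-length(lon)], lat[-1], lon[-1])
  cum <- c(0, cumsum(leg))
  total_s <- cum[length(cum)] * 1000 / airspeed_ms
  tt <- seq(0, total_s, by = step_s)
  dist <- tt * airspeed_ms / 1000
  seg <- findInterval(dist, cum, rightmost.closed = TRUE)
  seg[seg >= length(cum)] <- length(cum) - 1
  frac <- (dist - cum[seg]) / pmax(1e-9, leg[seg])
  list(t = t0 + tt,
       lat = lat[seg] + frac * (lat[seg + 1] - lat[seg]),
       lon = lon[seg] + frac * (lon[seg + 1] - lon[seg]))
}

#' Add wind displacement to flight positions
#'
#' Optional drift: the near-surface wind at the departure cell, sampled
#' hourly, displaces the trajectory cumulatively.
#' @keywords internal
apply_wind_drift <- function(wp, world, h, config) {
  if (!length(wp$t)) return(wp)
  hr <- round_to_hour(as.POSIXct(wp$t, tz = "UTC", origin = "1970-01-01"))
  dis_u <- numeric(length(wp$t)); dis_v <- numeric(length(wp$t))
  uu <- vv <- 0
  for (i in seq_along(wp$t)) {
    s <- tryCatch(sample_grid(world, h$capture_lat, h$capture_lon, hr[i]),
                  error = function(e) NULL)
    if (!is.null(s)) { uu <- s$u; vv <- s$v }
    dt <- if (i == 1) 0 else wp$t[i] - wp$t[i - 1]
    dis_u[i] <- (if (i == 1) 0 else dis_u[i - 1]) + uu * dt
    dis_v[i] <- (if (i == 1) 0 else dis_v[i - 1]) + vv * dt
  }
  wp$lat <- wp$lat + dis_v / 111195
  wp$lon <- wp$lon + dis_u / (111195 * cos(wp$lat * pi / 180))
  wp
}

#' Deployment table for the synthetic cohort
#' @param histories Output of [simulate_decisions()].
#' @return `data.frame` matching the deployments schema.
#' @export
make_deployments <- function(histories) {
  data.frame(tag_id = histories$bird_id, species = histories$species,
             capture_ts = histories$capture_ts,
             capture_lat = histories$capture_lat,
             capture_lon = histories$capture_lon,
             burst_interval_s = histories$burst_interval_s)
}

#' Run the full synthetic-world generator
#'
#' Weather, receivers, bird histories and detections in one call.
#'
#' @param config A [sim_config()].
#' @return List `world`, `receivers`, `histories`, `deployments`,
#'   `detections`.
#' @export
simulate_world <- function(config) {
  world <- simulate_weather(config)
  receivers <- make_receivers(config)
  histories <- simulate_decisions(world, config)
  detections <- simulate_detections(histories, receivers, world, config)
  list(world = world, receivers = receivers, histories = histories,
       deployments = make_deployments(histories), detections = detections)
}

#' Write synthetic-world outputs as plain-text files
#'
#' detections.csv, receivers.csv, deployments.csv, truth.csv, long-format
#' weather.csv, precip_stations.csv and precip.csv under `out_dir`.
#'
#' @param sim Output of [simulate_world()].
#' @param out_dir Output directory (created if needed).
#' @param weather Write the (large) long-format weather table too.
#' @return Invisibly, the vector of files written.
#' @export
write_sim_outputs <- function(sim, out_dir, weather = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  det <- data.frame(tag_id = sim$detections$tag_id,
                    timestamp = iso(sim$detections$ts),
                    receiver_id = sim$detections$receiver_id)
  files <- file.path(out_dir, c("detections.csv", "receivers.csv",
                                "deployments.csv", "truth.csv",
                                "precip_stations.csv", "precip.csv"))
  utils::write.csv(det, files[1], row.names = FALSE)
  utils::write.csv(sim$receivers, files[2], row.names = FALSE)
  dep <- sim$deployments
  dep$capture_ts <- iso(dep$capture_ts)
  utils::write.csv(dep, files[3], row.names = FALSE)
  tr <- sim$histories
  for (cc in c("capture_ts", "departure_ts", "flight_end_ts", "landing_ts",
               "tag_fail_ts"))
    tr[[cc]] <- iso(tr[[cc]])
  utils::write.csv(tr, files[4], row.names = FALSE)
  utils::write.csv(sim$world$stations, files[5], row.names = FALSE)
  pr <- data.frame(
    station_id = rep(sim$world$stations$station_id, each = length(sim$world$time)),
    hour = rep(iso(sim$world$time), nrow(sim$world$stations)),
    rain = as.vector(sim$world$rain))
  utils::write.csv(pr, files[6], row.names = FALSE)
  if (weather) {
    w <- sim$world
    grid <- expand.grid(lat = w$lat, lon = w$lon)
    long <- data.frame(
      time = rep(iso(w$time), nrow(grid)),
      lat = rep(grid$lat, each = length(w$time)),
      lon = rep(grid$lon, each = length(w$time)),
      u10 = as.vector(w$u), v10 = as.vector(w$v), t2m = as.vector(w$t2m),
      sp = as.vector(w$sp), tcc = as.vector(w$tcc))
    f <- file.path(out_dir, "weather.csv")
    utils::write.csv(long, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
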