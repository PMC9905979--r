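#' Climatological scaling of the generator covariates
#'
#' Means and standard deviations of the behavioural covariates at the
#' capture-site grid cells over the whole simulated period.  The
#' generator applies its slope coefficients on this standardized scale,
#' mirroring the centred-and-scaled covariates of the fitted models.
#' @keywords internal
generator_scaling <- function(world) {
  caps <- capture_sites()
  series <- lapply(seq_len(nrow(caps)), function(k) {
    i <- which.min(abs(world$lat - caps$lat[k]))
    j <- which.min(abs(world$lon - caps$lon[k]))
    list(u = world$u[, i, j], v = world$v[, i, j],
         sp = world$sp[, i, j], tcc = world$tcc[, i, j])
  })
  blocks <- attr(world$time, "block_len")
  lag_diff <- function(x, lag) {
    idx <- c(0, cumsum(blocks))
    unlist(lapply(seq_along(blocks), function(b) {
      xb <- x[(idx[b] + 1):idx[b + 1]]
      xb[-seq_len(lag)] - xb[seq_len(length(xb) - lag)]
    }))
  }
  pool <- function(f) unlist(lapply(series, f))
  ms <- function(x) c(mean = mean(x), sd = stats::sd(x))
  list(u = ms(pool(function(s) s$u)),
       v = ms(pool(function(s) s$v)),
       du24 = ms(pool(function(s) lag_diff(s$u, 24))),
       dv24 = ms(pool(function(s) lag_diff(s$v, 24))),
       dp24 = ms(pool(function(s) lag_diff(s$sp, 24))),
       cloud = ms(pool(function(s) s$tcc)),
       dvflight = ms(pool(function(s) lag_diff(s$v, 6))))
}

#' Route waypoints for a synthetic flight
#'
#' Minimal trajectory model: constant-airspeed travel along great-circle
#' legs.  The onshore route follows the coastline polyline from the
#' capture site to the western network edge and then exits; the offshore
#' route crosses the bight directly to a landfall point and then leaves
#' the network inland.  `end_index` marks the network-exit decision point
#' at which the landing decision is evaluated.
#'
#' @param capture_lat,capture_lon Capture site.
#' @param route `"onshore"` or `"offshore"`.
#' @return List with `lat`, `lon` waypoint vectors and `end_index`.
#' @keywords internal
route_path <- function(capture_lat, capture_lon, route) {
  if (route == "offshore") {
    # out over the bight (past the island receiver), landfall, then inland
    lat <- c(capture_lat, 54.35, 53.66, 53.20)
    lon <- c(capture_lon, 7.95, 7.30, 7.00)
    list(lat = unname(lat), lon = unname(lon), end_index = 3L)
  } else {
    poly <- coast_polyline()
    d <- haversine_km(capture_lat, capture_lon, poly$lat, poly$lon)
    start <- which.min(d)
    lat <- c(capture_lat, poly$lat[start:nrow(poly)])
    lon <- c(capture_lon, poly$lon[start:nrow(poly)])
    n <- length(lat)
    # exit leg: continue 80 km beyond the last coastal point
    b <- initial_bearing(lat[n - 1], lon[n - 1], lat[n], lon[n])
    ex <- destination_point(lat[n], lon[n], b, 80)
    list(lat = c(lat, ex$lat), lon = c(lon, ex$lon), end_index = n)
  }
}

#' Simulate bird histories from the configured decision rules
#'
#' Each bird's nightly departure is a Bernoulli draw with probability
#' `1 - exp(-integral of the hazard over the night interval)` under the
#' configured proportional-hazards generator; the route of a departing
#' bird is drawn from the routing logit given the standardized eastward
#' wind near departure (Sedge-Warbler-like birds are forced onshore); the
#' landing decision is drawn from the landing logit given end-of-flight
#' covariates.  Year-species and day-of-year random intercepts are drawn
#' per model from the configured group standard deviations.
#'
#' @param world A `weather_world` from [simulate_weather()].
#' @param config The same [sim_config()].
#' @return `data.frame` of true bird histories (one row per bird), with
#'   the climatological scaling attached as attribute `"scaling"`.
#' @export
simulate_decisions <- function(world, config) {
  stopifnot(inherits(world, "weather_world"))
  cf <- config$coefs
  need <- names(default_coefs()$departure)
  if (!all(need %in% names(cf$departure)))
    stop("configuration error: departure coefficient vector does not match ",
         "the model design (missing: ",
         paste(setdiff(need, names(cf$departure)), collapse = ", "), ")")
  if (!all(c("intercept", "u") %in% names(cf$routing)) ||
      !all(c("intercept", "dv_flight", "cloud") %in% names(cf$landing)))
    stop("configuration error: routing/landing coefficient vector mismatch")

  set.seed(config$seed + 1L)
  clim <- generator_scaling(world)
  caps <- capture_sites()
  sp_levels <- species_levels()
  years <- config$years

  ys_eff <- lapply(c("dep", "rou", "lan"), function(m) {
    e <- matrix(stats::rnorm(length(years) * 3, 0, cf$group_sd["year_species"]),
                length(years), 3,
                dimnames = list(as.character(years), sp_levels))
    e
  })
  names(ys_eff) <- c("dep", "rou", "lan")
  doys <- 180:300
  doy_eff <- lapply(c("dep", "rou", "lan"), function(m)
    stats::setNames(stats::rnorm(length(doys), 0, cf$group_sd["doy"]),
                    as.character(doys)))
  names(doy_eff) <- c("dep", "rou", "lan")

  std <- function(x, key) (x - clim[[key]]["mean"]) / clim[[key]]["sd"]
  H0 <- function(t) {
    # cumulative baseline hazard by Simpson's rule on [0, t]
    g <- seq(0, t, length.out = 2 * max(8, ceiling(4 * t)) + 1)
    h <- config$baseline_rate(g)
    w <- c(1, rep(c(4, 2), length.out = length(g) - 2), 1)
    w[length(w)] <- 1
    sum(w * h) * (g[2] - g[1]) / 3
  }
  max_n <- config$max_stopover_nights
  dH <- vapply(seq_len(max_n), function(t) H0(t) - H0(t - 1), numeric(1))

  rows <- list()
  id <- 0L
  for (sp_i in seq_along(sp_levels)) {
    sp <- sp_levels[sp_i]
    n_sp <- config$n_birds[[sp]]
    year_of <- rep(years, length.out = n_sp)
    site_of <- rep(seq_len(nrow(caps)), length.out = n_sp)
    for (b in seq_len(n_sp)) {
      id <- id + 1L
      yr <- year_of[b]
      site <- site_of[b]
      clat <- caps$lat[site]; clon <- caps$lon[site]
      cap_date <- as.Date(paste0(yr, "-", config$capture_start)) +
        sample.int(as.integer(as.Date(paste0(yr, "-", config$capture_end)) -
                                as.Date(paste0(yr, "-", config$capture_start))) + 1L,
                   1L) - 1L
      cap_ts <- as.POSIXct(cap_date, tz = "UTC") +
        3600 * stats::runif(1, 6, 10)
      cap_doy <- as.integer(format(cap_date, "%j"))
      bi <- round(stats::runif(1, config$burst_interval_range[1],
                               config$burst_interval_range[2]), 1)

      season_end <- as.Date(paste0(yr, "-", config$season_end))
      n_nights <- min(max_n, as.integer(season_end - cap_date) - 1L)

      dep_night <- NA_integer_; dep_ts <- as.POSIXct(NA, tz = "UTC")
      rain_dep <- NA_integer_
      sdays <- cap_date + seq_len(n_nights) - 1L
      shours <- sunset_utc(clat, clon, sdays)
      wsall <- sample_point_series(world, clat, clon, shours)
      for (t in seq_len(n_nights)) {
        sday <- sdays[t]
        shour <- shours[t]
        ws <- wsall[t]
        u_s <- std(ws$u, "u"); v_s <- std(ws$v, "v")
        eta <- cf$departure[["u_lin"]] * u_s + cf$departure[["u_quad"]] * u_s^2 +
          cf$departure[["v_lin"]] * v_s + cf$departure[["v_quad"]] * v_s^2 +
          cf$departure[["du24"]] * std(ws$du24, "du24") +
          cf$departure[["dv24"]] * std(ws$dv24, "dv24") +
          cf$departure[["dp24"]] * std(ws$dp24, "dp24") +
          cf$departure[["cloud"]] * std(ws$tcc, "cloud") +
          cf$departure[["rain"]] * ws$rain +
          ys_eff$dep[as.character(yr), sp] +
          doy_eff$dep[as.character(cap_doy)]
        if (sp == "whitethroat")
          eta <- eta + cf$departure[["sp_gwt"]] +
            cf$departure[["gwt_dp24"]] * std(ws$dp24, "dp24")
        if (sp == "sedge_warbler")
          eta <- eta + cf$departure[["sp_sw"]] +
            cf$departure[["sw_dp24"]] * std(ws$dp24, "dp24")
        p_dep <- 1 - exp(-dH[t] * exp(eta))
        if (stats::runif(1) < p_dep) {
          dep_night <- t
          rain_dep <- ws$rain
          # route decision with the eastward wind shortly after sunset
          uhr <- round_to_hour(shour + 2 * 3600)
          u_rou <- std(sample_grid(world, clat, clon, uhr)$u, "u")
          if (sp == "sedge_warbler") {
            route <- "onshore"
          } else {
            dep_doy <- as.integer(format(sday, "%j"))
            p_off <- stats::plogis(cf$routing[["intercept"]] +
                                     cf$routing[["u"]] * u_rou +
                                     ys_eff$rou[as.character(yr), sp] +
                                     doy_eff$rou[as.character(dep_doy)])
            route <- if (stats::runif(1) < p_off) "offshore" else "onshore"
          }
          off <- route == "offshore"
          m <- if (off) 1.4 else 1.9
          s <- if (off) 0.8 else 1.2
          offset_h <- stats::qnorm(stats::runif(1, stats::pnorm(0, m, s), 1), m, s)
          dep_ts <- shour + offset_h * 3600
          break
        }
      }

      route <- if (is.na(dep_night)) NA_character_ else route
      landed <- NA; land_ts <- as.POSIXct(NA, tz = "UTC")
      end_lat <- NA_real_; end_lon <- NA_real_; end_ts <- as.POSIXct(NA, tz = "UTC")
      if (!is.na(dep_night)) {
        path <- route_path(clat, clon, route)
        ei <- path$end_index
        leg <- haversine_km(path$lat[-length(path$lat)], path$lon[-length(path$lon)],
                            path$lat[-1], path$lon[-1])
        end_lat <- path$lat[ei]; end_lon <- path$lon[ei]
        end_ts <- dep_ts + sum(leg[seq_len(ei - 1)]) * 1000 / config$airspeed_ms
        end_hr <- round_to_hour(end_ts)
        beg_hr <- round_to_hour(dep_ts)
        ok <- !is.na(match(as.numeric(end_hr), as.numeric(world$time)))
        if (ok) {
          v_end <- sample_grid(world, end_lat, end_lon, end_hr)$v
          v_beg <- sample_grid(world, clat, clon, beg_hr)$v
          cl_end <- sample_grid(world, end_lat, end_lon, end_hr)$tcc
          end_doy <- as.integer(format(as.Date(end_ts, tz = "UTC"), "%j"))
          eta_l <- cf$landing[["intercept"]] +
            cf$landing[["dv_flight"]] * std(v_end - v_beg, "dvflight") +
            cf$landing[["cloud"]] * std(cl_end, "cloud") +
            ys_eff$lan[as.character(yr), sp] +
            doy_eff$lan[as.character(end_doy)]
          landed <- stats::runif(1) < stats::plogis(eta_l)
          if (landed) land_ts <- end_ts
        } else landed <- FALSE
      }

      fail_ts <- as.POSIXct(NA, tz = "UTC")
      if (stats::runif(1) < config$tag_fail_prob) {
        horizon <- if (!is.na(dep_night)) dep_ts else
          as.POSIXct(season_end, tz = "UTC")
        fail_ts <- cap_ts + stats::runif(1) *
          (as.numeric(horizon) - as.numeric(cap_ts))
      }

      rows[[id]] <- data.frame(
        bird_id = sprintf("T%04d", id), species = sp, year = yr,
        capture_site = caps$site[site], capture_ts = cap_ts,
        capture_lat = clat, capture_lon = clon, capture_doy = cap_doy,
        burst_interval_s = bi,
        departure_night = dep_night, departure_ts = dep_ts,
        route = route, rain_at_departure = rain_dep,
        flight_end_lat = end_lat, flight_end_lon = end_lon,
        flight_end_ts = end_ts,
        landed = landed, landing_ts = land_ts,
        landing_lat = ifelse(isTRUE(landed), end_lat, NA_real_),
        landing_lon = ifelse(isTRUE(landed), end_lon, NA_real_),
        tag_fail_ts = fail_ts,
        has_flight = !is.na(dep_night) &&
          (is.na(fail_ts) || fail_ts >= dep_ts))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scaling") <- clim
  out
}
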