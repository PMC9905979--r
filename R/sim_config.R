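#' Default generator coefficients for the three decision models
#'
#' Point estimates of the final fitted models are used as the behavioural
#' rules of the synthetic world, so that downstream model fitting has a
#' known truth to recover.  All slopes act on centred-and-scaled
#' covariates (one climatological s.d.); `rain` is binary and the species
#' contrasts are indicators against the Garden-Warbler-like reference.
#'
#' The two wind polynomial terms of the departure hazard are reported on
#' an orthonormal-basis scale in the source analysis; they are mapped to
#' the per-standardized-unit scale by dividing by the square root of the
#' analysis row count (about 1700 bird-nights), see the methods vignette.
#'
#' @return Named list with components `departure`, `routing`, `landing`,
#'   `group_sd`.
#' @export
default_coefs <- function() {
  s <- 1 / sqrt(1700)
  list(
    departure = c(
      u_lin    = -3.48 * s,
      u_quad   = -4.00 * s,
      v_lin    = -2.88 * s,
      v_quad   = -1.83 * s,
      du24     = -0.34,
      dv24     = -0.16,
      dp24     =  0.13,
      cloud    = -0.20,
      rain     = -0.74,
      sp_gwt   = -0.02,
      sp_sw    = -0.58,
      gwt_dp24 =  0.35,
      sw_dp24  =  0.05
    ),
    routing = c(intercept = -2.16, u = -1.40),
    landing = c(intercept = -2.32, dv_flight = 0.66, cloud = 0.56),
    group_sd = c(year_species = 0.25, doy = 0.25)
  )
}

#' Simulation configuration
#'
#' Builds the configuration object for the synthetic world: region,
#' seasons, receiver network, tag properties, weather-process parameters
#' and the behavioural (decision-model) coefficients.  Defaults describe a
#' German-Bight-like coastal study: three species tagged mid/late August
#' over three seasons, receivers along the coastline plus an offshore
#' island, 0.25-degree hourly weather.
#'
#' @param seed Integer; fixes every random draw of the simulation.
#' @param n_birds Named integer vector of birds per species; names must be
#'   `garden_warbler`, `whitethroat`, `sedge_warbler`.
#' @param years Integer vector of study years.
#' @param season_start,season_end Month-day strings bounding each season's
#'   weather window.
#' @param capture_start,capture_end Month-day strings bounding the tagging
#'   period (must lie inside the season).
#' @param bbox Named numeric: `lat_min`, `lat_max`, `lon_min`, `lon_max`.
#' @param grid_step Grid spacing in degrees (0.25, as in common reanalysis
#'   products).
#' @param receiver_spacing_km Spacing of coastal receivers along the
#'   coastline polyline.
#' @param detection_radius_km Detection radius; must lie in [5, 15] km.
#' @param burst_interval_range Range (s) of per-tag burst intervals; must
#'   lie within [4.5, 8].
#' @param det_prob Per-burst detection probability inside the radius.
#' @param fp_rate False positives per receiver-hour (Poisson rate).
#' @param tag_fail_prob Probability a tag fails (battery/loss/predation)
#'   before the flight is recorded, producing a bird with no flight.
#' @param airspeed_ms Constant airspeed along route waypoints.
#' @param wind_drift Logical; add wind displacement to the trajectory.
#' @param flight_step_s Trajectory sampling step during flight (s).
#' @param stopover_every_h Hours between detection runs while at stopover.
#' @param run_n_bursts Bursts per detection run.
#' @param weather Named list of weather-process parameters (see
#'   [simulate_weather()]).
#' @param coefs Generator coefficients, see [default_coefs()].
#' @param max_stopover_nights Hard cap on modelled stopover length (days);
#'   also the right boundary of the baseline-hazard support.
#' @param baseline_rate Function of night `t` (days since capture) giving
#'   the baseline departure hazard per day.  The default rises linearly in
#'   `t`, calibrated so that the covariate-free stopover distribution has
#'   median 9 nights and quartiles near 6 and 12.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_birds = c(garden_warbler = 93L, whitethroat = 95L,
                                   sedge_warbler = 87L),
                       years = 2019:2021,
                       season_start = "08-10", season_end = "09-30",
                       capture_start = "08-16", capture_end = "08-31",
                       bbox = c(lat_min = 53.25, lat_max = 55.25,
                                lon_min = 6.375, lon_max = 9.375),
                       grid_step = 0.25,
                       receiver_spacing_km = 18,
                       detection_radius_km = 10,
                       burst_interval_range = c(4.5, 8),
                       det_prob = 0.8,
                       fp_rate = 0.02,
                       tag_fail_prob = 0.35,
                       airspeed_ms = 10,
                       wind_drift = FALSE,
                       flight_step_s = 300,
                       stopover_every_h = 4,
                       run_n_bursts = 6,
                       weather = list(),
                       coefs = default_coefs(),
                       max_stopover_nights = 30,
                       baseline_rate = NULL) {
  if (grid_step <= 0) stop("configuration error: grid_step must be positive")
  if (detection_radius_km < 5 || detection_radius_km > 15)
    stop("configuration error: detection radius outside [5, 15] km")
  if (burst_interval_range[1] < 4.5 || burst_interval_range[2] > 8 ||
      diff(burst_interval_range) < 0)
    stop("configuration error: burst interval range outside [4.5, 8] s")
  if (bbox["lat_max"] <= bbox["lat_min"] || bbox["lon_max"] <= bbox["lon_min"])
    stop("configuration error: empty bounding box")
  if (length(years) < 1) stop("configuration error: empty study window")
  stopifnot(all(c("garden_warbler", "whitethroat", "sedge_warbler") %in%
                  names(n_birds)))

  wdef <- list(
    u_mean = 2, u_sd = 3, v_mean = 0.5, v_sd = 2.5,
    ar = 0.95,                      # hourly AR(1) of the synoptic latents
    grad_sd = 0.6,                  # s.d. of the spatial-gradient latents
    cell_sd = 0.15,                 # iid micro-noise per cell-hour
    t_mean = 285, t_sd = 2.5, t_diurnal = 3,
    p_mean = 101300, p_ar = 0.995, p_innov = 60, p_halfrange = 3000,
    cloud_ar = 0.97, cloud_lat_sd = 1.6, cloud_mean_logit = 0.2,
    rain_base = 0.12, rain_cloud_slope = 1.5,
    n_stations = 18
  )
  wdef[names(weather)] <- weather

  if (is.null(baseline_rate)) {
    # h0(t) = c*t with c chosen so the covariate-free median stopover is 9
    # nights (H0(9) = log 2); quartiles then fall near 6 and 12 nights.
    b1 <- 2 * log(2) / 81
    baseline_rate <- function(t) b1 * t
  }

  cfg <- list(seed = as.integer(seed), n_birds = n_birds, years = years,
              season_start = season_start, season_end = season_end,
              capture_start = capture_start, capture_end = capture_end,
              bbox = bbox, grid_step = grid_step,
              receiver_spacing_km = receiver_spacing_km,
              detection_radius_km = detection_radius_km,
              burst_interval_range = burst_interval_range,
              det_prob = det_prob, fp_rate = fp_rate,
              tag_fail_prob = tag_fail_prob,
              airspeed_ms = airspeed_ms, wind_drift = wind_drift,
              flight_step_s = flight_step_s,
              stopover_every_h = stopover_every_h,
              run_n_bursts = run_n_bursts,
              weather = wdef, coefs = coefs,
              max_stopover_nights = max_stopover_nights,
              baseline_rate = baseline_rate)
  class(cfg) <- "sim_config"
  cfg
}

#' Species labels of the synthetic world
#' @keywords internal
species_levels <- function() c("garden_warbler", "whitethroat", "sedge_warbler")

#' Receiver network of the synthetic study area
#'
#' Coastal receivers every `receiver_spacing_km` along a German-Bight-like
#' coastline polyline, an offshore island receiver (Helgoland analogue),
#' receivers at both capture sites and two inland stations.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with `receiver_id`, `lat`, `lon`, `is_coastal`,
#'   `is_helgoland_like`.
#' @export
make_receivers <- function(config) {
  coast <- coast_polyline()
  pts <- interpolate_polyline(coast, config$receiver_spacing_km)
  rec <- data.frame(lat = pts$lat, lon = pts$lon,
                    is_coastal = TRUE, is_helgoland_like = FALSE)
  extra <- data.frame(
    lat = c(54.53, 54.84, 54.182, 54.40, 53.95),
    lon = c(8.88, 8.78, 7.885, 9.15, 9.05),
    is_coastal = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    is_helgoland_like = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  rec <- rbind(rec, extra)
  rec$receiver_id <- sprintf("R%03d", seq_len(nrow(rec)))
  rec[, c("receiver_id", "lat", "lon", "is_coastal", "is_helgoland_like")]
}

#' Synthetic coastline polyline (capture area to western network edge)
#' @keywords internal
coast_polyline <- function() {
  data.frame(
    lat = c(55.10, 54.90, 54.70, 54.53, 54.35, 54.15, 53.98, 53.87,
            53.78, 53.70, 53.66, 53.60, 53.52),
    lon = c(8.45, 8.60, 8.75, 8.88, 8.78, 8.85, 8.70, 8.35,
            8.05, 7.70, 7.30, 6.90, 6.50))
}

#' Resample a polyline at (approximately) fixed arc spacing
#' @keywords internal
interpolate_polyline <- function(poly, spacing_km) {
  seg <- haversine_km(poly$lat[-nrow(poly)], poly$lon[-nrow(poly)],
                      poly$lat[-1], poly$lon[-1])
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- seq(0, total, by = spacing_km)
  lat <- stats::approx(cum, poly$lat, xout = targets)$y
  lon <- stats::approx(cum, poly$lon, xout = targets)$y
  list(lat = lat, lon = lon, total_km = total)
}
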