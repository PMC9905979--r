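# Attaching weather covariates to bird-nights (departure analysis) and to
# flight begin/end points (routing and landing analyses).

#' Centre and scale columns to one standard deviation
#'
#' @param data `data.frame`; the named columns are replaced by
#'   `(x - mean) / sd`.
#' @param cols Character vector of columns to standardize.
#' @return List `data` (transformed) and `scaling` (data.frame with
#'   `column`, `center`, `scale`) so coefficients can be mapped back to
#'   natural units.
#' @export
standardize <- function(data, cols) {
  if (length(cols) == 0)
    return(list(data = data,
                scaling = data.frame(column = character(0),
                                     center = numeric(0), scale = numeric(0))))
  sc <- data.frame(column = cols, center = NA_real_, scale = NA_real_)
  for (i in seq_along(cols)) {
    x <- data[[cols[i]]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero variance in column '", cols[i], "'")
    data[[cols[i]]] <- (x - m) / s
    sc$center[i] <- m; sc$scale[i] <- s
  }
  list(data = data, scaling = sc)
}

#' Invert [standardize()] for one column
#'
#' @param x Standardized values.
#' @param scaling The scaling record.
#' @param column Column name.
#' @return Values in natural units.
#' @export
unstandardize <- function(x, scaling, column) {
  i <- match(column, scaling$column)
  if (is.na(i)) stop("no scaling record for column '", column, "'")
  x * scaling$scale[i] + scaling$center[i]
}

#' Night index of a departure
#'
#' Number of sunsets (at the flight-begin location) between capture and
#' the flight begin, counting the sunset of the capture day as night 1.
#' @keywords internal
departure_night_index <- function(capture_ts, begin_ts, lat, lon) {
  d0 <- as.Date(capture_ts, tz = "UTC")
  n <- 0L
  repeat {
    ss <- sunset_utc(lat, lon, d0 + n, round_hour = FALSE)
    if (ss > begin_ts) break
    n <- n + 1L
    if (n > 400L) stop("runaway night index; inconsistent timestamps")
  }
  max(1L, n)
}

#' Build the bird-night departure table
#'
#' One row per bird per night from capture until (and including) the
#' departure night, with weather sampled at the flight-begin location at
#' each night's sunset hour (rounded to the full hour) and 24-h changes
#' from the same location.  Rows with missing rain (no station within
#' 20 km) or missing 24-h reference are flagged `excluded` and counted in
#' a message.
#'
#' @param stopovers Output of [stopover_records()].
#' @param first_flights Output of [classify_route()] (first flights).
#' @param deployments Deployment table (`tag_id`, `species`,
#'   `capture_ts`).
#' @param world A `weather_world`.
#' @param censored_birds Optional `data.frame` of never-departing birds
#'   (`tag_id`, last night to include) to add as right-censored rows;
#'   weather is then sampled at the capture location.  Off by default.
#' @return `data.table`, one row per bird-night.
#' @export
build_departure_table <- function(stopovers, first_flights, deployments,
                                  world, censored_birds = NULL) {
  fl <- data.table::as.data.table(first_flights)
  dep <- data.table::as.data.table(deployments)
  rows <- list()
  for (i in seq_len(nrow(fl))) {
    tag <- fl$tag_id[i]
    d <- dep[tag_id == tag]
    if (nrow(d) == 0) stop("no deployment record for tag ", tag)
    cap_ts <- d$capture_ts[1]
    blat <- fl$begin_lat[i]; blon <- fl$begin_lon[i]
    n_nights <- departure_night_index(cap_ts, fl$begin_ts[i], blat, blon)
    cap_date <- as.Date(cap_ts, tz = "UTC")
    ss <- sunset_utc(blat, blon, cap_date + seq_len(n_nights) - 1L)
    ws <- sample_point_series(world, blat, blon, ss)
    rows[[length(rows) + 1]] <- data.table::data.table(
      tag_id = tag, species = d$species[1],
      year = as.integer(format(cap_date, "%Y")),
      capture_doy = as.integer(format(cap_date, "%j")),
      night = seq_len(n_nights), sunset_ts = ss, ws,
      departed = as.integer(seq_len(n_nights) == n_nights))
  }
  if (!is.null(censored_birds)) {
    cb <- data.table::as.data.table(censored_birds)
    for (i in seq_len(nrow(cb))) {
      d <- dep[tag_id == cb$tag_id[i]]
      cap_ts <- d$capture_ts[1]
      cap_date <- as.Date(cap_ts, tz = "UTC")
      clat <- d$capture_lat[1]; clon <- d$capture_lon[1]
      for (t in seq_len(cb$last_night[i])) {
        ss <- sunset_utc(clat, clon, cap_date + (t - 1L))
        ws <- tryCatch(weather_sample(world, clat, clon, ss),
                       error = function(e) NULL)
        if (is.null(ws)) next
        rows[[length(rows) + 1]] <- data.table::data.table(
          tag_id = cb$tag_id[i], species = d$species[1],
          year = as.integer(format(cap_date, "%Y")),
          capture_doy = as.integer(format(cap_date, "%j")),
          night = t, sunset_ts = ss, ws, departed = 0L)
      }
    }
  }
  out <- data.table::rbindlist(rows)
  out[, excluded := is.na(rain) | is.na(du24) | is.na(u)]
  n_ex <- sum(out$excluded)
  if (n_ex > 0)
    message(n_ex, " bird-night rows flagged (missing weather/rain coverage)")
  out[]
}

#' Build flight-level covariates for the routing and landing models
#'
#' Weather at the flight begin (begin location, detected departure time)
#' and at the flight end (end location, end-detection time used as the
#' estimated landing time), begin-to-end changes in both wind components,
#' minimum stopover duration and the landing indicator.
#'
#' @param first_flights Output of [classify_route()].
#' @param stopovers Output of [stopover_records()].
#' @param landings Output of [detect_landing()].
#' @param deployments Deployment table.
#' @param world A `weather_world`.
#' @return `data.table`, one row per first flight.
#' @export
build_flight_covariates <- function(first_flights, stopovers, landings,
                                    deployments, world) {
  fl <- data.table::as.data.table(first_flights)
  st <- data.table::as.data.table(stopovers)
  dep <- data.table::as.data.table(deployments)
  rows <- list()
  for (i in seq_len(nrow(fl))) {
    tag <- fl$tag_id[i]
    bhr <- round_to_hour(fl$begin_ts[i])
    ehr <- round_to_hour(fl$end_ts[i])
    wb <- tryCatch(weather_sample(world, fl$begin_lat[i], fl$begin_lon[i], bhr),
                   error = function(e) NULL)
    we <- tryCatch(weather_sample(world, fl$end_lat[i], fl$end_lon[i], ehr),
                   error = function(e) NULL)
    if (is.null(wb) || is.null(we)) next
    names(wb) <- paste0(names(wb), "_begin")
    names(we) <- paste0(names(we), "_end")
    rows[[length(rows) + 1]] <- data.table::data.table(
      tag_id = tag, species = dep[tag_id == tag, species][1],
      year = as.integer(format(fl$begin_ts[i], "%Y", tz = "UTC")),
      dep_doy = as.integer(format(fl$begin_ts[i], "%j", tz = "UTC")),
      end_doy = as.integer(format(fl$end_ts[i], "%j", tz = "UTC")),
      route = fl$route[i],
      wb, we,
      du_flight = we$u_end - wb$u_begin,
      dv_flight = we$v_end - wb$v_begin,
      stopover_days = st[tag_id == tag, stopover_days][1],
      landed = as.integer(tag %in% landings$tag_id))
  }
  data.table::rbindlist(rows)
}
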