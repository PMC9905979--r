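# Rule-based conversion of raw detections into flights, routes and
# landings.  All thresholds are arguments with the published defaults.

#' Filter presumed false-positive detections
#'
#' Stand-in for the (external) Motus false-positive filtering routine: a
#' detection is retained only if it belongs to a run of at least
#' `min_run` bursts at the same receiver in which every successive gap is
#' at most `window_s` seconds and within `mult_tol` (relative) of an
#' integer multiple of the tag's burst interval.  Detections of tags
#' absent from the deployment table are dropped with a message.
#'
#' @param detections `data.frame`/`data.table` with `tag_id`, `ts`
#'   (POSIXct), `receiver_id`.
#' @param deployments Deployment table with `tag_id`, `burst_interval_s`.
#' @param min_run Minimum run length (bursts).
#' @param window_s Maximum gap between bursts of a run (s).
#' @param mult_tol Relative tolerance around integer burst-interval
#'   multiples.
#' @return Filtered `data.table`; attribute `n_dropped_unknown` counts
#'   detections of unknown tags.
#' @export
filter_false_positives <- function(detections, deployments, min_run = 3,
                                   window_s = 600, mult_tol = 0.2) {
  det <- data.table::as.data.table(detections)
  known <- det$tag_id %in% deployments$tag_id
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    message(n_unknown, " detections of unknown tags dropped")
  det <- det[known]
  bi_map <- stats::setNames(deployments$burst_interval_s, deployments$tag_id)
  det[, `:=`(.bi = bi_map[tag_id])]
  data.table::setorder(det, tag_id, receiver_id, ts)
  det[, .gap := c(NA, diff(as.numeric(ts))), by = .(tag_id, receiver_id)]
  det[, .mult := round(.gap / .bi)]
  det[, .ok := !is.na(.gap) & .gap <= window_s & .mult >= 1 &
        abs(.gap / .bi - .mult) <= mult_tol]
  det[, .run := cumsum(!.ok), by = .(tag_id, receiver_id)]
  det[, .len := .N, by = .(tag_id, receiver_id, .run)]
  out <- det[.len >= min_run]
  out[, c(".bi", ".gap", ".mult", ".ok", ".run", ".len") := NULL]
  data.table::setorder(out, tag_id, ts, receiver_id)
  data.table::setattr(out, "n_dropped_unknown", n_unknown)
  out[]
}

#' Attach receiver coordinates and flags to detections
#' @keywords internal
resolve_receivers <- function(detections, receivers) {
  det <- data.table::as.data.table(detections)
  rec <- data.table::as.data.table(receivers)
  miss <- setdiff(unique(det$receiver_id), rec$receiver_id)
  if (length(miss))
    stop("unresolvable receiver_id(s): ", paste(miss, collapse = ", "))
  out <- rec[det, on = "receiver_id"]
  data.table::setorder(out, tag_id, ts, receiver_id)
  out[]
}

#' Segment detections into sustained flights
#'
#' Candidate movement chains are maximal runs of a tag's time-ordered
#' detections in which every gap between successive detections at
#' *different* receivers is below `max_gap_h` hours and every gap at the
#' *same* receiver is below `same_receiver_break_h` hours (the latter
#' separates stationary dwell phases from movement).  A chain is a flight
#' iff its cumulative great-circle distance is at least `min_km` or it
#' involves at least `min_receivers` distinct receivers.  Flight begin
#' and end are trimmed to the last detection of the leading
#' single-receiver run and the first detection of the trailing one, i.e.
#' the detected begin and end of actual movement.
#'
#' With `gap_rule = "span"` the `max_gap_h` criterion is instead applied
#' to the whole chain span (alternative reading; not the default).
#'
#' @param detections Filtered detections (`tag_id`, `ts`, `receiver_id`).
#' @param receivers Receiver table with coordinates.
#' @param min_km Distance criterion (km).
#' @param min_receivers Receiver-count criterion.
#' @param max_gap_h Maximum gap between consecutive detections at
#'   different receivers (h).
#' @param same_receiver_break_h Same-receiver gap splitting chains (h);
#'   `Inf` disables the split.
#' @param gap_rule `"per_gap"` (default) or `"span"`.
#' @return `data.table` of flights: identifiers of the chain's first/last
#'   detection rows, trimmed begin/end location-times, `distance_km`,
#'   `n_receivers`, `n_detections`.
#' @export
segment_flights <- function(detections, receivers, min_km = 35,
                            min_receivers = 3, max_gap_h = 7,
                            same_receiver_break_h = 1,
                            gap_rule = c("per_gap", "span")) {
  gap_rule <- match.arg(gap_rule)
  det <- resolve_receivers(detections, receivers)
  if (nrow(det) == 0) return(empty_flights())
  det[, det_id := .I]
  det[, `:=`(.t = as.numeric(ts))]
  det[, `:=`(.gap = c(NA, diff(.t)),
             .same = c(NA, receiver_id[-1] == receiver_id[-.N])),
      by = tag_id]
  if (gap_rule == "per_gap") {
    det[, .brk := is.na(.gap) |
          (!.same & .gap >= max_gap_h * 3600) |
          (.same & .gap > same_receiver_break_h * 3600)]
  } else {
    det[, .brk := is.na(.gap) | (.same & .gap > same_receiver_break_h * 3600)]
  }
  det[, chain := cumsum(.brk)]

  fl <- det[, {
    leg <- haversine_km(lat[-.N], lon[-.N], lat[-1], lon[-1])
    dist <- if (.N > 1) sum(leg) else 0
    # trim leading/trailing single-receiver runs
    rr <- rle(receiver_id)
    b <- rr$lengths[1]
    e <- .N - rr$lengths[length(rr$lengths)] + 1L
    if (e < b) { b <- 1L; e <- .N }
    list(det_first = det_id[1], det_last = det_id[.N],
         n_detections = .N,
         n_receivers = data.table::uniqueN(receiver_id),
         distance_km = dist,
         span_h = (.t[.N] - .t[1]) / 3600,
         begin_ts = ts[b], begin_lat = lat[b], begin_lon = lon[b],
         begin_receiver = receiver_id[b],
         end_ts = ts[e], end_lat = lat[e], end_lon = lon[e],
         end_receiver = receiver_id[e])
  }, by = .(tag_id, chain)]

  qual <- fl$distance_km >= min_km | fl$n_receivers >= min_receivers
  if (gap_rule == "span")
    qual <- fl$distance_km >= min_km |
      (fl$n_receivers >= min_receivers & fl$span_h < max_gap_h)
  out <- fl[qual]
  out[, is_first_flight := FALSE]
  data.table::setattr(out, "detections", det)
  out[]
}

#' @keywords internal
empty_flights <- function() {
  data.table::data.table(tag_id = character(), chain = integer(),
                         det_first = integer(), det_last = integer(),
                         n_detections = integer(), n_receivers = integer(),
                         distance_km = numeric(), span_h = numeric(),
                         begin_ts = as.POSIXct(character(), tz = "UTC"),
                         begin_lat = numeric(), begin_lon = numeric(),
                         begin_receiver = character(),
                         end_ts = as.POSIXct(character(), tz = "UTC"),
                         end_lat = numeric(), end_lon = numeric(),
                         end_receiver = character(),
                         is_first_flight = logical())
}

#' Keep only each bird's first flight
#'
#' Earliest flight begin per tag (tie-break: earlier end time), marked
#' `is_first_flight`; tags without flights are simply absent.
#'
#' @param flights Output of [segment_flights()].
#' @return One row per tag with at least one flight.
#' @export
select_first_flight <- function(flights) {
  if (nrow(flights) == 0) return(flights)
  fl <- data.table::as.data.table(flights)
  data.table::setorder(fl, tag_id, begin_ts, end_ts)
  out <- fl[, .SD[1], by = tag_id]
  out[, is_first_flight := TRUE]
  det <- attr(flights, "detections")
  if (!is.null(det)) data.table::setattr(out, "detections", det)
  out[]
}

#' Classify flights as offshore or onshore
#'
#' Offshore iff the flight begins north of `lat_thr`, ends west of
#' `lon_thr` and has no coastal-flagged detections strictly between its
#' begin and end, or includes any detection at the offshore-island
#' (Helgoland-like) receiver; onshore otherwise.
#'
#' @param flights Output of [segment_flights()] /
#'   [select_first_flight()] (must carry the `"detections"` attribute, or
#'   pass `detections`).
#' @param receivers Receiver table with `is_coastal`,
#'   `is_helgoland_like`.
#' @param detections Optional resolved detection table.
#' @param lat_thr,lon_thr Classification thresholds (degrees).
#' @return The flights table with a `route` column.
#' @export
classify_route <- function(flights, receivers, detections = NULL,
                           lat_thr = 54.135, lon_thr = 8.08) {
  if (!all(c("is_coastal", "is_helgoland_like") %in% names(receivers)))
    stop("configuration error: receiver table lacks route flags")
  fl <- data.table::as.data.table(flights)
  det <- if (is.null(detections)) attr(flights, "detections") else
    resolve_receivers(detections, receivers)
  if (is.null(det)) stop("detections required for route classification")
  if (!"det_id" %in% names(det)) det[, det_id := .I]
  if (nrow(fl) == 0) { fl[, route := character(0)]; return(fl[]) }
  data.table::setkey(det, tag_id)
  route <- character(nrow(fl))
  for (i in seq_len(nrow(fl))) {
    ch <- det[.(fl$tag_id[i])][det_id >= fl$det_first[i] &
                                 det_id <= fl$det_last[i]]
    helgo <- any(ch$is_helgoland_like)
    between <- ch[ts > fl$begin_ts[i] & ts < fl$end_ts[i]]
    coastal_between <- any(between$is_coastal)
    off <- (fl$begin_lat[i] > lat_thr & fl$end_lon[i] < lon_thr &
              !coastal_between) | helgo
    route[i] <- if (off) "offshore" else "onshore"
  }
  fl[, route := route]
  data.table::setattr(fl, "detections", det)
  fl[]
}

#' Detect a landing after a flight
#'
#' A bird is deemed to have landed within the study area if its
#' detections within `window_d` days after the flight end show (i) a span
#' of more than `dwell_h` hours at one receiver, or (ii) only slow
#' movement: all successive ground speeds below `slow_ms` m/s and all
#' positions within `slow_range_km` km of the flight end.  Otherwise it
#' is assumed to have left the study area.
#'
#' @param flights Flights table (with `"detections"` attribute or pass
#'   `detections` + `receivers`).
#' @param receivers,detections See [classify_route()].
#' @param dwell_h Dwell-rule threshold (h).
#' @param slow_ms Slow-movement speed threshold (m/s).
#' @param slow_range_km Maximum displacement from flight end (km).
#' @param window_d Post-flight window (days).
#' @return `data.table` of landing events: `tag_id`, `rule`
#'   (`"dwell"`/`"slow-movement"`), `landing_ts`, `landing_lat`,
#'   `landing_lon`, `receiver_id`.
#' @export
detect_landing <- function(flights, receivers = NULL, detections = NULL,
                           dwell_h = 1, slow_ms = 5, slow_range_km = 32,
                           window_d = 3) {
  det <- if (is.null(detections)) attr(flights, "detections") else
    resolve_receivers(detections, receivers)
  if (is.null(det)) stop("detections required for landing detection")
  if (!"det_id" %in% names(det)) det[, det_id := .I]
  data.table::setkey(det, tag_id)
  fl <- data.table::as.data.table(flights)
  out <- list()
  for (i in seq_len(nrow(fl))) {
    dtag <- det[.(fl$tag_id[i])]
    # (i) dwell at the final receiver: the flight's trailing
    # single-receiver run (from the trimmed end to the chain's last
    # detection) spanning more than dwell_h hours
    tail_run <- dtag[det_id <= fl$det_last[i] & ts >= fl$end_ts[i]]
    tail_span <- if (nrow(tail_run))
      diff(range(as.numeric(tail_run$ts))) / 3600 else 0
    # subsequent detections after the chain, within the window
    post <- dtag[det_id > fl$det_last[i] &
                   ts > fl$end_ts[i] & ts <= fl$end_ts[i] + window_d * 86400]
    if (tail_span > dwell_h) {
      out[[length(out) + 1]] <- data.table::data.table(
        tag_id = fl$tag_id[i], rule = "dwell", landing_ts = fl$end_ts[i],
        landing_lat = fl$end_lat[i], landing_lon = fl$end_lon[i],
        receiver_id = fl$end_receiver[i])
      next
    }
    if (nrow(post) == 0) next
    # dwell at some post-flight receiver
    span <- post[, .(span_h = (max(as.numeric(ts)) - min(as.numeric(ts))) / 3600,
                     first_ts = min(ts), lat = lat[1], lon = lon[1]),
                 by = receiver_id]
    dw <- span[span_h > dwell_h][order(first_ts)]
    if (nrow(dw) > 0) {
      out[[length(out) + 1]] <- data.table::data.table(
        tag_id = fl$tag_id[i], rule = "dwell", landing_ts = dw$first_ts[1],
        landing_lat = dw$lat[1], landing_lon = dw$lon[1],
        receiver_id = dw$receiver_id[1])
      next
    }
    # (ii) slow movement near the flight end
    pts <- rbind(
      data.table::data.table(ts = fl$end_ts[i], lat = fl$end_lat[i],
                             lon = fl$end_lon[i]),
      post[, .(ts, lat, lon)])
    dt <- diff(as.numeric(pts$ts))
    dd <- haversine_km(pts$lat[-nrow(pts)], pts$lon[-nrow(pts)],
                       pts$lat[-1], pts$lon[-1]) * 1000
    sp <- ifelse(dt > 0, dd / dt, 0)
    rng <- haversine_km(fl$end_lat[i], fl$end_lon[i], post$lat, post$lon)
    if (all(sp < slow_ms) && all(rng < slow_range_km)) {
      out[[length(out) + 1]] <- data.table::data.table(
        tag_id = fl$tag_id[i], rule = "slow-movement",
        landing_ts = post$ts[1], landing_lat = post$lat[1],
        landing_lon = post$lon[1], receiver_id = post$receiver_id[1])
    }
  }
  if (length(out) == 0)
    return(data.table::data.table(tag_id = character(), rule = character(),
                                  landing_ts = as.POSIXct(character(), tz = "UTC"),
                                  landing_lat = numeric(), landing_lon = numeric(),
                                  receiver_id = character()))
  data.table::rbindlist(out)
}

#' Minimum stopover durations
#'
#' Time from tag deployment to the detected flight begin, reported in
#' whole days (floored), matching the day-grained departure model.
#'
#' @param first_flights Output of [select_first_flight()].
#' @param deployments Deployment table.
#' @return `data.table` with `tag_id`, `capture_ts`, `begin_ts`,
#'   `stopover_days`.
#' @export
stopover_records <- function(first_flights, deployments) {
  fl <- data.table::as.data.table(first_flights)
  dep <- data.table::as.data.table(deployments)[, .(tag_id, capture_ts)]
  out <- dep[fl[, .(tag_id, begin_ts)], on = "tag_id"]
  out[, stopover_days := floor((as.numeric(begin_ts) -
                                  as.numeric(capture_ts)) / 86400)]
  if (any(out$stopover_days < 0))
    stop("flight begins before capture; inconsistent inputs")
  out[]
}

#' Full track-processing stage
#'
#' filter -> segment -> first flight -> route class -> landings ->
#' stopovers, with the published thresholds as defaults.
#'
#' @param detections Raw detections.
#' @param receivers Receiver table.
#' @param deployments Deployment table.
#' @param ... Threshold overrides passed to the stage functions
#'   (`min_run`, `min_km`, `min_receivers`, `max_gap_h`,
#'   `same_receiver_break_h`, `lat_thr`, `lon_thr`, `dwell_h`, `slow_ms`,
#'   `slow_range_km`, `window_d`).
#' @return List `filtered`, `flights` (all), `first_flights` (with
#'   `route`), `landings`, `stopovers`.
#' @export
process_tracks <- function(detections, receivers, deployments, ...) {
  dots <- list(...)
  arg <- function(nm, def) if (!is.null(dots[[nm]])) dots[[nm]] else def
  filtered <- filter_false_positives(detections, deployments,
                                     min_run = arg("min_run", 3),
                                     window_s = arg("window_s", 600),
                                     mult_tol = arg("mult_tol", 0.2))
  flights <- segment_flights(filtered, receivers,
                             min_km = arg("min_km", 35),
                             min_receivers = arg("min_receivers", 3),
                             max_gap_h = arg("max_gap_h", 7),
                             same_receiver_break_h = arg("same_receiver_break_h", 1))
  first <- select_first_flight(flights)
  first <- classify_route(first, receivers,
                          lat_thr = arg("lat_thr", 54.135),
                          lon_thr = arg("lon_thr", 8.08))
  landings <- detect_landing(first,
                             dwell_h = arg("dwell_h", 1),
                             slow_ms = arg("slow_ms", 5),
                             slow_range_km = arg("slow_range_km", 32),
                             window_d = arg("window_d", 3))
  stopovers <- stopover_records(first, deployments)
  list(filtered = filtered, flights = flights, first_flights = first,
       landings = landings, stopovers = stopovers)
}
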