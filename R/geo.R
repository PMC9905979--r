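#' Great-circle distance between points
#'
#' Haversine distance on a sphere with the IUGG mean Earth radius
#' 6371.0088 km.  Inputs are recycled, so a vector of points against a
#' single reference works.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  r <- 6371.0088
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

#' Ground speed between two timed positions
#'
#' @param lat1,lon1 First position (decimal degrees).
#' @param t1 First timestamp (`POSIXct`).
#' @param lat2,lon2,t2 Second position and timestamp; must be after `t1`.
#' @return Speed in m/s.
#' @export
ground_speed <- function(lat1, lon1, t1, lat2, lon2, t2) {
  dt <- as.numeric(t2) - as.numeric(t1)
  if (any(dt <= 0)) stop("ground_speed undefined for non-positive elapsed time")
  haversine_km(lat1, lon1, lat2, lon2) * 1000 / dt
}

#' Destination point along a great circle
#'
#' Position reached from a start point after travelling `dist_km` along an
#' initial bearing.  Used by the trajectory simulator.
#'
#' @param lat,lon Start point, decimal degrees.
#' @param bearing_deg Initial bearing, degrees clockwise from north.
#' @param dist_km Distance in km.
#' @return List with `lat`, `lon`.
#' @keywords internal
destination_point <- function(lat, lon, bearing_deg, dist_km) {
  r <- 6371.0088
  d <- dist_km / r
  b <- bearing_deg * pi / 180
  p1 <- lat * pi / 180
  l1 <- lon * pi / 180
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(b))
  l2 <- l1 + atan2(sin(b) * sin(d) * cos(p1), cos(d) - sin(p1) * sin(p2))
  list(lat = p2 * 180 / pi, lon = ((l2 * 180 / pi + 540) %% 360) - 180)
}

#' Initial great-circle bearing from a to b
#' @keywords internal
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  (th * 180 / pi + 360) %% 360
}

#' Sunset time in UTC
#'
#' Sunset (solar centre at -0.833 deg altitude, i.e. upper limb at the
#' horizon with standard refraction) computed with the NOAA solar position
#' algorithm.  Suitable away from the polar circles.
#'
#' @param lat,lon Location in decimal degrees.
#' @param date A `Date` (the civil date, UTC).
#' @param round_hour If `TRUE` (default) round to the nearest full hour,
#'   the resolution at which hourly weather is sampled.
#' @return `POSIXct` (UTC) sunset time.
#' @export
sunset_utc <- function(lat, lon, date, round_hour = TRUE) {
  if (abs(lat) >= 66.5) stop("sunset_utc not defined near/inside polar circles")
  date <- as.Date(date)
  # NOAA spreadsheet algorithm: Julian century from J2000
  jd <- as.numeric(date) + 2440587.5  # midnight UTC of `date`
  sunset_min <- vapply(jd + 0.5, function(jday) {
    jc <- (jday - 2451545) / 36525
    gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
    gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
    eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
    seqc <- sin(gmas * pi / 180) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
      sin(2 * gmas * pi / 180) * (0.019993 - 0.000101 * jc) +
      sin(3 * gmas * pi / 180) * 0.000289
    stl <- gmls + seqc
    sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * pi / 180)
    moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
    oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * pi / 180)
    decl <- asin(sin(oc * pi / 180) * sin(sal * pi / 180)) * 180 / pi
    vary <- tan(oc / 2 * pi / 180)^2
    eqtime <- 4 * (vary * sin(2 * gmls * pi / 180) -
                     2 * eeo * sin(gmas * pi / 180) +
                     4 * eeo * vary * sin(gmas * pi / 180) * cos(2 * gmls * pi / 180) -
                     0.5 * vary^2 * sin(4 * gmls * pi / 180) -
                     1.25 * eeo^2 * sin(2 * gmas * pi / 180)) * 180 / pi
    cos_ha <- (sin(-0.833 * pi / 180) - sin(lat * pi / 180) * sin(decl * pi / 180)) /
      (cos(lat * pi / 180) * cos(decl * pi / 180))
    if (cos_ha < -1 || cos_ha > 1) stop("sun does not set/rise on this date")
    ha <- acos(cos_ha) * 180 / pi
    solar_noon_min <- 720 - 4 * lon - eqtime
    solar_noon_min + 4 * ha
  }, numeric(1))
  out <- as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + sunset_min * 60,
                    tz = "UTC", origin = "1970-01-01")
  if (round_hour) out <- round_to_hour(out)
  out
}

#' Round POSIXct to the nearest full hour (half-hours round up)
#' @keywords internal
round_to_hour <- function(t) {
  as.POSIXct(floor((as.numeric(t) + 1800) / 3600) * 3600,
             tz = "UTC", origin = "1970-01-01")
}
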