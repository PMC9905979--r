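# Independent oracles and shared fixtures.  Oracles deliberately avoid
# the package's own code paths.

# --- great-circle distance: spherical law of cosines ----------------------
slc_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  r * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

# --- sunset oracle: sunrise equation with Spencer (1971) Fourier series ---
# Declination and equation of time from a different formulation than the
# package's NOAA implementation.
sunset_oracle_utc <- function(lat, lon, date) {
  n <- as.numeric(as.Date(date) - as.Date(format(as.Date(date), "%Y-01-01")))
  g <- 2 * pi / 365 * (n + (19 - 12) / 24)  # fractional year at ~19 UTC
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  phi <- lat * pi / 180
  cos_ha <- (sin(-0.833 * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  ha <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi
  minutes <- 720 - 4 * lon - eqtime + 4 * ha
  as.POSIXct(as.Date(date), tz = "UTC") + minutes * 60
}

# NOAA solar-calculator oracle, written independently of the package
# (degree->radian helper style, explicit day-fraction iteration).
noaa_sunset_oracle <- function(lat, lon, date) {
  rad <- pi / 180
  days <- as.numeric(as.Date(date)) + 2440587.5 - 2451545
  tod <- 19 / 24  # evaluate orbital elements near the event
  jc <- (days + tod) / 36525
  L0 <- (280.46646 + 36000.76983 * jc + 0.0003032 * jc^2) %% 360
  M <- 357.52911 + 35999.05029 * jc - 0.0001537 * jc^2
  e <- 0.016708634 - 0.000042037 * jc - 0.0000001267 * jc^2
  C <- (1.914602 - 0.004817 * jc - 0.000014 * jc^2) * sin(M * rad) +
    (0.019993 - 0.000101 * jc) * sin(2 * M * rad) + 0.000289 * sin(3 * M * rad)
  lam <- L0 + C - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * rad)
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.815 * jc + 0.00059 * jc^2 - 0.001813 * jc^3) / 3600
  eps <- eps0 + 0.00256 * cos((125.04 - 1934.136 * jc) * rad)
  delta <- asin(sin(eps * rad) * sin(lam * rad))
  y <- tan(eps * rad / 2)^2
  E <- 4 / rad * (y * sin(2 * L0 * rad) - 2 * e * sin(M * rad) +
                    4 * e * y * sin(M * rad) * cos(2 * L0 * rad) -
                    0.5 * y^2 * sin(4 * L0 * rad) -
                    1.25 * e^2 * sin(2 * M * rad))
  H <- acos(pmin(1, pmax(-1, (sin(-0.833 * rad) - sin(lat * rad) * sin(delta)) /
                           (cos(lat * rad) * cos(delta))))) / rad
  mins <- 720 - 4 * lon - E + 4 * H
  as.POSIXct(as.Date(date), tz = "UTC") + mins * 60
}

# --- exhaustive flight-segmentation oracle --------------------------------
# Enumerate every contiguous sub-chain of a tag's time-ordered detections,
# keep those that are gap-valid under the chain rule, qualify them by the
# distance / receiver-count criteria, and return the maximal qualifying
# chains (as index ranges into the sorted detections).
oracle_segments <- function(det, receivers, min_km = 35, min_receivers = 3,
                            max_gap_h = 7, same_receiver_break_h = 1) {
  det <- merge(as.data.frame(det), as.data.frame(receivers),
               by = "receiver_id", sort = FALSE)
  det <- det[order(det$tag_id, det$ts, det$receiver_id), ]
  out <- list()
  for (tag in unique(det$tag_id)) {
    d <- det[det$tag_id == tag, ]
    n <- nrow(d)
    pair_ok <- function(i) {
      gap <- as.numeric(d$ts[i + 1]) - as.numeric(d$ts[i])
      if (d$receiver_id[i + 1] == d$receiver_id[i])
        gap <= same_receiver_break_h * 3600
      else gap < max_gap_h * 3600
    }
    valid <- if (n > 1) vapply(seq_len(n - 1), pair_ok, logical(1)) else logical(0)
    qualifies <- function(a, b) {
      idx <- a:b
      dist <- if (b > a)
        sum(slc_km(d$lat[idx[-length(idx)]], d$lon[idx[-length(idx)]],
                   d$lat[idx[-1]], d$lon[idx[-1]])) else 0
      dist >= min_km || length(unique(d$receiver_id[idx])) >= min_receivers
    }
    cands <- list()
    for (a in 1:n) for (b in a:n) {
      if (b > a && !all(valid[a:(b - 1)])) next
      if (qualifies(a, b)) cands[[length(cands) + 1]] <- c(a, b)
    }
    # keep maximal chains only
    for (c1 in cands) {
      maximal <- !any(vapply(cands, function(c2)
        (c2[1] <= c1[1] && c2[2] >= c1[2]) && !all(c2 == c1), logical(1)))
      if (maximal)
        out[[length(out) + 1]] <- list(tag_id = tag, a = c1[1], b = c1[2],
                                       begin = d$ts[c1[1]], end = d$ts[c1[2]])
    }
  }
  out
}

# random toy detection set (<= 12 detections, few receivers)
random_toy_detections <- function(n_rec = 4, n_det = NULL) {
  if (is.null(n_det)) n_det <- sample(2:12, 1)
  rec <- data.frame(receiver_id = sprintf("R%02d", 1:n_rec),
                    lat = runif(n_rec, 53.5, 55), lon = runif(n_rec, 7, 9),
                    is_coastal = TRUE, is_helgoland_like = FALSE)
  det <- data.frame(
    tag_id = "T1",
    ts = as.POSIXct("2020-08-20 20:00:00", tz = "UTC") +
      sort(runif(n_det, 0, 36 * 3600)),
    receiver_id = sample(rec$receiver_id, n_det, replace = TRUE))
  list(det = det, rec = rec)
}

# --- Ramsay (1988) M-spline recursion oracle ------------------------------
mspline_oracle <- function(x, knots, degree, i) {
  # knots: full padded sequence; order k = degree + 1; returns M_i(x)
  k <- degree + 1
  Mrec <- function(x, i, k) {
    ti <- knots[i]; tik <- knots[i + k]
    if (tik <= ti) return(0)
    if (k == 1) return(ifelse(x >= ti & x < tik, 1 / (tik - ti), 0))
    num <- k * ((x - ti) * Mrec(x, i, k - 1) +
                  (tik - x) * Mrec(x, i + 1, k - 1))
    num / ((k - 1) * (tik - ti))
  }
  Mrec(x, i, k)
}

# --- direct simulators from the decision models ---------------------------
# bird-nights from the proportional-hazards model with rain and cloud
# effects only (constant-slope ramp baseline, median stopover 9 nights)
sim_hazard_rc <- function(n_birds, b_rain = -0.74, b_cloud = -0.20,
                          seed = 1, max_nights = 30) {
  set.seed(seed)
  b1 <- 2 * log(2) / 81
  dH <- b1 * ((seq_len(max_nights))^2 - (seq_len(max_nights) - 1)^2) / 2
  rows <- vector("list", n_birds)
  for (k in seq_len(n_birds)) {
    cl <- rnorm(max_nights)
    rn <- rbinom(max_nights, 1, 0.15)
    eta <- b_rain * rn + b_cloud * cl
    p <- 1 - exp(-dH * exp(eta))
    dep <- which(runif(max_nights) < p)
    last <- if (length(dep)) dep[1] else max_nights
    rows[[k]] <- data.frame(
      tag_id = sprintf("T%04d", k), species = "garden_warbler",
      year = 2019L, capture_doy = 230L, night = seq_len(last),
      tcc = cl[seq_len(last)], rain = rn[seq_len(last)],
      departed = as.integer(seq_len(last) == last & length(dep) > 0))
  }
  do.call(rbind, rows)
}

# flight rows from the routing logit (standardized eastward wind)
sim_routing <- function(n, intercept = -2.16, slope = -1.40, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  y <- runif(n) < plogis(intercept + slope * u)
  data.frame(tag_id = sprintf("T%04d", seq_len(n)),
             species = rep(c("garden_warbler", "whitethroat"),
                           length.out = n),
             year = 2019L, dep_doy = sample(228:250, n, replace = TRUE),
             u_begin = u,
             route = ifelse(y, "offshore", "onshore"))
}

# --- shared synthetic run (memoized across test files) --------------------
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42,
                        n_birds = c(garden_warbler = 60, whitethroat = 60,
                                    sedge_warbler = 50),
                        years = 2019:2020)
      cache <<- list(config = cfg, sim = simulate_world(cfg))
    }
    cache
  }
})

tiny_config <- function(seed = 5, ...) {
  sim_config(seed = seed,
             n_birds = c(garden_warbler = 12, whitethroat = 12,
                         sedge_warbler = 10),
             years = 2019, ...)
}
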