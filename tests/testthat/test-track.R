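mk_rec <- function(lat, lon, coastal = TRUE, helgo = FALSE) {
  data.frame(receiver_id = sprintf("R%02d", seq_along(lat)), lat = lat,
             lon = lon, is_coastal = coastal, is_helgoland_like = helgo)
}
mk_det <- function(rec_ids, hours, tag = "T1",
                   t0 = as.POSIXct("2020-08-20 20:00:00", tz = "UTC")) {
  data.frame(tag_id = tag, ts = t0 + hours * 3600, receiver_id = rec_ids)
}

test_that("false-positive filter keeps burst-interval runs and drops strays", {
  dep <- data.frame(tag_id = "T1", burst_interval_s = 5)
  t0 <- as.POSIXct("2020-08-20 20:00:00", tz = "UTC")
  good <- data.frame(tag_id = "T1", ts = t0 + (0:4) * 5, receiver_id = "R01")
  lone <- data.frame(tag_id = "T1", ts = t0 + 4000, receiver_id = "R02")
  out <- filter_false_positives(rbind(good, lone), dep)
  expect_equal(nrow(out), 5)
  expect_true(all(out$receiver_id == "R01"))
  # gaps at integer multiples (missed bursts) are still a run
  gap2 <- data.frame(tag_id = "T1", ts = t0 + c(0, 10, 15, 25), receiver_id = "R03")
  out <- filter_false_positives(gap2, dep)
  expect_equal(nrow(out), 4)
  # unknown tags are dropped with a message
  expect_message(
    out <- filter_false_positives(rbind(good, transform(good, tag_id = "TX")),
                                  dep),
    "unknown")
  expect_equal(attr(out, "n_dropped_unknown"), 5)
})

test_that("filter removes injected noise but keeps true detections", {
  s <- shared_sim()
  det <- s$sim$detections
  out <- filter_false_positives(det, s$sim$deployments)
  noise_kept <- sum(out$is_noise)
  true_kept <- sum(!out$is_noise)
  expect_gte(1 - noise_kept / sum(det$is_noise), 0.95)
  expect_lte(1 - true_kept / sum(!det$is_noise), 0.01)
})

test_that("flight segmentation applies the distance / receiver / gap rules", {
  # two detections ~40 km apart, 2 h gap: flight by the distance rule
  rec <- mk_rec(c(54.0, 54.36), c(8.0, 8.0))
  fl <- segment_flights(mk_det(c("R01", "R02"), c(0, 2)), rec)
  expect_equal(nrow(fl), 1)
  expect_gt(fl$distance_km, 35)
  # three distinct receivers, 6-h gaps, ~20 km total: receiver rule
  rec <- mk_rec(c(54.0, 54.09, 54.18), c(8.0, 8.0, 8.0))
  fl <- segment_flights(mk_det(c("R01", "R02", "R03"), c(0, 6, 12)), rec)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$n_receivers, 3)
  expect_lt(fl$distance_km, 35)
  # same but 8-h gaps: chain breaks, no flight
  fl <- segment_flights(mk_det(c("R01", "R02", "R03"), c(0, 8, 16)), rec)
  expect_equal(nrow(fl), 0)
  # detections at one receiver over 5 days: no flight
  fl <- segment_flights(mk_det(rep("R01", 6), seq(0, 120, by = 24)),
                        mk_rec(54, 8))
  expect_equal(nrow(fl), 0)
  # span reading of the 7-h rule is available
  rec <- mk_rec(c(54.0, 54.09, 54.18), c(8.0, 8.0, 8.0))
  fl <- segment_flights(mk_det(c("R01", "R02", "R03"), c(0, 4, 8)), rec,
                        gap_rule = "span")
  expect_equal(nrow(fl), 0)  # 8-h span fails the span reading
})

test_that("segmentation equals the exhaustive sub-chain oracle on toy data", {
  set.seed(99)
  for (rep in 1:120) {
    toy <- random_toy_detections()
    fl <- segment_flights(toy$det, toy$rec)
    or <- oracle_segments(toy$det, toy$rec)
    expect_equal(nrow(fl), length(or))
    if (nrow(fl) && length(or)) {
      # compare chain extents via first/last detection timestamps
      ob <- sort(vapply(or, function(o) as.numeric(o$begin), numeric(1)))
      oe <- sort(vapply(or, function(o) as.numeric(o$end), numeric(1)))
      det_sorted <- attr(fl, "detections")
      expect_equal(sort(as.numeric(det_sorted$ts[match(fl$det_first,
                                                       det_sorted$det_id)])), ob)
      expect_equal(sort(as.numeric(det_sorted$ts[match(fl$det_last,
                                                       det_sorted$det_id)])), oe)
    }
  }
})

test_that("first-flight selection takes the earliest begin with a stable tie-break", {
  rec <- mk_rec(c(54.0, 54.5, 54.0, 54.5), c(8.0, 8.0, 9.0, 9.0))
  d1 <- mk_det(c("R01", "R02"), c(0, 2))
  d2 <- mk_det(c("R03", "R04"), c(48, 50))
  fl <- segment_flights(rbind(d1, d2), rec)
  expect_equal(nrow(fl), 2)
  first <- select_first_flight(fl)
  expect_equal(nrow(first), 1)
  expect_true(first$is_first_flight)
  expect_equal(first$begin_receiver, "R01")
})

test_that("route classification follows thresholds, coastline and island rules", {
  rec <- data.frame(
    receiver_id = c("A", "B", "C", "H"),
    lat = c(54.5, 54.0, 53.6, 54.18),
    lon = c(8.9, 8.5, 7.5, 7.89),
    is_coastal = c(TRUE, TRUE, TRUE, FALSE),
    is_helgoland_like = c(FALSE, FALSE, FALSE, TRUE))
  # offshore: begins north of 54.135, ends west of 8.08, nothing coastal between
  fl <- segment_flights(mk_det(c("A", "C"), c(0, 3)), rec)
  cr <- classify_route(fl, rec)
  expect_equal(cr$route, "offshore")
  # intermediate coastal detection forces onshore
  fl <- segment_flights(mk_det(c("A", "B", "C"), c(0, 1.5, 3)), rec)
  expect_equal(classify_route(fl, rec)$route, "onshore")
  # island detection forces offshore regardless
  fl <- segment_flights(mk_det(c("A", "H", "C"), c(0, 1.5, 3)), rec)
  expect_equal(classify_route(fl, rec)$route, "offshore")
  # begin latitude south of the threshold: onshore whatever the end
  rec2 <- transform(rec, lat = c(54.0, 53.8, 53.6, 54.18))
  fl <- segment_flights(mk_det(c("A", "C"), c(0, 3)), rec2)
  expect_equal(classify_route(fl, rec2)$route, "onshore")
  # missing flags are a configuration error
  expect_error(classify_route(fl, rec2[, 1:3]), "configuration error")
})

test_that("landing rules: dwell, slow movement, or departure from the area", {
  rec <- mk_rec(c(54.5, 54.2, 53.9, 53.88), c(8.9, 8.5, 8.1, 8.08))
  base <- mk_det(c("R01", "R02", "R03"), c(0, 1, 2))
  # 90 minutes of continued detections at the last receiver: dwell rule
  dwell <- mk_det(rep("R03", 4), c(2.3, 2.8, 3.2, 3.6))
  fl <- select_first_flight(segment_flights(rbind(base, dwell), rec))
  land <- detect_landing(fl)
  expect_equal(land$rule, "dwell")
  expect_equal(land$receiver_id, "R03")
  # slow post-flight movement nearby within the window (no single-receiver
  # dwell: one detection per receiver)
  rec5 <- rbind(rec, mk_rec(53.86, 8.06)[1, ])
  rec5$receiver_id[5] <- "R05"
  slow <- mk_det(c("R04", "R05"), c(26, 50))
  fl <- select_first_flight(segment_flights(rbind(base, slow), rec5))
  land <- detect_landing(fl)
  expect_equal(land$rule, "slow-movement")
  # no subsequent detections: bird left the study area
  fl <- select_first_flight(segment_flights(base, rec))
  expect_equal(nrow(detect_landing(fl)), 0)
  # fast onward movement is not a landing
  fast <- mk_det("R01", 26)  # ~70 km back north in < a day, but speed check:
  fl <- select_first_flight(segment_flights(rbind(base, fast), rec))
  expect_equal(nrow(detect_landing(fl)), 0)  # outside 32 km range
})

test_that("stopover duration is floored whole days from capture to flight begin", {
  rec <- mk_rec(c(54.0, 54.36), c(8.0, 8.0))
  t0 <- as.POSIXct("2020-08-20 08:00:00", tz = "UTC")
  det <- data.frame(tag_id = "T1",
                    ts = t0 + 9.4 * 86400 + c(0, 2 * 3600),
                    receiver_id = c("R01", "R02"))
  fl <- select_first_flight(segment_flights(det, rec))
  dep <- data.frame(tag_id = "T1", capture_ts = t0, burst_interval_s = 5)
  st <- stopover_records(fl, dep)
  expect_equal(st$stopover_days, 9)
})

test_that("end-to-end processing recovers flights, routes and landings", {
  s <- shared_sim()
  pr <- process_tracks(s$sim$detections, s$sim$receivers, s$sim$deployments)
  h <- s$sim$histories
  truth_flights <- sum(h$has_flight)
  expect_gte(nrow(pr$first_flights) / truth_flights, 0.90)
  m <- merge(as.data.frame(pr$first_flights)[, c("tag_id", "route")],
             h[, c("bird_id", "route")], by.x = "tag_id", by.y = "bird_id")
  expect_gte(mean(m$route.x == m$route.y), 0.95)
  # per-species onshore + offshore = per-species totals
  sp <- merge(as.data.frame(pr$first_flights), h[, c("bird_id", "species")],
              by.x = "tag_id", by.y = "bird_id")
  agg <- table(sp$species, sp$route)
  expect_true(all(rowSums(agg) == table(sp$species)[rownames(agg)]))
})

test_that("route class is invariant to detections after the flight end", {
  rec <- data.frame(
    receiver_id = c("A", "B", "C"),
    lat = c(54.5, 54.0, 53.6), lon = c(8.9, 8.5, 7.5),
    is_coastal = TRUE, is_helgoland_like = FALSE)
  flight <- mk_det(c("A", "C"), c(0, 3))
  later_coastal <- mk_det("B", 30)  # separate chain, after the flight
  fl <- select_first_flight(segment_flights(rbind(flight, later_coastal), rec))
  expect_equal(classify_route(fl, rec)$route, "offshore")
})
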