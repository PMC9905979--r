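test_that("the weather world is deterministic, gap-free and well-formed", {
  cfg <- tiny_config()
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1$u, w2$u)
  expect_identical(w1$rain, w2$rain)
  expect_true(all(w1$tcc >= 0 & w1$tcc <= 1))
  expect_equal(unique(round(diff(w1$lat), 10)), 0.25)
  expect_equal(unique(round(diff(w1$lon), 10)), 0.25)
  expect_false(anyNA(w1$u))
  expect_equal(unique(diff(as.numeric(w1$time))), 3600)
  # every capture site has a rain station within 20 km
  caps <- migradecide:::capture_sites()
  for (k in seq_len(nrow(caps)))
    expect_lt(min(haversine_km(caps$lat[k], caps$lon[k],
                               w1$stations$lat, w1$stations$lon)), 20)
})

test_that("AR coefficient zero gives temporally independent hourly fields", {
  cfg <- tiny_config(seed = 8, weather = list(ar = 0, cell_sd = 0.01))
  w <- simulate_weather(cfg)
  ac <- stats::acf(w$u[, 3, 4], plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(ac), 3 / sqrt(length(w$time)) + 0.02)
})

test_that("zero rain-cloud slope recovers the configured base rate", {
  cfg <- tiny_config(seed = 9, weather = list(rain_cloud_slope = 0,
                                              rain_base = 0.12))
  w <- simulate_weather(cfg)
  x <- as.vector(w$rain)
  n <- length(x)
  expect_gt(n, 10000)
  phat <- mean(x)
  se <- sqrt(0.12 * 0.88 / n)
  expect_lt(abs(phat - 0.12), 4 * se)
})

test_that("grid sampling is a nearest-cell exact-hour lookup", {
  cfg <- tiny_config()
  w <- simulate_weather(cfg)
  # cell centre returns that cell's value
  hr <- w$time[100]
  s <- sample_grid(w, w$lat[4], w$lon[5], hr)
  expect_identical(s$u, w$u[100, 4, 5])
  # agreement with a brute-force nearest-cell oracle at random points
  set.seed(3)
  for (i in 1:100) {
    lat <- runif(1, min(w$lat), max(w$lat))
    lon <- runif(1, min(w$lon), max(w$lon))
    ti <- sample(length(w$time), 1)
    s <- sample_grid(w, lat, lon, w$time[ti])
    io <- which.min(abs(w$lat - lat)); jo <- which.min(abs(w$lon - lon))
    expect_identical(s$tcc, w$tcc[ti, io, jo])
  }
  expect_error(sample_grid(w, 40, 8, w$time[1]), "outside weather grid")
  expect_error(sample_grid(w, 54, 8, w$time[1] + 1800), "hour outside")
})

test_that("nearest-station rain honours the 20 km limit and tie-break", {
  cfg <- tiny_config()
  w <- simulate_weather(cfg)
  # override stations with a controlled set
  w$stations <- data.frame(station_id = c("S01", "S02"),
                           lat = c(54.50, 55.10), lon = c(8.80, 6.60))
  w$rain <- cbind(rep(1L, length(w$time)), rep(0L, length(w$time)))
  hr <- w$time[10]
  expect_identical(nearest_rain(w, 54.53, 8.85, hr), 1L)  # ~5 km away
  expect_true(is.na(nearest_rain(w, 54.20, 7.60, hr)))    # > 20 km from both
  # equidistant stations: lower station_id wins
  w$stations <- data.frame(station_id = c("S01", "S02"),
                           lat = c(54.40, 54.60), lon = c(8.80, 8.80))
  w$rain <- cbind(rep(1L, length(w$time)), rep(0L, length(w$time)))
  expect_identical(nearest_rain(w, 54.50, 8.80, hr), 1L)
})

test_that("24-h deltas are same-location differences; periodic fields vanish", {
  cfg <- tiny_config()
  w <- simulate_weather(cfg)
  hr <- w$time[200]
  ws <- weather_sample(w, 54.53, 8.88, hr)
  i <- which.min(abs(w$lat - 54.53)); j <- which.min(abs(w$lon - 8.88))
  expect_equal(ws$du24, w$u[200, i, j] - w$u[200 - 24, i, j])
  # a 24-h-periodic field has identically zero delta
  w$u[] <- rep(sin(2 * pi * (seq_along(w$time) %% 24) / 24),
               length(w$lat) * length(w$lon))
  ws <- weather_sample(w, 54.53, 8.88, hr)
  expect_equal(ws$du24, 0)
})

test_that("batched point sampling equals repeated single samples", {
  cfg <- tiny_config()
  w <- simulate_weather(cfg)
  hrs <- w$time[c(30, 100, 500)]
  batch <- sample_point_series(w, 54.53, 8.88, hrs)
  for (k in seq_along(hrs)) {
    one <- weather_sample(w, 54.53, 8.88, hrs[k])
    expect_equal(batch$u[k], one$u)
    expect_equal(batch$dp24[k], one$dp24)
    expect_equal(batch$rain[k], one$rain)
  }
  # hour outside the axis flags NA instead of erroring
  batch <- sample_point_series(w, 54.53, 8.88, w$time[1] - 86400 * 300)
  expect_true(is.na(batch$u))
})
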