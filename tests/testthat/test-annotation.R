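test_that("standardize centres, scales, errors on constants and round-trips", {
  d <- data.frame(a = rnorm(50, 5, 3), b = runif(50))
  out <- standardize(d, c("a", "b"))
  expect_equal(mean(out$data$a), 0, tolerance = 1e-12)
  expect_equal(sd(out$data$b), 1, tolerance = 1e-12)
  expect_equal(unstandardize(out$data$a, out$scaling, "a"), d$a)
  expect_error(standardize(data.frame(z = rep(2, 10)), "z"),
               "zero variance in column 'z'")
  expect_error(unstandardize(1, out$scaling, "nope"), "no scaling record")
})

test_that("the departure table has one row per bird-night up to departure", {
  s <- shared_sim()
  pr <- process_tracks(s$sim$detections, s$sim$receivers, s$sim$deployments)
  tab <- build_departure_table(pr$stopovers, pr$first_flights,
                               s$sim$deployments, s$sim$world)
  # one block per bird; departed = 1 exactly on the last night
  blocks <- tab[, .(n = .N, nights = list(night), dep_sum = sum(departed),
                    dep_last = departed[.N]), by = tag_id]
  expect_true(all(vapply(blocks$nights, function(x)
    identical(as.integer(x), seq_along(x)), logical(1))))
  expect_true(all(blocks$dep_sum == 1))
  expect_true(all(blocks$dep_last == 1))
  expect_equal(nrow(tab), sum(blocks$n))
  # night index matches the generator truth for the detected birds
  h <- s$sim$histories
  m <- merge(blocks, h[, c("bird_id", "departure_night")],
             by.x = "tag_id", by.y = "bird_id")
  expect_gte(mean(m$n == m$departure_night), 0.95)
  # sunsets are rounded to the full hour
  expect_true(all(as.numeric(tab$sunset_ts) %% 3600 == 0))
  # a bird departing night 1 contributes exactly 1 row with departed = 1
  one <- m$tag_id[m$departure_night == 1]
  if (length(one)) expect_true(all(blocks$n[blocks$tag_id %in% one] == 1))
})

test_that("typical stopovers yield the documented row pattern", {
  s <- shared_sim()
  pr <- process_tracks(s$sim$detections, s$sim$receivers, s$sim$deployments)
  tab <- build_departure_table(pr$stopovers, pr$first_flights,
                               s$sim$deployments, s$sim$world)
  nine <- tab[, .N, by = tag_id][N == 9]
  expect_gt(nrow(nine), 0)  # 9-night stopovers are common in this world
  b <- tab[tag_id == nine$tag_id[1]][order(night)]
  expect_equal(b$departed, c(rep(0L, 8), 1L))
})

test_that("flight covariates carry exact begin-to-end wind changes", {
  s <- shared_sim()
  pr <- process_tracks(s$sim$detections, s$sim$receivers, s$sim$deployments)
  fc <- build_flight_covariates(pr$first_flights, pr$stopovers, pr$landings,
                                s$sim$deployments, s$sim$world)
  expect_equal(fc$dv_flight, fc$v_end - fc$v_begin)
  expect_equal(fc$du_flight, fc$u_end - fc$u_begin)
  expect_true(all(fc$landed %in% 0:1))
  expect_true(all(fc$route %in% c("onshore", "offshore")))
  expect_true(all(fc$stopover_days >= 0))
})

test_that("censored birds can be appended with capture-site weather", {
  s <- shared_sim()
  pr <- process_tracks(s$sim$detections, s$sim$receivers, s$sim$deployments)
  dep <- s$sim$deployments
  no_flight <- setdiff(dep$tag_id, pr$first_flights$tag_id)[1:3]
  cb <- data.frame(tag_id = no_flight, last_night = 5L)
  tab <- build_departure_table(pr$stopovers, pr$first_flights, dep,
                               s$sim$world, censored_birds = cb)
  cens <- tab[tag_id %in% no_flight]
  expect_equal(nrow(cens), 15)
  expect_true(all(cens$departed == 0L))
})
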