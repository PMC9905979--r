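test_that("hazard log-likelihood matches exponential closed forms", {
  # constant baseline c, no covariates, one bird departing at t = 1:
  # loglik = log(c) - c
  for (c0 in c(0.05, 0.3, 1.2)) {
    Tb <- 10
    b <- mspline_basis(degree = 0, boundary = c(0, Tb), df = 1)
    ll <- hazard_loglik(night = 1, event = 1, basis = b, weights = c0 * Tb)
    expect_equal(ll, log(c0) - c0, tolerance = 1e-9)
  }
  # doubling all hazards of a censored-only dataset doubles the
  # (negative) log-survival term exactly
  b <- mspline_basis(degree = 3, boundary = c(0, 20), df = 5)
  w <- c(0.5, 1, 2, 1, 0.5)
  ll1 <- hazard_loglik(night = c(3, 7, 12), event = c(0, 0, 0),
                       basis = b, weights = w)
  ll2 <- hazard_loglik(night = c(3, 7, 12), event = c(0, 0, 0),
                       basis = b, weights = 2 * w)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  expect_error(hazard_loglik(1, 1, basis = b, weights = c(-1, 1, 1, 1, 1)),
               "nonnegative")
})

test_that("interval cumulative hazards agree with numerical quadrature", {
  b <- mspline_basis(degree = 3, boundary = c(0, 25), df = 6,
                     interior_knots = c(6, 13))
  set.seed(6)
  w <- rexp(6)
  for (t in c(1, 4, 13, 24)) {
    want <- stats::integrate(function(x) drop(mspline_eval(b, x) %*% w),
                             t - 1, t, rel.tol = 1e-10)$value
    got <- drop((ispline_eval(b, t) - ispline_eval(b, t - 1)) %*% w)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the ML fit recovers the analytic exponential rate", {
  set.seed(7)
  lam <- 0.18
  n <- 150
  # discrete-night data from a constant hazard
  t_dep <- pmin(1 + rgeom(n, 1 - exp(-lam)), 30L)
  tab <- data.frame(tag_id = rep(sprintf("B%03d", 1:n), t_dep),
                    species = "garden_warbler", year = 2019L,
                    capture_doy = 230L,
                    night = unlist(lapply(t_dep, seq_len)),
                    departed = unlist(lapply(t_dep, function(k)
                      as.integer(seq_len(k) == k))))
  fit <- fit_departure_model(tab, covariates = character(0), df = 1,
                             degree = 0, boundary = c(0, 30),
                             random_effects = FALSE, prior_sd = Inf,
                             n_draws = 500, seed = 1)
  # fitted constant hazard = exp(b0) * (1/Tb); analytic MLE = D / sum(t)
  rate_hat <- exp(fit$map[["intercept"]]) / 30
  rate_mle <- sum(tab$departed) / sum(t_dep)
  expect_equal(rate_hat, rate_mle, tolerance = 1e-4)
})

test_that("rain and cloud effects are recovered from simulated bird-nights", {
  fits <- lapply(1:3, function(r) {
    tab <- sim_hazard_rc(250, seed = 100 + r)
    fit_departure_model(tab, covariates = c("cloud", "rain"),
                        random_effects = FALSE, n_draws = 1000, seed = r)
  })
  est <- t(vapply(fits, function(f)
    f$summary[match(c("cloud", "rain"), parameter),
              estimate], numeric(2)))
  expect_lt(mean(est[, 1]), 0)       # cloud slope negative on average
  expect_lt(mean(est[, 2]), 0)       # rain slope negative on average
  covered <- vapply(fits, function(f) {
    s <- f$summary
    s[parameter == "rain", q2.5] <= -0.74 && -0.74 <= s[parameter == "rain", q97.5]
  }, logical(1))
  expect_gte(sum(covered), 2)
})

test_that("posterior summaries are internally consistent", {
  tab <- sim_hazard_rc(150, seed = 11)
  fit <- fit_departure_model(tab, covariates = c("cloud", "rain"),
                             random_effects = FALSE, n_draws = 2000, seed = 2)
  s <- fit$summary
  expect_true(all(s$q2.5 <= s$q97.5))
  expect_true(all(s$p_gt_0 >= 0 & s$p_gt_0 <= 1))
  # P(beta > 0) is by definition the fraction of draws above zero
  expect_equal(s[parameter == "rain", p_gt_0],
               mean(fit$draws[, "rain"] > 0))
})

test_that("nightly departure predictions match a per-draw oracle", {
  tab <- sim_hazard_rc(150, seed = 12)
  fit <- fit_departure_model(tab, covariates = c("cloud", "rain"),
                             random_effects = FALSE, n_draws = 50, seed = 3)
  pr <- predict_departure_prob(fit, profile = list(rain = 0), nights = c(3, 9))
  # brute-force recomputation from the draws
  dI <- ispline_eval(fit$basis, c(3, 9)) - ispline_eval(fit$basis, c(2, 8))
  x <- migradecide:::profile_to_x(fit, list(rain = 0))
  oracle <- sapply(seq_len(nrow(fit$draws)), function(i) {
    par <- fit$draws[i, ]
    w <- migradecide:::softmax0(par[fit$idx$gamma])
    eta <- par[1] + sum(x * par[fit$idx$beta])
    1 - exp(-exp(eta) * drop(dI %*% w))
  })
  expect_equal(pr$mean, rowMeans(oracle), tolerance = 1e-12)
  # monotone in the linear predictor: rain (negative effect) lowers it
  pr_rain <- predict_departure_prob(fit, profile = list(rain = 1),
                                    nights = c(3, 9))
  if (fit$summary[parameter == "rain", estimate] < 0)
    expect_true(all(pr_rain$mean < pr$mean))
  expect_error(predict_departure_prob(fit, nights = 100), "boundary")
})

test_that("full-design fit runs on the synthetic pipeline output", {
  s <- shared_sim()
  pr <- process_tracks(s$sim$detections, s$sim$receivers, s$sim$deployments)
  tab <- build_departure_table(pr$stopovers, pr$first_flights,
                               s$sim$deployments, s$sim$world)
  fit <- fit_departure_model(tab, n_draws = 500, seed = 4)
  expect_s3_class(fit, "migra_fit")
  expect_equal(fit$summary$parameter[1:5],
               c("intercept", "u_lin", "u_quad", "v_lin", "v_quad"))
  expect_equal(nrow(fit$summary), 16)  # intercept + 13 effects + 2 group sds
})
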