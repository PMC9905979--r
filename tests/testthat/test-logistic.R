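test_that("flat-prior fit without random effects equals glm's MLE", {
  d <- sim_routing(1000, intercept = -1, slope = -1.2, seed = 20)
  fit <- fit_logistic_glmm(d, routing_spec(), random_effects = FALSE,
                           prior_sd = Inf, n_draws = 200, seed = 1)
  y <- as.integer(d$route == "offshore")
  ref <- glm(y ~ scale(d$u_begin), family = binomial())
  expect_equal(unname(fit$map[1:2]), unname(coef(ref)), tolerance = 1e-4)
})

test_that("small group variance reduces the GLMM to ordinary logistic", {
  d <- sim_routing(1000, intercept = -1, slope = -1.2, seed = 21)
  fit_re <- fit_logistic_glmm(d, routing_spec(), n_draws = 500, seed = 1)
  fit_plain <- fit_logistic_glmm(d, routing_spec(), random_effects = FALSE,
                                 n_draws = 500, seed = 1)
  a <- fit_re$summary[parameter %in% c("intercept", "u_begin"), estimate]
  b <- fit_plain$summary[parameter %in% c("intercept", "u_begin"), estimate]
  expect_equal(a, b, tolerance = 0.05)
})

test_that("intercept CI covers the logit of the observed rate (no effects)", {
  set.seed(22)
  n <- 400
  d <- data.frame(tag_id = sprintf("T%03d", 1:n), species = "garden_warbler",
                  year = 2019L, dep_doy = 230L,
                  u_begin = rnorm(n),
                  route = ifelse(runif(n) < 0.5, "offshore", "onshore"))
  fit <- fit_logistic_glmm(d, glmm_spec("route", positive = "offshore"),
                           random_effects = FALSE, n_draws = 2000, seed = 2)
  s <- fit$summary[parameter == "intercept"]
  target <- qlogis(mean(d$route == "offshore"))
  expect_true(s$q2.5 <= target && target <= s$q97.5)
})

test_that("standardization invariance: unit changes leave coefficients fixed", {
  d <- sim_routing(600, seed = 23)
  d2 <- d; d2$u_begin <- d2$u_begin * 1000  # mm/s instead of m/s
  f1 <- fit_logistic_glmm(d, routing_spec(), random_effects = FALSE,
                          n_draws = 200, seed = 3)
  f2 <- fit_logistic_glmm(d2, routing_spec(), random_effects = FALSE,
                          n_draws = 200, seed = 3)
  expect_equal(f1$summary$estimate, f2$summary$estimate, tolerance = 1e-6)
})

test_that("degenerate inputs error or warn as contracted", {
  d <- sim_routing(50, seed = 24)
  d$route <- "onshore"
  expect_error(fit_logistic_glmm(d, routing_spec()), "single class")
  # complete separation triggers a warning flag
  d <- sim_routing(80, seed = 25)
  d$route <- ifelse(d$u_begin > 0, "offshore", "onshore")
  fit <- fit_logistic_glmm(d, routing_spec(), random_effects = FALSE,
                           prior_sd = Inf, n_draws = 100, seed = 4)
  expect_true(any(grepl("separation", fit$warnings)))
})

test_that("posterior_prob_positive is an exact draw count", {
  expect_equal(posterior_prob_positive(c(1, 2, 3)), 1)
  expect_equal(posterior_prob_positive(c(-1, 1)), 0.5)
  expect_error(posterior_prob_positive(numeric(0)), "no posterior draws")
  set.seed(26)
  x <- rnorm(10000, 0.3)
  expect_equal(posterior_prob_positive(x), sum(x > 0) / 10000)
})

test_that("the routing slope is recovered from its own generative model", {
  hits <- vapply(1:3, function(r) {
    d <- sim_routing(500, seed = 30 + r)
    fit <- fit_logistic_glmm(d, routing_spec(), n_draws = 1000, seed = r)
    s <- fit$summary[parameter == "u_begin"]
    s$q2.5 <= -1.40 && -1.40 <= s$q97.5
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("the MCMC refinement agrees with the Laplace approximation", {
  d <- sim_routing(400, seed = 40)
  f1 <- fit_logistic_glmm(d, routing_spec(), random_effects = FALSE,
                          n_draws = 2000, seed = 5)
  f2 <- fit_logistic_glmm(d, routing_spec(), random_effects = FALSE,
                          method = "mcmc", n_draws = 2000, seed = 5)
  a <- f1$summary[parameter == "u_begin"]
  b <- f2$summary[parameter == "u_begin"]
  expect_lt(abs(a$estimate - b$estimate), 0.15)
  expect_true(all(f2$rhat < 1.1, na.rm = TRUE))
})
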