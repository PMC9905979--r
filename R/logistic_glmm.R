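# Bayesian logistic regressions with random intercepts: the routing
# (offshore versus onshore) and landing decisions.

#' Specification of a logistic decision model
#'
#' @param response Column holding the 0/1 response (or a factor/character
#'   whose `positive` level codes 1).
#' @param positive Value of `response` coded as 1 (e.g. `"offshore"`).
#' @param covariates Continuous covariate columns (centred and scaled
#'   before fitting).
#' @param binary Covariate columns entered as-is (0/1).
#' @param groups Random-intercept grouping columns.
#' @param exclude_species Species dropped before fitting (the routing
#'   model excludes the species with no offshore flights).
#' @return List of class `glmm_spec`.
#' @export
glmm_spec <- function(response, positive = NULL, covariates = character(0),
                      binary = character(0),
                      groups = c("year_species", "doy"),
                      exclude_species = character(0)) {
  structure(list(response = response, positive = positive,
                 covariates = covariates, binary = binary, groups = groups,
                 exclude_species = exclude_species),
            class = "glmm_spec")
}

#' Final routing-model specification (offshore probability vs eastward wind)
#' @export
routing_spec <- function() {
  glmm_spec(response = "route", positive = "offshore",
            covariates = "u_begin", exclude_species = "sedge_warbler")
}

#' Final landing-model specification (northward-wind change and cloud)
#'
#' `alternative = TRUE` swaps the flight-level northward-wind change for
#' the 24-h change at the flight end (an alternative reading of the
#' covariate definition).
#' @param alternative Use the 24-h rather than flight-level wind change.
#' @export
landing_spec <- function(alternative = FALSE) {
  glmm_spec(response = "landed",
            covariates = c(if (alternative) "dv24_end" else "dv_flight",
                           "tcc_end"))
}

#' Fit a Bayesian logistic GLMM by Laplace approximation or MCMC
#'
#' Bernoulli-logit likelihood with fixed effects and per-group random
#' intercepts; Normal(0, `prior_sd`) priors on the intercept and the
#' standardized fixed effects, half-Student-t(3, 0, 2.5) on the group
#' standard deviations.
#'
#' @param rows Flight-level covariate table (see
#'   [build_flight_covariates()]); a `year_species` group column is
#'   derived from `year` and `species`, `doy` from `dep_doy`/`end_doy`
#'   depending on the response.
#' @param spec A [glmm_spec()].
#' @param random_effects Include random intercepts.
#' @param prior_sd Fixed-effect prior s.d. (`Inf` for ML).
#' @param method `"laplace"` (default) or `"mcmc"`.
#' @param n_draws Total posterior draws.
#' @param seed Integer seed.
#' @return A `migra_fit`.
#' @export
fit_logistic_glmm <- function(rows, spec, random_effects = TRUE,
                              prior_sd = 2.5, method = c("laplace", "mcmc"),
                              n_draws = 4000, seed = 1L) {
  method <- match.arg(method)
  d <- data.table::as.data.table(rows)
  if (length(spec$exclude_species) && "species" %in% names(d))
    d <- d[!species %in% spec$exclude_species]
  y <- d[[spec$response]]
  if (!is.null(spec$positive)) y <- as.integer(y == spec$positive)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("response has a single class; cannot fit")
  if (!"year_species" %in% names(d) && all(c("year", "species") %in% names(d)))
    d[, year_species := paste(year, species, sep = ":")]
  if (!"doy" %in% names(d)) {
    doy_col <- if (identical(spec$response, "landed") && "end_doy" %in% names(d))
      "end_doy" else if ("dep_doy" %in% names(d)) "dep_doy" else NULL
    if (!is.null(doy_col)) d[, doy := get(doy_col)]
  }
  sc <- standardize(as.data.frame(d), spec$covariates)
  parts <- list()
  if (length(spec$covariates))
    parts$cont <- as.matrix(sc$data[spec$covariates])
  if (length(spec$binary))
    parts$bin <- as.matrix(as.data.frame(d)[spec$binary])
  X <- if (length(parts)) do.call(cbind, unname(parts)) else
    matrix(0, nrow(d), 0)
  colnames(X) <- c(spec$covariates, spec$binary)
  p <- ncol(X)

  re <- random_effects && all(spec$groups %in% names(d))
  if (re) {
    g1 <- factor(d[[spec$groups[1]]]); g2 <- factor(d[[spec$groups[2]]])
    n1 <- nlevels(g1); n2 <- nlevels(g2)
    i1 <- as.integer(g1); i2 <- as.integer(g2)
  } else n1 <- n2 <- 0

  par_names <- c("intercept", colnames(X),
                 if (re) c(paste0("b1_", seq_len(n1)),
                           paste0("b2_", seq_len(n2)),
                           "log_sd1", "log_sd2"))
  ib <- if (p) 1 + seq_len(p) else integer(0)
  at <- 1 + p
  if (re) {
    ig1 <- at + seq_len(n1); ig2 <- at + n1 + seq_len(n2)
    is1 <- at + n1 + n2 + 1L; is2 <- is1 + 1L
  }

  logpost <- function(par) {
    eta <- par[1] + (if (p) drop(X %*% par[ib]) else 0)
    lp <- 0
    if (re) {
      sd1 <- group_sd(par[is1]); sd2 <- group_sd(par[is2])
      eta <- eta + par[ig1][i1] + par[ig2][i2]
      lp <- lp + sum(stats::dnorm(par[ig1], 0, sd1, log = TRUE)) +
        sum(stats::dnorm(par[ig2], 0, sd2, log = TRUE)) +
        log_sd_prior(par[is1]) + log_sd_prior(par[is2])
    }
    ll <- sum(y * eta - log1p(exp(eta)))
    if (is.finite(prior_sd))
      lp <- lp + stats::dnorm(par[1], 0, prior_sd, log = TRUE) +
        (if (p) sum(stats::dnorm(par[ib], 0, prior_sd, log = TRUE)) else 0)
    val <- ll + lp
    if (!is.finite(val)) return(-1e10)
    val
  }

  grad <- function(par) {
    eta <- par[1] + (if (p) drop(X %*% par[ib]) else 0)
    if (re) eta <- eta + par[ig1][i1] + par[ig2][i2]
    r <- y - stats::plogis(eta)
    g <- numeric(length(par))
    g[1] <- sum(r)
    if (p) g[ib] <- drop(crossprod(X, r))
    if (re) {
      sd1 <- group_sd(par[is1]); sd2 <- group_sd(par[is2])
      g[ig1] <- drop(rowsum(r, i1)) - par[ig1] / sd1^2
      g[ig2] <- drop(rowsum(r, i2)) - par[ig2] / sd2^2
      g[is1] <- sum(par[ig1]^2 / sd1^2 - 1) * group_sd_dlog(par[is1]) -
        (par[is1] - log(0.3))
      g[is2] <- sum(par[ig2]^2 / sd2^2 - 1) * group_sd_dlog(par[is2]) -
        (par[is2] - log(0.3))
    }
    if (is.finite(prior_sd)) {
      g[1] <- g[1] - par[1] / prior_sd^2
      if (p) g[ib] <- g[ib] - par[ib] / prior_sd^2
    }
    g
  }

  init <- stats::setNames(numeric(length(par_names)), par_names)
  init[1] <- stats::qlogis(pmin(pmax(mean(y), 0.02), 0.98))
  if (re) { init[is1] <- log(0.3); init[is2] <- log(0.3) }

  la <- fit_map_laplace(logpost, init, n_draws = n_draws, seed = seed,
                        grad = grad)
  warnings <- character(0)
  rhat <- NULL
  if (any(abs(la$map[c(1, ib)]) > 10))
    warnings <- c(warnings, "possible complete separation: extreme estimates")
  if (method == "mcmc") {
    mc <- mcmc_sample(logpost, la$map, la$sigma,
                      n_iter = ceiling(n_draws / 4), warmup = 1000,
                      seed = seed)
    draws <- mc$draws; rhat <- mc$rhat
    if (any(rhat > 1.05, na.rm = TRUE))
      warnings <- c(warnings, "sampler non-convergence: max R-hat > 1.05")
  } else {
    draws <- la$draws
    if (!la$converged)
      warnings <- c(warnings, "MAP optimisation did not report convergence")
  }

  sm <- posterior_summary(draws, c("intercept", colnames(X)))
  if (re) {
    sds <- cbind(sd_year_species = group_sd(draws[, is1]),
                 sd_doy = group_sd(draws[, is2]))
    sm <- rbind(sm, posterior_summary(sds))
  }
  structure(list(model = paste0("logistic (", spec$response, ")"),
                 method = method, summary = sm, draws = draws,
                 map = la$map, par_names = par_names, scaling = sc$scaling,
                 spec = spec, warnings = warnings, rhat = rhat),
            class = "migra_fit")
}
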