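# The nightly departure model: proportional hazards with an M-spline
# baseline, quadratic (orthogonal-polynomial) wind effects, weather
# covariates and year-species / day-of-year random intercepts.

#' @keywords internal
softmax0 <- function(gamma) {
  e <- exp(c(0, gamma) - max(0, gamma))
  e / sum(e)
}

#' Design matrix for the departure hazard model
#'
#' Continuous covariates are centred and scaled to one s.d.; both wind
#' components enter as degree-2 orthogonal polynomials; species enters as
#' two indicator contrasts against the Garden-Warbler-like reference,
#' with species-by-pressure-change interactions.
#'
#' @param table Output of [build_departure_table()] (flagged rows are
#'   dropped).
#' @param covariates Subset of
#'   `c("u_poly","v_poly","du24","dv24","dp24","cloud","rain","species",
#'   "species_dp24")`.
#' @return List with `X`, `night`, `event`, `groups`, `scaling`,
#'   `poly_records`, `data`.
#' @export
departure_design <- function(table,
                             covariates = c("u_poly", "v_poly", "du24",
                                            "dv24", "dp24", "cloud", "rain",
                                            "species", "species_dp24")) {
  dt <- data.table::as.data.table(table)
  if ("excluded" %in% names(dt)) dt <- dt[excluded == FALSE]
  cont <- intersect(c("u", "v", "du24", "dv24", "dp24", "tcc"), names(dt))
  need <- character(0)
  if ("u_poly" %in% covariates) need <- c(need, "u")
  if ("v_poly" %in% covariates) need <- c(need, "v")
  for (nm in intersect(c("du24", "dv24", "dp24"), covariates)) need <- c(need, nm)
  if ("cloud" %in% covariates) need <- c(need, "tcc")
  if ("species_dp24" %in% covariates) need <- union(need, "dp24")
  sc <- standardize(as.data.frame(dt), unique(intersect(need, cont)))
  d <- sc$data
  X <- NULL; poly_rec <- list()
  add <- function(X, M, nms) {
    M <- as.matrix(M); colnames(M) <- nms; cbind(X, M)
  }
  if ("u_poly" %in% covariates) {
    op <- orthogonal_poly(d$u, 2)
    poly_rec$u <- op$record
    X <- add(X, op$basis, c("u_lin", "u_quad"))
  }
  if ("v_poly" %in% covariates) {
    op <- orthogonal_poly(d$v, 2)
    poly_rec$v <- op$record
    X <- add(X, op$basis, c("v_lin", "v_quad"))
  }
  for (nm in intersect(c("du24", "dv24", "dp24"), covariates))
    X <- add(X, d[[nm]], nm)
  if ("cloud" %in% covariates) X <- add(X, d$tcc, "cloud")
  if ("rain" %in% covariates) X <- add(X, as.numeric(d$rain), "rain")
  has_sp <- "species" %in% covariates && length(unique(d$species)) > 1
  if (has_sp) {
    X <- add(X, cbind(as.numeric(d$species == "whitethroat"),
                      as.numeric(d$species == "sedge_warbler")),
             c("sp_gwt", "sp_sw"))
    if ("species_dp24" %in% covariates)
      X <- add(X, cbind(as.numeric(d$species == "whitethroat") * d$dp24,
                        as.numeric(d$species == "sedge_warbler") * d$dp24),
               c("gwt_dp24", "sw_dp24"))
  }
  if (is.null(X)) X <- matrix(0, nrow(d), 0)
  groups <- list(
    ys = factor(paste(d$year, d$species, sep = ":")),
    doy = factor(d$capture_doy))
  list(X = X, night = d$night, event = d$departed, groups = groups,
       scaling = sc$scaling, poly_records = poly_rec, data = d)
}

#' Proportional-hazards log-likelihood with M-spline baseline
#'
#' Hazard `h(t) = m(t) * exp(eta)` with `m` a nonnegative-weight M-spline
#' mixture and piecewise-constant covariates per night interval
#' `[t-1, t)`.  The log-likelihood is the sum of `log h` at the event
#' times minus each row's interval cumulative hazard
#' `exp(eta) * (I(t) - I(t-1))` (right-censored rows simply have
#' `event = 0`).
#'
#' @param night Night index per row (interval end, days since capture).
#' @param event 1 on a bird's departure row, 0 otherwise.
#' @param eta Linear predictor per row (default 0).
#' @param basis An [mspline_basis()].
#' @param weights Nonnegative M-spline weights (length `basis$df`).
#' @return Scalar log-likelihood.
#' @export
hazard_loglik <- function(night, event, eta = 0, basis, weights) {
  if (any(weights < 0)) stop("baseline weights must be nonnegative")
  eta <- rep_len(eta, length(night))
  ut <- sort(unique(night))
  Mv <- drop(mspline_eval(basis, ut) %*% weights)
  dIv <- drop((ispline_eval(basis, ut) - ispline_eval(basis, ut - 1)) %*% weights)
  ix <- match(night, ut)
  sum(event * (log(Mv[ix]) + eta)) - sum(exp(eta) * dIv[ix])
}

#' Fit the Bayesian departure hazard model
#'
#' MAP estimation with a Laplace-approximation posterior by default, or
#' an adaptive-Metropolis refinement (`method = "mcmc"`).  Priors:
#' Normal(0, `prior_sd`) on the intercept and standardized fixed effects,
#' Normal(0, 1) on the baseline simplex logits, half-Student-t(3, 0, 2.5)
#' on the two group standard deviations.  `prior_sd = Inf` drops the
#' fixed-effect and simplex priors (maximum likelihood).
#'
#' @param table Output of [build_departure_table()].
#' @param covariates See [departure_design()].
#' @param df,degree Baseline M-spline dimension and degree; interior
#'   knots default to quantiles of the observed departure nights.
#' @param boundary Baseline support; defaults to `c(0, max(night))`.
#' @param random_effects Include the two random-intercept terms.
#' @param prior_sd Prior s.d. of fixed effects (`Inf` for ML).
#' @param method `"laplace"` or `"mcmc"`.
#' @param n_draws Posterior draws (total, across chains for MCMC).
#' @param seed Integer seed.
#' @return A `migra_fit` with the Table-style `summary` of the fixed
#'   effects and group s.d.s, plus full `draws`.
#' @export
fit_departure_model <- function(table,
                                covariates = c("u_poly", "v_poly", "du24",
                                               "dv24", "dp24", "cloud", "rain",
                                               "species", "species_dp24"),
                                df = 5, degree = 3, boundary = NULL,
                                random_effects = TRUE, prior_sd = 2.5,
                                method = c("laplace", "mcmc"),
                                n_draws = 4000, seed = 1L) {
  method <- match.arg(method)
  des <- departure_design(table, covariates)
  if (sum(des$event) < 1) stop("no departure events in the table")
  tmax <- max(des$night)
  if (is.null(boundary)) boundary <- c(0, tmax)
  n_int <- df - degree - 1
  knots <- NULL
  if (n_int > 0) {
    qs <- stats::quantile(des$night[des$event == 1],
                          probs = seq_len(n_int) / (n_int + 1), names = FALSE)
    qs <- pmin(pmax(qs, boundary[1] + 1e-6), boundary[2] - 1e-6)
    if (length(unique(qs)) == n_int && all(diff(qs) > 0)) knots <- qs
  }
  basis <- mspline_basis(degree = degree, boundary = boundary, df = df,
                         interior_knots = knots)

  ut <- sort(unique(des$night))
  Mmat <- mspline_eval(basis, ut)
  dImat <- ispline_eval(basis, ut) - ispline_eval(basis, ut - 1)
  ix <- match(des$night, ut)
  X <- des$X
  p <- ncol(X)
  ys <- as.integer(des$groups$ys); n_ys <- nlevels(des$groups$ys)
  doy <- as.integer(des$groups$doy); n_doy <- nlevels(des$groups$doy)
  re <- random_effects

  par_names <- c("intercept",
                 colnames(X),
                 if (df > 1) paste0("w_logit", seq_len(df - 1)),
                 if (re) c(paste0("b_ys", seq_len(n_ys)),
                           paste0("b_doy", seq_len(n_doy)),
                           "log_sd_ys", "log_sd_doy"))
  idx <- split_idx(p, df, re, n_ys, n_doy)

  event <- des$event
  Mrow <- Mmat[ix, , drop = FALSE]
  Drow <- dImat[ix, , drop = FALSE]
  logpost <- function(par) {
    b0 <- par[1]
    beta <- if (p) par[idx$beta] else numeric(0)
    w <- if (df > 1) softmax0(par[idx$gamma]) else 1
    eta <- b0 + (if (p) drop(X %*% beta) else 0)
    lp <- 0
    if (re) {
      b_ys <- par[idx$b_ys]; b_doy <- par[idx$b_doy]
      sd_ys <- group_sd(par[idx$ls_ys]); sd_doy <- group_sd(par[idx$ls_doy])
      eta <- eta + b_ys[ys] + b_doy[doy]
      lp <- lp + sum(stats::dnorm(b_ys, 0, sd_ys, log = TRUE)) +
        sum(stats::dnorm(b_doy, 0, sd_doy, log = TRUE)) +
        log_sd_prior(par[idx$ls_ys]) + log_sd_prior(par[idx$ls_doy])
    }
    mv <- drop(Mmat %*% w)[ix]
    div <- drop(dImat %*% w)[ix]
    ll <- sum(event * (log(mv) + eta)) - sum(exp(eta) * div)
    if (is.finite(prior_sd)) {
      lp <- lp + stats::dnorm(b0, 0, prior_sd, log = TRUE)
      if (p) lp <- lp + sum(stats::dnorm(beta, 0, prior_sd, log = TRUE))
      if (df > 1) lp <- lp + sum(stats::dnorm(par[idx$gamma], 0, 1, log = TRUE))
    }
    val <- ll + lp
    if (!is.finite(val)) return(-1e10)
    val
  }

  grad <- function(par) {
    b0 <- par[1]
    beta <- if (p) par[idx$beta] else numeric(0)
    w <- if (df > 1) softmax0(par[idx$gamma]) else 1
    eta <- b0 + (if (p) drop(X %*% beta) else 0)
    if (re) eta <- eta + par[idx$b_ys][ys] + par[idx$b_doy][doy]
    mv <- drop(Mrow %*% w)
    div <- drop(Drow %*% w)
    ee <- exp(eta)
    r <- event - ee * div
    g <- numeric(length(par))
    g[1] <- sum(r)
    if (p) g[idx$beta] <- drop(crossprod(X, r))
    if (df > 1) {
      gw <- drop(crossprod(Mrow, event / mv)) - drop(crossprod(Drow, ee))
      g[idx$gamma] <- w[-1] * (gw[-1] - sum(gw * w))
      if (is.finite(prior_sd)) g[idx$gamma] <- g[idx$gamma] - par[idx$gamma]
    }
    if (re) {
      b_ys <- par[idx$b_ys]; b_doy <- par[idx$b_doy]
      sd_ys <- group_sd(par[idx$ls_ys]); sd_doy <- group_sd(par[idx$ls_doy])
      g[idx$b_ys] <- drop(rowsum(r, ys)) - b_ys / sd_ys^2
      g[idx$b_doy] <- drop(rowsum(r, doy)) - b_doy / sd_doy^2
      g[idx$ls_ys] <- sum(b_ys^2 / sd_ys^2 - 1) * group_sd_dlog(par[idx$ls_ys]) -
        (par[idx$ls_ys] - log(0.3))
      g[idx$ls_doy] <- sum(b_doy^2 / sd_doy^2 - 1) * group_sd_dlog(par[idx$ls_doy]) -
        (par[idx$ls_doy] - log(0.3))
    }
    if (is.finite(prior_sd)) {
      g[1] <- g[1] - b0 / prior_sd^2
      if (p) g[idx$beta] <- g[idx$beta] - beta / prior_sd^2
    }
    g
  }

  init <- stats::setNames(numeric(length(par_names)), par_names)
  init[1] <- log(max(1e-6, sum(event)) / sum(drop(dImat %*% rep(1 / df, df))[ix]))
  if (re) { init[idx$ls_ys] <- log(0.3); init[idx$ls_doy] <- log(0.3) }

  la <- fit_map_laplace(logpost, init, n_draws = n_draws, seed = seed,
                        grad = grad)
  warnings <- character(0)
  rhat <- NULL
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

  fixed <- c("intercept", colnames(X))
  sm <- posterior_summary(draws, fixed)
  if (re) {
    sds <- cbind(sd_ys = group_sd(draws[, idx$ls_ys]),
                 sd_doy = group_sd(draws[, idx$ls_doy]))
    sm <- rbind(sm, posterior_summary(sds))
  }
  structure(list(model = "departure hazard", method = method,
                 summary = sm, draws = draws, map = la$map,
                 par_names = par_names, idx = idx, basis = basis,
                 design = des, df = df, p = p, warnings = warnings,
                 rhat = rhat),
            class = "migra_fit")
}

#' @keywords internal
split_idx <- function(p, df, re, n_ys, n_doy) {
  at <- 1L
  idx <- list()
  idx$beta <- if (p) at + seq_len(p) else integer(0)
  at <- at + p
  idx$gamma <- if (df > 1) at + seq_len(df - 1) else integer(0)
  at <- at + max(0, df - 1)
  if (re) {
    idx$b_ys <- at + seq_len(n_ys); at <- at + n_ys
    idx$b_doy <- at + seq_len(n_doy); at <- at + n_doy
    idx$ls_ys <- at + 1L; idx$ls_doy <- at + 2L
  }
  idx
}

#' Nightly departure probability for a covariate profile
#'
#' Per posterior draw, the probability of departing on night `t` is
#' `1 - exp(-exp(eta) * (I0(t) - I0(t-1)))`; unspecified numeric
#' covariates sit at their training means (0 on the standardized scale).
#'
#' @param fit A departure-model `migra_fit`.
#' @param profile Named list of covariate values in natural units (e.g.
#'   `list(u = -2, rain = 0)`).
#' @param nights Integer night indices (within the baseline boundary).
#' @return `data.table` with `night`, `mean`, `q2.5`, `q97.5`.
#' @export
predict_departure_prob <- function(fit, profile = list(), nights) {
  basis <- fit$basis
  if (any(nights < basis$boundary[1] + 1 - 1e-9 |
          nights > basis$boundary[2] + 1e-9))
    stop("night outside the baseline boundary knots")
  x <- profile_to_x(fit, profile)
  dI <- ispline_eval(basis, nights) - ispline_eval(basis, nights - 1)
  draws <- fit$draws
  p <- fit$p
  out <- matrix(NA_real_, nrow(draws), length(nights))
  for (i in seq_len(nrow(draws))) {
    par <- draws[i, ]
    w <- if (fit$df > 1) softmax0(par[fit$idx$gamma]) else 1
    eta <- par[1] + (if (p) sum(x * par[fit$idx$beta]) else 0)
    out[i, ] <- 1 - exp(-exp(eta) * drop(dI %*% w))
  }
  data.table::data.table(
    night = nights, mean = colMeans(out),
    q2.5 = apply(out, 2, stats::quantile, 0.025),
    q97.5 = apply(out, 2, stats::quantile, 0.975))
}

#' Map a natural-unit covariate profile onto the design columns
#' @keywords internal
profile_to_x <- function(fit, profile) {
  des <- fit$design
  x <- stats::setNames(numeric(fit$p), colnames(des$X))
  std1 <- function(nm, val) {
    i <- match(nm, des$scaling$column)
    (val - des$scaling$center[i]) / des$scaling$scale[i]
  }
  for (nm in names(profile)) {
    val <- profile[[nm]]
    if (nm == "u" && !is.null(des$poly_records$u)) {
      x[c("u_lin", "u_quad")] <-
        orthogonal_poly_predict(des$poly_records$u, std1("u", val))
    } else if (nm == "v" && !is.null(des$poly_records$v)) {
      x[c("v_lin", "v_quad")] <-
        orthogonal_poly_predict(des$poly_records$v, std1("v", val))
    } else if (nm == "cloud" && "cloud" %in% names(x)) {
      x["cloud"] <- std1("tcc", val)
    } else if (nm == "rain" && "rain" %in% names(x)) {
      x["rain"] <- val
    } else if (nm %in% c("du24", "dv24", "dp24") && nm %in% names(x)) {
      x[nm] <- std1(nm, val)
    } else if (nm %in% names(x)) {
      x[nm] <- val  # already on the design scale (contrasts etc.)
    } else {
      stop("unknown profile covariate '", nm, "'")
    }
  }
  x
}
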