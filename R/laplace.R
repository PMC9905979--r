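# Posterior computation: MAP + Laplace approximation by default, with an
# optional adaptive random-walk Metropolis refinement.  Both operate on a
# user-supplied log-posterior over an unconstrained parameter vector.

#' Maximise a log-posterior and draw from its Laplace approximation
#'
#' @param logpost Function of the parameter vector returning the (un-
#'   normalised) log posterior.
#' @param init Initial parameter vector (named).
#' @param n_draws Number of posterior draws.
#' @param seed Integer seed for the draws.
#' @return List `map`, `value`, `converged`, `sigma`, `draws`
#'   (`n_draws x p`).
#' @keywords internal
fit_map_laplace <- function(logpost, init, n_draws = 4000, seed = 1L,
                            grad = NULL) {
  p <- length(init)
  opt <- stats::optim(init, logpost, gr = grad, method = "BFGS",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-12))
  # polish once; BFGS can stop early on flat ridges
  opt <- stats::optim(opt$par, logpost, gr = grad, method = "BFGS",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-12))
  H <- stats::optimHess(opt$par, logpost, gr = grad)
  sigma <- neg_inv_pd(H)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  draws <- sweep(z %*% chol(sigma), 2, opt$par, `+`)
  colnames(draws) <- names(init)
  list(map = opt$par, value = opt$value, converged = opt$convergence == 0,
       sigma = sigma, draws = draws)
}

#' Invert the negative Hessian, repairing non-positive-definiteness
#' @keywords internal
neg_inv_pd <- function(H) {
  A <- -(H + t(H)) / 2
  e <- eigen(A, symmetric = TRUE)
  lam <- pmax(e$values, 1e-2)  # absolute floor: repair flat/saddle directions
  e$vectors %*% diag(1 / lam, length(lam)) %*% t(e$vectors)
}

#' Adaptive random-walk Metropolis sampler
#'
#' Four (by default) chains started by jittering `init`, proposals from a
#' scaled multivariate normal using `sigma` (typically the Laplace
#' covariance), with Robbins-Monro scale adaptation during warmup toward
#' a 0.234 acceptance rate.  Split R-hat is computed per parameter.
#'
#' @keywords internal
mcmc_sample <- function(logpost, init, sigma, n_chains = 4, n_iter = 1000,
                        warmup = 1000, seed = 1L) {
  p <- length(init)
  set.seed(seed)
  L <- chol(sigma)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    x <- init + drop(stats::rnorm(p, 0, 0.1) %*% L)
    lp <- logpost(x)
    scale <- 2.38 / sqrt(p)
    keep <- matrix(NA_real_, n_iter, p)
    for (i in seq_len(warmup + n_iter)) {
      prop <- x + scale * drop(stats::rnorm(p) %*% L)
      lp2 <- logpost(prop)
      acc <- log(stats::runif(1)) < lp2 - lp
      if (acc) { x <- prop; lp <- lp2 }
      if (i <= warmup)
        scale <- exp(log(scale) + (as.numeric(acc) - 0.234) / sqrt(i))
      else keep[i - warmup, ] <- x
    }
    chains[[ch]] <- keep
  }
  draws <- do.call(rbind, chains)
  colnames(draws) <- names(init)
  rh <- apply(array(unlist(chains), c(n_iter, p, n_chains)), 2, split_rhat)
  list(draws = draws, rhat = stats::setNames(rh, names(init)))
}

#' Split R-hat for one parameter (matrix iterations x chains)
#' @keywords internal
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior probability that a parameter is positive
#'
#' The proportion of posterior draws larger than zero.
#'
#' @param draws Numeric vector (or single-column matrix) of draws.
#' @return Probability in `[0, 1]`.
#' @export
posterior_prob_positive <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) == 0) stop("no posterior draws")
  mean(draws > 0)
}

#' Summarise posterior draws in the reporting-table format
#'
#' @param draws Matrix of draws (columns = parameters).
#' @param params Optional subset/order of parameter names.
#' @return `data.table` with `parameter`, `estimate`, `q2.5`, `q97.5`,
#'   `p_gt_0`.
#' @export
posterior_summary <- function(draws, params = colnames(draws)) {
  draws <- draws[, params, drop = FALSE]
  data.table::data.table(
    parameter = params,
    estimate = colMeans(draws),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q97.5 = apply(draws, 2, stats::quantile, 0.975),
    p_gt_0 = apply(draws, 2, posterior_prob_positive))
}

#' Log of the half-Student-t prior density (location 0)
#' @keywords internal
log_half_t <- function(x, df = 3, scale = 2.5) {
  stats::dt(x / scale, df = df, log = TRUE) - log(scale) + log(2)
}

#' Zero-avoiding prior on a log group standard deviation
#'
#' Normal on the log scale; unlike a half-t on the sd it keeps the joint
#' MAP of (effects, scale) finite, which the Laplace route requires (the
#' half-t joint mode degenerates at sd = 0).
#' @keywords internal
log_sd_prior <- function(ls, mu = log(0.3), sigma = 1) {
  stats::dnorm(ls, mu, sigma, log = TRUE)
}

#' Group scale with a small floor
#'
#' `sd = 0.01 + exp(ls)`: the floor removes the degenerate funnel at
#' sd -> 0 (the likelihood gradient in `ls` vanishes below the floor, so
#' the log-scale prior keeps the mode finite) and bounds the Hessian
#' curvature of the random-effect block, which keeps the Laplace
#' covariance well conditioned.
#' @keywords internal
group_sd <- function(ls) 0.01 + exp(ls)

#' d(log prior + likelihood scale terms)/d ls helper: e^ls / sd
#' @keywords internal
group_sd_dlog <- function(ls) exp(ls) / group_sd(ls)

#' @export
print.migra_fit <- function(x, ...) {
  cat("Bayesian", x$model, "fit (", x$method, ")\n", sep = " ")
  print(x$summary)
  if (!is.null(x$warnings) && length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
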