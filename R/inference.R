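#' Sum of squared deviations between data and model ratio curve
#'
#' The design function of both the fit and the sensitivity analysis:
#' \deqn{SSD = \sum_i (r_{obs}(t_i) - r(t_i; \theta, r_0))^2,} where r(t) is
#' the closed-form ratio trajectory.
#'
#' @param params A \code{\link{rate_params}} object.
#' @param r0 Initial ratio D/S at t = 0.
#' @param data A \code{\link{timecourse}}.
#' @return The SSD (>= 0; 0 iff the curve interpolates every observation).
#' @examples
#' sum_squared_deviations(rate_params(0.2, 0.22, 0.01, 0.001),
#'                        r0 = 0.0395, data = mcf7_timecourse())
#' @export
sum_squared_deviations <- function(params, r0, data) {
  params <- as_rate_params(params)
  stopifnot(inherits(data, "csc_timecourse"), nrow(data) >= 1L)
  pred <- ratio_eval(params$a, params$b, params$k2 - params$k1, r0,
                     data$time_days)
  sum((data$ratio - pred)^2)
}

#' Configuration of the adaptive Metropolis-Hastings fit
#'
#' @param iterations Total MCMC iterations (default 10,000).
#' @param burn_in Iterations discarded before summarizing (default 3,000).
#' @param seed Integer seed; every source of randomness in the fit flows
#'   from it.
#' @param bounds Named list of \code{c(lower, upper)} uniform prior bounds
#'   for \code{k1}, \code{k2}, \code{a}, \code{b}, the noise scale
#'   \code{sigma}, and (when estimated) \code{r0}. Defaults: growth rates on
#'   [0, 1] per day, conversion rates on [0, 0.5] per day, \code{sigma} on
#'   (0, 20] on the ratio scale, \code{r0} on [0, 1].
#' @param noise_model \code{"gaussian"}: independent Gaussian errors on the
#'   observed ratio with unknown scale \code{sigma} (matches the SSD design
#'   function); \code{"lognormal"}: Gaussian errors on log(ratio), for data
#'   spanning orders of magnitude.
#' @param r0 \code{"first_obs"} fixes the initial ratio to the first
#'   observation (the sorted-purity measurement); \code{"estimate"} samples
#'   it with the other parameters.
#' @param adapt_start Fraction of iterations run with the fixed initial
#'   proposal before covariance adaptation begins (default 0.1).
#' @param adapt_every Recompute the proposal covariance from the chain
#'   history every this many iterations during the adaptive phase.
#' @param init_scale Initial proposal standard deviation as a fraction of
#'   each prior range.
#' @param init Starting values: \code{"least_squares"} (default) starts the
#'   walker at a deterministic multi-start Nelder-Mead minimum of the SSD
#'   with the noise scale set to the residual standard deviation;
#'   \code{"midpoint"} starts at the prior midpoint; or a named numeric
#'   vector of explicit values.
#' @return A list of class \code{"csc_fit_config"}.
#' @export
fit_config <- function(iterations = 10000L, burn_in = 3000L, seed = 1L,
                       bounds = list(), noise_model = c("gaussian", "lognormal"),
                       r0 = c("first_obs", "estimate"),
                       adapt_start = 0.1, adapt_every = 50L,
                       init_scale = 0.05, init = "least_squares") {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (iterations < 1L || burn_in < 0L || burn_in >= iterations)
    stop("need 0 <= burn_in < iterations", call. = FALSE)
  default_bounds <- list(k1 = c(0, 1), k2 = c(0, 1), a = c(0, 0.5),
                         b = c(0, 0.5), sigma = c(0, 20), r0 = c(0, 1))
  for (nm in names(bounds)) {
    if (!nm %in% names(default_bounds))
      stop("unknown bound '", nm, "'", call. = FALSE)
    bb <- bounds[[nm]]
    if (length(bb) != 2L || any(!is.finite(bb)) || bb[1L] < 0 ||
        bb[2L] <= bb[1L])
      stop("bounds for '", nm, "' must be non-negative with lower < upper",
           call. = FALSE)
    default_bounds[[nm]] <- as.numeric(bb)
  }
  structure(list(iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed), bounds = default_bounds,
                 noise_model = match.arg(noise_model),
                 r0 = match.arg(r0),
                 adapt_start = adapt_start,
                 adapt_every = as.integer(adapt_every),
                 init_scale = init_scale, init = init),
            class = "csc_fit_config")
}

#' Log posterior density of the ratio-fit model
#'
#' Independent uniform priors on all parameters (so the log prior is
#' constant within bounds and \code{-Inf} outside) with a Gaussian
#' likelihood on the observed ratio,
#' \eqn{-n \log\sigma - SSD/(2\sigma^2) - (n/2)\log 2\pi}, or the same form
#' on log(ratio) under the lognormal noise model.
#'
#' @param params A \code{\link{rate_params}} object.
#' @param sigma Observation-noise scale (> 0).
#' @param data A \code{\link{timecourse}}.
#' @param config A \code{\link{fit_config}}.
#' @param r0 Initial ratio (defaults to the first observation).
#' @return The log posterior (finite within bounds, \code{-Inf} outside).
#'   With an empty (NULL) data set, just the log prior.
#' @export
log_posterior <- function(params, sigma, data, config = fit_config(),
                          r0 = NULL) {
  params <- as_rate_params(params)
  if (is.null(r0) && !is.null(data)) r0 <- data$ratio[1L]
  theta <- c(k1 = params$k1, k2 = params$k2, a = params$a, b = params$b,
             sigma = sigma)
  if (!is.null(r0) && config$r0 == "estimate") theta <- c(theta, r0 = r0)
  for (nm in names(theta)) {
    bb <- config$bounds[[nm]]
    if (theta[[nm]] < bb[1L] || theta[[nm]] > bb[2L]) return(-Inf)
  }
  if (sigma <= 0) return(-Inf)
  if (is.null(data)) return(0)  # uniform log prior, up to a constant
  n <- nrow(data)
  pred <- ratio_eval(params$a, params$b, params$k2 - params$k1, r0,
                     data$time_days)
  ss <- if (config$noise_model == "gaussian") {
    sum((data$ratio - pred)^2)
  } else {
    if (any(data$ratio <= 0) || any(pred <= 0)) return(-Inf)
    sum((log(data$ratio) - log(pred))^2)
  }
  -n * log(sigma) - ss / (2 * sigma^2) - n / 2 * log(2 * pi)
}

#' Fit the ratio model by adaptive Metropolis-Hastings MCMC
#'
#' Samples the posterior of the four rates plus the noise scale (and
#' optionally the initial ratio) under the priors and likelihood of
#' \code{\link{log_posterior}}. The sampler is a covariance-adapting
#' random-walk Metropolis: after an initial fixed-proposal phase, the
#' multivariate-normal proposal covariance is recomputed from the chain
#' history (scaled by 2.38^2/d, with a small diagonal jitter) at regular
#' intervals. Runs are bit-for-bit reproducible under a fixed seed.
#'
#' Because the ratio r(t) depends on the rates only through
#' (a, b, k2 - k1), ratio data cannot identify k1 and k2 individually; their
#' marginals track the prior along the ridge k2 - k1 = const, and summaries
#' should be read on (a, b, delta = k2 - k1). \code{\link{summarize_chain}}
#' reports both.
#'
#' @param data A \code{\link{timecourse}}; NULL samples the prior alone.
#' @param config A \code{\link{fit_config}}.
#' @return An object of class \code{"csc_chain"}: list with \code{samples}
#'   (matrix of retained draws, one column per parameter plus
#'   \code{delta}), \code{acceptance_rate}, \code{seed}, \code{config},
#'   \code{r0}, \code{data}.
#' @examples
#' \donttest{
#' fit <- run_adaptive_mh(mcf7_timecourse(), fit_config(seed = 1))
#' summarize_chain(fit)
#' }
#' @export
run_adaptive_mh <- function(data, config = fit_config()) {
  stopifnot(inherits(config, "csc_fit_config"))
  if (!is.null(data)) stopifnot(inherits(data, "csc_timecourse"))
  est_r0 <- config$r0 == "estimate"
  par_names <- c("k1", "k2", "a", "b", "sigma", if (est_r0) "r0")
  d <- length(par_names)
  lower <- vapply(config$bounds[par_names], `[`, numeric(1), 1L)
  upper <- vapply(config$bounds[par_names], `[`, numeric(1), 2L)
  r0_fixed <- if (!est_r0 && !is.null(data)) data$ratio[1L] else NA_real_

  times <- if (!is.null(data)) data$time_days else numeric(0)
  robs <- if (!is.null(data)) data$ratio else numeric(0)
  n <- length(robs)
  lognoise <- config$noise_model == "lognormal"
  logr <- if (lognoise && n) log(robs)

  logpost <- function(th) {
    if (any(th < lower) || any(th > upper) || th[5L] <= 0) return(-Inf)
    if (n == 0L) return(0)
    r0 <- if (est_r0) th[6L] else r0_fixed
    pred <- ratio_eval(th[3L], th[4L], th[2L] - th[1L], r0, times)
    sg <- th[5L]
    if (lognoise) {
      if (any(pred <= 0)) return(-Inf)
      ss <- sum((logr - log(pred))^2)
    } else ss <- sum((robs - pred)^2)
    -n * log(sg) - ss / (2 * sg^2)
  }

  theta <- mh_init(config, data, par_names, lower, upper, r0_fixed,
                   lognoise)

  set.seed(config$seed)
  iters <- config$iterations
  adapt_from <- max(10L, as.integer(config$adapt_start * iters))
  chain <- matrix(NA_real_, iters, d, dimnames = list(NULL, par_names))
  L <- diag(config$init_scale * pmax(abs(theta), 0.02 * (upper - lower)), d)
  lp <- logpost(theta)
  if (!is.finite(lp))
    stop("initial position has zero posterior density; supply 'init' ",
         "within the prior bounds", call. = FALSE)
  accepted <- 0L
  sd_scale <- 2.38^2 / d
  for (i in seq_len(iters)) {
    prop <- theta + as.numeric(L %*% stats::rnorm(d))
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      accepted <- accepted + 1L
    }
    chain[i, ] <- theta
    if (i >= adapt_from && i %% config$adapt_every == 0L) {
      cv <- sd_scale * (stats::cov(chain[seq_len(i), , drop = FALSE]) +
                          1e-10 * diag(d))
      ch <- tryCatch(chol(cv), error = function(e) NULL)
      if (!is.null(ch)) L <- t(ch)
    }
  }
  if (accepted == 0L)
    stop("no proposal was accepted over the whole run; ",
         "decrease 'init_scale' or supply better 'init'", call. = FALSE)
  retained <- chain[(config$burn_in + 1L):iters, , drop = FALSE]
  retained <- cbind(retained, delta = retained[, "k2"] - retained[, "k1"])
  structure(list(samples = retained,
                 acceptance_rate = accepted / iters,
                 seed = config$seed, config = config,
                 r0 = if (est_r0) NA_real_ else r0_fixed,
                 data = data),
            class = "csc_chain")
}

# Starting position of the walker. "least_squares": deterministic
# multi-start Nelder-Mead minimization of the (noise-model-matched) SSD in
# the identifiable coordinates (a, b, delta), with the noise scale set to
# the residual standard deviation; no randomness, so seed reproducibility
# is unaffected. "midpoint": prior midpoint (always used for prior-only
# runs). A named numeric vector is used as given.
mh_init <- function(config, data, par_names, lower, upper, r0_fixed,
                    lognoise) {
  init <- config$init
  names(lower) <- names(upper) <- par_names
  mid <- (lower + upper) / 2
  if (is.numeric(init)) {
    theta <- init[par_names]
    if (any(!is.finite(theta)))
      stop("'init' must name values for all sampled parameters: ",
           paste(par_names, collapse = ", "), call. = FALSE)
    return(as.numeric(theta))
  }
  if (identical(init, "midpoint") || is.null(data)) return(unname(mid))

  times <- data$time_days
  robs <- data$ratio
  n <- length(robs)
  est_r0 <- "r0" %in% par_names
  r0 <- if (est_r0) robs[1L] else r0_fixed
  dlo <- lower[["k2"]] - upper[["k1"]]
  dhi <- upper[["k2"]] - lower[["k1"]]
  obj <- function(p) {
    a <- p[1L]; b <- p[2L]; delta <- p[3L]
    if (a < lower[["a"]] || a > upper[["a"]] || b < lower[["b"]] ||
        b > upper[["b"]] || delta < dlo || delta > dhi) return(1e12)
    pred <- ratio_eval(a, b, delta, r0, times)
    if (lognoise) {
      if (any(pred <= 0)) return(1e12)
      sum((log(robs) - log(pred))^2)
    } else sum((robs - pred)^2)
  }
  starts <- expand.grid(a = c(0.005, 0.05), b = c(0.001, 0.02),
                        delta = c(0.02, 0.1, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  a <- min(max(best$par[1L], lower[["a"]]), upper[["a"]])
  b <- min(max(best$par[2L], lower[["b"]]), upper[["b"]])
  delta <- best$par[3L]
  k1 <- min(max(mid[["k1"]], lower[["k2"]] - delta), upper[["k2"]] - delta)
  k1 <- min(max(k1, lower[["k1"]]), upper[["k1"]])
  k2 <- min(max(k1 + delta, lower[["k2"]]), upper[["k2"]])
  sigma <- sqrt(max(best$value, 1e-12) / n)
  sigma <- min(max(sigma, 1e-6), upper[["sigma"]])
  theta <- c(k1, k2, a, b, sigma)
  if (est_r0)
    theta <- c(theta, min(max(r0, lower[["r0"]]), upper[["r0"]]))
  theta
}

#' @export
print.csc_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d retained draws (%d iterations, %d burn-in)\n",
              nrow(x$samples), x$config$iterations, x$config$burn_in))
  cat(sprintf("  acceptance rate %.3f, seed %d\n", x$acceptance_rate, x$seed))
  invisible(x)
}

# limiting ratio per posterior draw, vectorized over samples (b > 0 almost
# surely under the continuous sampler; the b = 0 limit is handled anyway)
rinf_samples <- function(samples) {
  a <- samples[, "a"]; b <- samples[, "b"]
  cc <- samples[, "delta"] - b + a
  out <- ifelse(b > 0, (cc + sqrt(cc^2 + 4 * a * b)) / (2 * b),
                ifelse(cc < 0, a / (-cc), ifelse(a > 0 | cc > 0, Inf, NaN)))
  as.numeric(out)
}

#' Summarize a posterior chain
#'
#' Posterior medians and central credible intervals for the raw rates, the
#' noise scale, and the identifiable reduction (a, b, delta = k2 - k1);
#' derived quantities (the limiting ratio r_inf and the asymptotic CSC
#' percentage 100/(1 + r_inf)) are computed per posterior draw and then
#' summarized, never from summarized parameters; and the pointwise posterior
#' median fitted curve with its credible band over a time grid.
#'
#' @param chain A \code{"csc_chain"} from \code{\link{run_adaptive_mh}}.
#' @param t_grid Time grid in days for the fitted/predicted ratio curve.
#' @param level Credible level for all intervals (default 0.95).
#' @param curve_draws Maximum number of (evenly thinned) draws used for the
#'   curve band.
#' @return A list of class \code{"csc_fit_summary"}: \code{estimates} (one
#'   row per quantity: median, lower, upper), \code{curve} (data.frame
#'   \code{time_days}, \code{ratio}, \code{lower}, \code{upper},
#'   \code{csc_percent}), \code{acceptance_rate}, \code{seed}, \code{r0},
#'   \code{level}.
#' @export
summarize_chain <- function(chain, t_grid = seq(0, 300, by = 2),
                            level = 0.95, curve_draws = 1000L) {
  stopifnot(inherits(chain, "csc_chain"), nrow(chain$samples) >= 1L)
  s <- chain$samples
  al <- (1 - level) / 2
  qs <- function(v) stats::quantile(v, c(0.5, al, 1 - al), names = FALSE,
                                    na.rm = TRUE)
  rinf <- rinf_samples(s)
  pct <- 100 / (1 + rinf)
  quantities <- cbind(s, r_inf = rinf, asymptotic_csc_percent = pct)
  est <- t(apply(quantities, 2L, qs))
  colnames(est) <- c("median", "lower", "upper")
  est <- data.frame(quantity = rownames(est), est, row.names = NULL)

  curve <- NULL
  if (length(t_grid) && !is.null(chain$data)) {
    idx <- unique(round(seq(1L, nrow(s), length.out = min(curve_draws,
                                                          nrow(s)))))
    r0s <- if (is.na(chain$r0)) s[idx, "r0"] else rep(chain$r0, length(idx))
    pred <- vapply(seq_along(idx), function(j) {
      i <- idx[j]
      ratio_eval(s[i, "a"], s[i, "b"], s[i, "delta"], r0s[j], t_grid)
    }, numeric(length(t_grid)))
    bands <- apply(pred, 1L, qs)
    curve <- data.frame(time_days = t_grid, ratio = bands[1L, ],
                        lower = bands[2L, ], upper = bands[3L, ],
                        csc_percent = 100 / (1 + bands[1L, ]))
  }
  structure(list(estimates = est, curve = curve,
                 acceptance_rate = chain$acceptance_rate,
                 seed = chain$seed, r0 = chain$r0, level = level),
            class = "csc_fit_summary")
}

#' @export
print.csc_fit_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%.0f%% credible intervals, seed %d):\n",
              100 * x$level, x$seed))
  print(x$estimates, row.names = FALSE, digits = 4)
  ri <- x$estimates[x$estimates$quantity == "r_inf", ]
  pc <- x$estimates[x$estimates$quantity == "asymptotic_csc_percent", ]
  cat(sprintf("\nLimiting ratio D/S: %.3g [%.3g, %.3g]\n",
              ri$median, ri$lower, ri$upper))
  cat(sprintf("Asymptotic CSC percentage: %.3g%% [%.3g, %.3g]\n",
              pc$median, pc$lower, pc$upper))
  invisible(x)
}
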