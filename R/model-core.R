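#' Right-hand side of the two-compartment model
#'
#' Instantaneous rates of change of the CSC population S and the
#' differentiated-cell population D under linear mass-action kinetics:
#' \deqn{dS/dt = k_1 S - a S + b D, \quad dD/dt = k_2 D + a S - b D.}
#' Each compartment grows at its intrinsic rate and exchanges cells with the
#' other at rates proportional to the donor population.
#'
#' @param params A \code{\link{rate_params}} object.
#' @param S,D Current population sizes (S > 0, D >= 0; any consistent scale).
#' @return Numeric vector \code{c(dS, dD)}.
#' @examples
#' ode_rhs(rate_params(0.2, 0.22, 0.01, 0.001), S = 100, D = 10)
#' @export
ode_rhs <- function(params, S, D) {
  params <- as_rate_params(params)
  if (!is.finite(S) || !is.finite(D) || S <= 0 || D < 0)
    stop("state must satisfy S > 0, D >= 0", call. = FALSE)
  c(dS = (params$k1 - params$a) * S + params$b * D,
    dD = params$a * S + (params$k2 - params$b) * D)
}

#' Eigenvalues of the system matrix
#'
#' The growth exponents of the coupled system: the real roots of
#' \deqn{\lambda^2 - [(k_1-a)+(k_2-b)]\lambda + [(k_1-a)(k_2-b) - ab] = 0.}
#' For non-negative rates the discriminant equals
#' \eqn{[(k_1-a)-(k_2-b)]^2 + 4ab \ge 0}, so both roots are always real; the
#' dominant root \code{lambda1} sets the long-run growth rate of the culture.
#'
#' @param params A \code{\link{rate_params}} object.
#' @return Numeric vector \code{c(lambda1, lambda2)} with
#'   \code{lambda1 >= lambda2}, in per-day units.
#' @examples
#' eigenvalues(rate_params(0.2, 0.22, 0.01, 0.001))
#' @export
eigenvalues <- function(params) {
  params <- as_rate_params(params)
  a11 <- params$k1 - params$a
  a22 <- params$k2 - params$b
  tr <- a11 + a22
  disc <- (a11 - a22)^2 + 4 * params$a * params$b
  if (disc < 0)
    stop("negative discriminant: eigenvalues not real ",
         "(cannot occur for non-negative rates)", call. = FALSE)
  s <- sqrt(disc)
  c(lambda1 = (tr + s) / 2, lambda2 = (tr - s) / 2)
}

#' Closed-form solution of the two-compartment model
#'
#' Solves the linear system exactly. For distinct eigenvalues each
#' compartment is a two-exponential mixture
#' \eqn{c_1 e^{\lambda_1 t} + c_2 e^{\lambda_2 t}} with coefficients fixed by
#' the initial state through the spectral decomposition of the system matrix;
#' the degenerate case \eqn{\lambda_1 = \lambda_2} returns the confluent
#' solution \eqn{(c_1 + c_2 t) e^{\lambda t}}.
#'
#' @param params A \code{\link{rate_params}} object.
#' @param S0 Initial CSC population (> 0).
#' @param D0 Initial differentiated-cell population (>= 0).
#' @return An object of class \code{"csc_closed_form"} with fields
#'   \code{lambda1}, \code{lambda2}, the mixture coefficients for S and D,
#'   \code{S0}, \code{D0}, and \code{degenerate}. Evaluate it with
#'   \code{\link{eval_closed_form}}.
#' @examples
#' cf <- closed_form(rate_params(0.2, 0.22, 0.01, 0.001), S0 = 96.2, D0 = 3.8)
#' eval_closed_form(cf, t = c(0, 50, 100))
#' @export
closed_form <- function(params, S0, D0) {
  params <- as_rate_params(params)
  if (!is.finite(S0) || S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  if (!is.finite(D0) || D0 < 0) stop("D0 must be >= 0", call. = FALSE)
  lam <- eigenvalues(params)
  l1 <- lam[[1L]]; l2 <- lam[[2L]]
  a11 <- params$k1 - params$a
  a22 <- params$k2 - params$b
  degenerate <- (l1 - l2) < 1e-12 * max(1, abs(l1))
  if (!degenerate) {
    dl <- l1 - l2
    # e^{At} = e^{l1 t}(A - l2 I)/(l1 - l2) + e^{l2 t}(A - l1 I)/(l2 - l1)
    cS <- c((a11 - l2) * S0 + params$b * D0,
            -((a11 - l1) * S0 + params$b * D0)) / dl
    cD <- c(params$a * S0 + (a22 - l2) * D0,
            -(params$a * S0 + (a22 - l1) * D0)) / dl
  } else {
    # e^{At} = e^{lt}(I + (A - lI) t): coefficients of (1, t) e^{lt}
    l <- (l1 + l2) / 2
    cS <- c(S0, (a11 - l) * S0 + params$b * D0)
    cD <- c(D0, params$a * S0 + (a22 - l) * D0)
  }
  structure(list(lambda1 = l1, lambda2 = l2, cS = cS, cD = cD,
                 S0 = S0, D0 = D0, degenerate = degenerate,
                 params = params),
            class = "csc_closed_form")
}

#' Evaluate a closed-form solution
#'
#' @param cf A \code{"csc_closed_form"} object from \code{\link{closed_form}}.
#' @param t Vector of times in days (>= 0).
#' @return A data.frame with columns \code{t}, \code{S}, \code{D}.
#' @export
eval_closed_form <- function(cf, t) {
  stopifnot(inherits(cf, "csc_closed_form"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (!cf$degenerate) {
    e1 <- exp(cf$lambda1 * t); e2 <- exp(cf$lambda2 * t)
    S <- cf$cS[1L] * e1 + cf$cS[2L] * e2
    D <- cf$cD[1L] * e1 + cf$cD[2L] * e2
  } else {
    e <- exp((cf$lambda1 + cf$lambda2) / 2 * t)
    S <- (cf$cS[1L] + cf$cS[2L] * t) * e
    D <- (cf$cD[1L] + cf$cD[2L] * t) * e
  }
  data.frame(t = t, S = S, D = D)
}

#' @export
print.csc_closed_form <- function(x, ...) {
  cat("Closed-form solution of the two-compartment model\n")
  cat(sprintf("  eigenvalues: lambda1 = %.6g, lambda2 = %.6g (per day)%s\n",
              x$lambda1, x$lambda2,
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  initial state: S0 = %g, D0 = %g\n", x$S0, x$D0))
  invisible(x)
}

#' Ratio trajectory r(t) = D(t)/S(t)
#'
#' The ratio of differentiated cancer cells to CSCs obeys the Riccati
#' equation \deqn{dr/dt = a + (k_2 - b - k_1 + a) r - b r^2,} so it depends
#' on the four rates only through \eqn{(a, b, k_2 - k_1)}: adding the same
#' constant to both growth rates leaves r(t) unchanged, which is why ratio
#' data alone cannot identify \code{k1} and \code{k2} separately. The
#' returned evaluator uses the closed form with the fast exponential factored
#' out, so it is stable at large t (no overflow of
#' \eqn{e^{\lambda_1 t}}).
#'
#' @param params A \code{\link{rate_params}} object (or a list with elements
#'   \code{a}, \code{b} and either \code{k1}, \code{k2} or \code{delta}).
#' @param r0 Initial ratio D0/S0 (>= 0).
#' @return An object of class \code{"csc_ratio"}: call it as a function of a
#'   time vector, or access fields \code{r0}, \code{a}, \code{b},
#'   \code{delta}, \code{r_inf}.
#' @examples
#' r <- ratio_trajectory(rate_params(0.2, 0.22, 0.01, 0.001), r0 = 0.0395)
#' r(c(0, 100, 300))
#' r$r_inf
#' @export
ratio_trajectory <- function(params, r0) {
  params <- as_rate_params(params)
  if (!is.finite(r0) || r0 < 0) stop("r0 must be >= 0", call. = FALSE)
  a <- params$a; b <- params$b
  delta <- params$k2 - params$k1
  f <- function(t) {
    t <- as.numeric(t)
    if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
    ratio_eval(a, b, delta, r0, t)
  }
  structure(f, r0 = r0, a = a, b = b, delta = delta,
            r_inf = limiting_ratio(params), class = "csc_ratio")
}

# Overflow-safe evaluation of r(t) in the identifiable parameterization
# (a, b, delta = k2 - k1): the shifted system with k1 = 0, k2 = delta has the
# same ratio, and the fast exponential e^{lambda1 t} is factored out of D/S.
# Vectorized over t; internal workhorse for SSD and MCMC.
ratio_eval <- function(a, b, delta, r0, t) {
  a11 <- -a
  a22 <- delta - b
  tr <- a11 + a22
  disc <- sqrt((a11 - a22)^2 + 4 * a * b)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (disc >= 1e-12 * max(1, abs(l1))) {
    # with S0 = 1, D0 = r0, common factor e^{l1 t}/(l1 - l2) cancelled:
    e <- exp(-(l1 - l2) * t)
    (a + (a22 - l2) * r0 - (a + (a22 - l1) * r0) * e) /
      ((a11 - l2) + b * r0 - ((a11 - l1) + b * r0) * e)
  } else {
    # confluent eigenvalues: r(t) = (r0 + cD2 t) / (1 + cS2 t)
    l <- tr / 2
    (r0 + (a + (a22 - l) * r0) * t) / (1 + ((a11 - l) + b * r0) * t)
  }
}

#' @export
`$.csc_ratio` <- function(x, name) attr(x, name)

#' @export
print.csc_ratio <- function(x, ...) {
  cat("Ratio trajectory r(t) = D(t)/S(t)\n")
  cat(sprintf("  r0 = %g, a = %g, b = %g, k2 - k1 = %g\n",
              attr(x, "r0"), attr(x, "a"), attr(x, "b"), attr(x, "delta")))
  cat(sprintf("  limiting ratio r_inf = %g\n", attr(x, "r_inf")))
  invisible(x)
}

#' Limiting ratio of differentiated cells to CSCs (eigenvalue route)
#'
#' As t grows the dominant eigenvalue takes over and r(t) converges to the
#' ratio of the dominant eigenvector's components,
#' \eqn{r_\infty = (\lambda_1 - (k_1 - a)) / b} for b > 0. The asymptotic
#' CSC percentage of the culture is \code{100 / (1 + r_inf)}.
#'
#' Edge cases: with \code{b = 0} the limit is \code{a / (k1 - a - k2)} when
#' \code{k1 - a > k2} (the CSC compartment dominates) and \code{Inf}
#' otherwise (when \code{a > 0}, or when \code{a = 0} and \code{k2 > k1});
#' with \code{a = b = 0} and \code{k1 > k2} it is 0; with
#' \code{a = b = 0} and \code{k1 = k2} the ratio stays at its initial value
#' forever, which the parameters alone cannot determine, so \code{NaN} is
#' returned. When \code{a = 0} and \code{r0 = 0} the trajectory is
#' identically 0 regardless of this limit.
#'
#' @param params A \code{\link{rate_params}} object.
#' @return The limiting ratio (dimensionless, >= 0, possibly \code{Inf}).
#' @examples
#' limiting_ratio(rate_params(0.2, 0.22, 0.01, 0.001))
#' @export
limiting_ratio <- function(params) {
  params <- as_rate_params(params)
  a <- params$a; b <- params$b
  if (b > 0) {
    l1 <- eigenvalues(params)[[1L]]
    return((l1 - (params$k1 - a)) / b)
  }
  # b = 0: dr/dt = a + (k2 - k1 + a) r is linear in r
  slope <- params$k2 - params$k1 + a
  if (slope < 0) return(a / (-slope))
  if (a > 0) return(Inf)
  # a = b = 0: r(t) = r0 e^{(k2 - k1) t}
  if (slope > 0) return(Inf)
  NaN
}

#' Limiting ratio via the steady-state quadratic (algebraic route)
#'
#' The fixed points of the Riccati ratio equation solve
#' \deqn{b r^2 - (k_2 - b - k_1 + a) r - a = 0;} the attracting fixed point
#' is its larger root (the quadratic in dr/dt opens downward in r). This is
#' an independent algebraic derivation of the same quantity as
#' \code{\link{limiting_ratio}} and agrees with it identically.
#'
#' @inheritParams limiting_ratio
#' @return The limiting ratio.
#' @export
limiting_ratio_algebraic <- function(params) {
  params <- as_rate_params(params)
  a <- params$a; b <- params$b
  cc <- params$k2 - b - params$k1 + a
  if (b > 0)
    return((cc + sqrt(cc^2 + 4 * a * b)) / (2 * b))
  if (cc < 0) return(a / (-cc))
  if (a > 0 || cc > 0) return(Inf)
  NaN
}

#' Convert between CSC percentage and differentiated-to-CSC ratio
#'
#' A flow-cytometry readout reports the CSC percentage p of the culture; the
#' model works with the ratio r = D/S of differentiated cells to CSCs. The
#' two are related by \code{r = (100 - p)/p} and \code{p = 100/(1 + r)}.
#' Percentages are on the 0-100 scale throughout, never fractions.
#'
#' @param p CSC percentage in (0, 100].
#' @param r Ratio >= 0.
#' @return The converted value(s).
#' @examples
#' percent_to_ratio(96.2)   # 0.0395...
#' ratio_to_percent(65.6667)
#' @export
percent_to_ratio <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 100))
    stop("percentage must be in (0, 100]", call. = FALSE)
  (100 - p) / p
}

#' @rdname percent_to_ratio
#' @export
ratio_to_percent <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r) & !is.infinite(r)) || any(r < 0))
    stop("ratio must be >= 0", call. = FALSE)
  100 / (1 + r)
}
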