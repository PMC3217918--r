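test_that("ode_rhs is the linear mass-action right-hand side", {
  # decoupled exponential growth
  expect_equal(unname(ode_rhs(rate_params(0.2, 0.22, 0, 0), S = 1, D = 1)),
               c(0.2, 0.22))
  expect_equal(unname(ode_rhs(rate_params(0, 0, 0, 0), S = 5, D = 3)),
               c(0, 0))
  # direct substitution
  rhs <- ode_rhs(rate_params(0.2, 0.22, 0.01, 0.001), S = 100, D = 10)
  expect_equal(unname(rhs),
               c(0.2 * 100 - 0.01 * 100 + 0.001 * 10,
                 0.22 * 10 + 0.01 * 100 - 0.001 * 10))
  expect_error(ode_rhs(rate_params(0.2, 0.2, 0, 0), S = 0, D = 1), "S > 0")
})

test_that("rate parameters are validated", {
  expect_error(rate_params(-0.1, 0.2, 0, 0), "non-negative")
  expect_error(rate_params(0.1, NA, 0, 0), "finite")
  p <- rate_params(0.1, 0.2, 0.01, 0.001)
  expect_s3_class(p, "csc_params")
})

test_that("eigenvalues solve the characteristic quadratic", {
  # triangular case: eigenvalues are the diagonal entries, sorted
  expect_equal(unname(eigenvalues(rate_params(0.2, 0.22, 0, 0))),
               c(0.22, 0.2))
  # symmetric case k1 = k2 = k, a = b = c -> (k, k - 2c)
  expect_equal(unname(eigenvalues(rate_params(0.3, 0.3, 0.04, 0.04))),
               c(0.3, 0.3 - 0.08))
  # quadratic-formula oracle on trace and determinant
  p <- rate_params(0.2, 0.22, 0.01, 0.001)
  tr <- (0.2 - 0.01) + (0.22 - 0.001)
  dt <- (0.2 - 0.01) * (0.22 - 0.001) - 0.01 * 0.001
  expect_equal(tr, 0.409)
  expect_equal(dt, 0.04160, tolerance = 1e-10)
  lam_oracle <- c((tr + sqrt(tr^2 - 4 * dt)) / 2,
                  (tr - sqrt(tr^2 - 4 * dt)) / 2)
  expect_equal(unname(eigenvalues(p)), lam_oracle, tolerance = 1e-12)
  expect_equal(lam_oracle, c(0.21934, 0.18966), tolerance = 1e-4)
  # they are eigenvalues of the system matrix
  m <- matrix(c(0.19, 0.01, 0.001, 0.219), 2, 2)
  expect_equal(sort(unname(eigenvalues(p))), sort(eigen(m)$values))
})

test_that("discriminant is non-negative for random non-negative rates", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_params()
    disc <- ((p$k1 - p$a) - (p$k2 - p$b))^2 + 4 * p$a * p$b
    expect_gte(disc, 0)
    lam <- eigenvalues(p)
    expect_gte(lam[[1]], lam[[2]])
  }
})

test_that("closed form reproduces initial conditions and decoupled limits", {
  p <- rate_params(0.2, 0.22, 0.01, 0.001)
  cf <- closed_form(p, S0 = 96.2, D0 = 3.8)
  at0 <- eval_closed_form(cf, 0)
  expect_equal(at0$S, 96.2, tolerance = 1e-10)
  expect_equal(at0$D, 3.8, tolerance = 1e-10)
  # a = b = 0, D0 = 0: pure exponential CSC growth
  cf0 <- closed_form(rate_params(0.2, 0.22, 0, 0), S0 = 1, D0 = 0)
  tt <- c(0, 1, 10, 50)
  ev <- eval_closed_form(cf0, tt)
  expect_equal(ev$S, exp(0.2 * tt), tolerance = 1e-12)
  expect_equal(ev$D, rep(0, 4))
})

test_that("closed form matches adaptive-step numerical integration", {
  p <- rate_params(0.2, 0.22, 0.01, 0.001)
  cf <- closed_form(p, S0 = 96.2, D0 = 3.8)
  ts <- c(0, 10, 50, 120)
  num <- integrate_ode(p, 96.2, 3.8, ts)
  an <- eval_closed_form(cf, ts)
  expect_lt(max(relerr(an$S, num$S)), 1e-6)
  expect_lt(max(relerr(an$D, num$D)), 1e-6)
  # random draws, positivity along the way
  set.seed(21)
  for (i in 1:20) {
    pr <- random_params()
    S0 <- runif(1, 0.5, 100); D0 <- runif(1, 0, 100)
    ts <- c(0, 30, 150, 300)
    an <- eval_closed_form(closed_form(pr, S0, D0), ts)
    num <- integrate_ode(pr, S0, D0, ts)
    expect_lt(max(relerr(an$S, num$S)), 1e-6)
    expect_lt(max(relerr(an$D, num$D)), 1e-6)
    expect_true(all(an$S > 0))
    expect_true(all(an$D >= 0))
  }
})

test_that("degenerate (confluent) eigenvalues are handled", {
  # a = 0 makes the discriminant (a11 - a22)^2; choose k1 - a = k2 - b
  p <- rate_params(0.25, 0.3, 0, 0.05)
  lam <- eigenvalues(p)
  expect_equal(lam[[1]], lam[[2]], tolerance = 1e-12)
  cf <- closed_form(p, S0 = 10, D0 = 2)
  expect_true(cf$degenerate)
  ts <- c(0, 5, 40, 100)
  an <- eval_closed_form(cf, ts)
  num <- integrate_ode(p, 10, 2, ts)
  expect_lt(max(relerr(an$S, num$S)), 1e-6)
  expect_lt(max(relerr(an$D, num$D)), 1e-6)
})

test_that("ratio trajectory equals D(t)/S(t) and starts at r0", {
  p <- rate_params(0.2, 0.22, 0.01, 0.001)
  r <- ratio_trajectory(p, r0 = 0.0395)
  expect_equal(r(0), 0.0395)
  ts <- c(50, 100, 200)
  num <- integrate_ode(p, 1, 0.0395, c(0, ts))
  expect_lt(max(relerr(r(ts), num$D[-1] / num$S[-1])), 1e-6)
  # consistency with the closed form for a consistent (S0, D0)
  cf <- closed_form(p, S0 = 96.2, D0 = 96.2 * 0.0395)
  ev <- eval_closed_form(cf, ts)
  expect_equal(r(ts), ev$D / ev$S, tolerance = 1e-8)
})

test_that("ratio trajectory is constant at the Riccati fixed point", {
  p <- rate_params(0.2, 0.22, 0.01, 0.001)
  rinf <- limiting_ratio(p)
  r <- ratio_trajectory(p, r0 = rinf)
  ts <- c(0, 1, 10, 100, 300)
  expect_equal(r(ts), rep(rinf, length(ts)), tolerance = 1e-9)
})

test_that("ratio trajectory is invariant under (k1, k2) -> (k1+c, k2+c)", {
  set.seed(31)
  ts <- c(0, 5, 50, 200)
  for (i in 1:20) {
    p <- random_params()
    r0 <- runif(1, 0, 5)
    base <- ratio_trajectory(p, r0)(ts)
    for (cc in c(0.05, 0.3)) {
      shifted <- ratio_trajectory(
        rate_params(p$k1 + cc, p$k2 + cc, p$a, p$b), r0)(ts)
      expect_equal(shifted, base, tolerance = 1e-10)
    }
  }
})

test_that("|r(t) - r_inf| decreases monotonically toward the limit", {
  set.seed(41)
  ts <- seq(0, 300, by = 10)
  for (i in 1:20) {
    p <- random_params()
    if (p$b == 0) next
    rinf <- limiting_ratio(p)
    for (r0 in c(0.01, rinf * 2)) {
      gap <- abs(ratio_trajectory(p, r0)(ts) - rinf)
      expect_true(all(diff(gap) <= 1e-12 * pmax(1, gap[-length(gap)])))
    }
  }
})

test_that("both limiting-ratio routes agree and match the quadratic root", {
  # symmetry: k1 = k2, a = b > 0 -> 1
  expect_equal(limiting_ratio(rate_params(0.3, 0.3, 0.02, 0.02)), 1)
  expect_equal(limiting_ratio_algebraic(rate_params(0.3, 0.3, 0.02, 0.02)), 1)
  # a = 0, b > 0, k1 > k2 - b: CSC compartment dominates, ratio -> 0
  expect_equal(limiting_ratio(rate_params(0.3, 0.2, 0, 0.05)), 0)
  # positive root of b r^2 - (k2 - b - k1 + a) r - a = 0
  p <- rate_params(0.2, 0.22, 0.01, 0.001)
  cc <- 0.22 - 0.001 - 0.2 + 0.01
  root <- (cc + sqrt(cc^2 + 4 * 0.01 * 0.001)) / (2 * 0.001)
  expect_equal(limiting_ratio(p), root, tolerance = 1e-12)
  expect_equal(limiting_ratio_algebraic(p), root, tolerance = 1e-12)
  expect_equal(root, 29.3408, tolerance = 1e-4)
  # algebraic identity on random draws
  set.seed(51)
  for (i in 1:1000) {
    pr <- random_params()
    r1 <- limiting_ratio(pr)
    r2 <- limiting_ratio_algebraic(pr)
    if (is.finite(r1)) {
      expect_equal(r2, r1, tolerance = 1e-10)
    } else {
      expect_identical(r2, r1)
    }
  }
})

test_that("limiting ratio edge cases follow the linear-ODE limit", {
  # b = 0, a > 0, differentiated compartment dominant -> Inf
  expect_identical(limiting_ratio(rate_params(0.2, 0.22, 0.01, 0)), Inf)
  # b = 0, a > 0, CSC compartment dominant -> a/(k1 - a - k2)
  p <- rate_params(0.4, 0.1, 0.05, 0)
  expect_equal(limiting_ratio(p), 0.05 / (0.4 - 0.05 - 0.1))
  expect_equal(limiting_ratio_algebraic(p), limiting_ratio(p))
  # a = b = 0: sign of k2 - k1 decides; equal rates are indeterminate
  expect_identical(limiting_ratio(rate_params(0.1, 0.3, 0, 0)), Inf)
  expect_equal(limiting_ratio(rate_params(0.3, 0.1, 0, 0)), 0)
  expect_true(is.nan(limiting_ratio(rate_params(0.2, 0.2, 0, 0))))
  # the trajectory actually approaches the b = 0 finite limit
  r <- ratio_trajectory(p, r0 = 2)
  expect_equal(r(500), limiting_ratio(p), tolerance = 1e-6)
})

test_that("percent/ratio conversions match the printed data and round-trip", {
  expect_equal(percent_to_ratio(96.2), 0.0395, tolerance = 1e-4)
  expect_equal(percent_to_ratio(50), 1.0)
  expect_equal(percent_to_ratio(1.5), 65.6667, tolerance = 1e-4)
  expect_equal(ratio_to_percent(0), 100)
  p <- c(0.5, 1.5, 12.3, 50, 96.2, 100)
  expect_equal(ratio_to_percent(percent_to_ratio(p)), p, tolerance = 1e-12)
  expect_error(percent_to_ratio(0), "\\(0, 100\\]")
  expect_error(percent_to_ratio(-3), "\\(0, 100\\]")
  expect_error(ratio_to_percent(-0.1), ">= 0")
})
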