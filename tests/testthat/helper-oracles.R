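# Independent numerical-ODE oracle: adaptive-step integration of the
# right-hand side with deSolve::lsoda at tight tolerances. Used to check the
# closed-form solution, never the other way round.
integrate_ode <- function(params, S0, D0, times) {
  out <- deSolve::ode(c(S = S0, D = D0), times,
                      function(t, y, parms) list(ode_rhs(params, y[1], y[2])),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  as.data.frame(out)
}

# random non-negative parameter draws kept in a range where exp(lambda * t)
# stays representable out to t = 300
random_params <- function() {
  rate_params(runif(1, 0, 0.5), runif(1, 0, 0.5),
              runif(1, 0, 0.2), runif(1, 0, 0.2))
}

relerr <- function(x, ref) abs(x - ref) / pmax(abs(ref), 1e-300)
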