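# cscdrift

Kinetics of cancer-stem-cell (CSC) ratio drift in long-term sphere culture.

Sorted CSCs are routinely expanded as non-adherent spheres in serum-free
medium, but serial passaging does not preserve the sorted purity: in MCF-7
mammospheres the CD44+CD24-/low fraction falls from 96.2% at seeding to about
1.5% by day 160. `cscdrift` is for researchers who want to model, fit and
interrogate that drift: it implements the two-compartment linear kinetic
model behind it, Bayesian estimation of its rates from ratio time courses,
and a local sensitivity analysis that asks which rates the outcome actually
depends on.

## The model

CSCs `S(t)` and differentiated cancer cells `D(t)` grow and interconvert:

    dS/dt = k1*S - a*S + b*D
    dD/dt = k2*D + a*S - b*D

with four non-negative per-day rates: intrinsic growth rates `k1`, `k2`, the
CSC-to-differentiated conversion rate `a` (asymmetric division), and the
back-conversion rate `b` (e.g. EMT). The observable is the ratio
`r = D/S = (100 - p)/p` derived from the measured CSC percentage `p`. The
linear system solves exactly in terms of the eigenvalues `lambda1 >= lambda2`
of `[[k1-a, b], [a, k2-b]]`; the ratio obeys the Riccati equation

    dr/dt = a + (k2 - b - k1 + a)*r - b*r^2

and converges to the limiting ratio `r_inf = (lambda1 - (k1 - a))/b`, the
positive root of `b*r^2 - (k2 - b - k1 + a)*r - a = 0`. The asymptotic CSC
percentage of the culture is `100/(1 + r_inf)`. Ratio data identify only
`(a, b, k2 - k1)`; all summaries report this reduction alongside the raw
rates.

Parameters are estimated by adaptive Metropolis-Hastings MCMC (uniform
priors, Gaussian likelihood on r with unknown scale, covariance-adapting
proposals, 10,000 iterations with 3,000 burn-in by default); sensitivity is
measured by standardized local sensitivity coefficients of the
sum-of-squared-deviations design function under ±1-5% perturbations,
compared by one-way ANOVA with Tamhane's T2 post-hoc tests. See the
`csc-ratio-kinetics` vignette for the full account.

## Worked example

```r
library(cscdrift)

tc <- mcf7_timecourse()          # packaged 12-point MCF-7 time course
head(tc, 3)
#>  time_days csc_percent  ratio
#>          0        96.2 0.0395
#>         28        84.9 0.1779
#>         52        53.2 0.8797

p <- rate_params(k1 = 0.2, k2 = 0.22, a = 0.01, b = 0.001)
eigenvalues(p)
#>   lambda1   lambda2
#> 0.2193408 0.1896592
limiting_ratio(p)
#> [1] 29.34082

fit <- run_adaptive_mh(tc, fit_config(seed = 1))
summarize_chain(fit)
#>                quantity    median     lower     upper
#>                      k1 4.299e-01 1.616e-02  0.924521
#>                      k2 4.887e-01 7.777e-02  0.982962
#>                       a 1.448e-03 2.721e-05  0.011180
#>                       b 8.109e-04 5.448e-04  0.000994
#>                   sigma 4.311e+00 2.793e+00  8.337617
#>                   delta 5.948e-02 3.571e-02  0.066801
#>                   r_inf 7.396e+01 6.509e+01 88.725453
#>  asymptotic_csc_percent 1.334e+00 1.115e+00  1.513158
#>
#> Limiting ratio D/S: 74 [65.1, 88.7]
#> Asymptotic CSC percentage: 1.33% [1.11, 1.51]
```

The fit says the culture's differentiated-to-CSC ratio heads to a plateau
around 74 (so roughly 1.3% CSCs at equilibrium, matching the observed late
plateau near 1.5%), driven by a growth-rate difference `delta = k2 - k1`
of about 0.06/day with conversion rates two orders of magnitude smaller.
The wide, prior-like `k1` and `k2` marginals are the expected signature of
the identifiability ridge, not a fitting failure.

Sensitivity of the fit's design function at the posterior median:

```r
med <- apply(fit$samples[, c("k1", "k2", "a", "b")], 2, median)
sens <- sensitivity_analysis(tc, rate_params(med["k1"], med["k2"],
                                             med["a"], med["b"]))
sens$lsc$summary
#>   parameter        mean          sd
#> 1        k1 152539.0675 70511.39566
#> 2        k2 191634.9968 88800.36650
#> 3         a    103.0297    17.93081
#> 4         b    500.9777   346.22273
sens$anova
#> One-way ANOVA: F(3, 36) = 31.39, p = 3.753e-10
```

The growth rates dominate the conversion rates by orders of magnitude: the
equilibrium CSC fraction is controlled by how fast the two compartments
grow relative to each other, not by how fast they interconvert.

A thin command-line front-end over the same functions ships at
`inst/cli/cscdrift.R` (`fit`, `predict`, `sensitivity`, `simulate`
subcommands), and `cmd_fit()` / `cmd_sensitivity()` / `cmd_simulate()` /
`cmd_predict()` write the chain, summary JSON, curve and LSC artifacts from
R directly.

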