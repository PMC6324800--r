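# dwellgmm

Cumulant-based Generalized Method of Moments (GMM) estimation of hidden
kinetic decay parameters from single-molecule dwell times.

## The problem

Single-molecule experiments (bead-loss assays, smFRET, particle tracking)
produce lists of *dwell times*: the time a molecule takes to reach its final
state through a chain of hidden kinetic intermediates. For an n-step
irreversible scheme whose steps have mean residence times τ₁…τₙ, the
observed dwell time is a sum of independent exponentials, and the usual
analysis — histogramming and nonlinear least-squares fitting of a
multi-exponential decay — is biased and unstable at the sample sizes
single-molecule work actually delivers (tens of events, sometimes five).

`dwellgmm` estimates the τⱼ directly from the moments of the data, with no
binning. Cumulants of a sum of independent processes add, and the order-m
cumulant of an exponential step is (m−1)!τᵐ, so the n-step scheme has
population cumulants

    κ⁽ᵐ⁾(τ) = (m−1)! (τ₁ᵐ + τ₂ᵐ + … + τₙᵐ).

From the sample side, the k-statistics k⁽ᵐ⁾(t, T) — the unique unbiased
estimators of the cumulants — are computed up to fourth order. The moment
functions

    gₘ(τ, t, T) = κ⁽ᵐ⁾(τ) − k⁽ᵐ⁾(t, T),   m = 1…M,

have zero expectation at the true parameters, and the GMM estimate
minimises the quadratic form

    Q(τ) = Σₘ Σₘ' W_{mm'} gₘ gₘ',   τ̂ = argmin Q,

for a positive-definite weight matrix W. Supported weightings: identity
(I-matrix), inverse diagonal jackknife variances of the cumulants
(D-matrix, the default and the best performer in simulation studies),
inverse full jackknife covariance (C-matrix), and the inverse of a
covariance interpolated from precomputed Monte-Carlo tables (used by the
two-pass refinement). Minimisation is multi-start BFGS with an analytic
gradient over a log-spaced grid of starting points, so the global minimum
of the polynomial surface is found deterministically.

When the number of moment conditions equals the number of steps
(*just-specified*), the GMM coincides with the Classical Method of Moments
(CMM) whenever the CMM's moment equations have a real solution — but the
CMM frequently has none (its discriminant goes negative), in which case the
two-step GMM returns a *double root* and still delivers an estimate. The
package ships the exact CMM solver (Newton's identities + companion-matrix
roots) and the histogram NL-LSQM comparator (√N binning, exact
finite-bin-width correction, Levenberg–Marquardt) so all three analyses can
be run side by side, plus a simulation harness for bias/dispersion studies
and a just-specified model-order scan for asking "how many steps does this
data support?".

## Worked example

```r
library(dwellgmm)

# two-step scheme: tau = (10, 50) s, 500 observed dwell times
times <- simulate_irreversible(c(10, 50), 500, seed = 42)

fit <- gmm_fit(times, n_steps = 2)      # just-specified, D-matrix weights
summary(fit)
#> GMM fit: 2-step scheme, order 2, jackknife_diag weights
#> Decay parameter estimates (s, sorted):
#> [1] 10.3513 53.2553
#> Q_min = 7.60121e-30 on 500 dwell times
#>
#> Sample k-statistics vs fitted population cumulants:
#>         k^(m) kappa^(m)         g_m
#> m=1   63.6066   63.6066 9.30811e-13
#> m=2 2943.2800 2943.2800 1.00044e-10
#>
#> Starts: 10 (10 converged); weight scheme: jackknife_diag
```

The estimates (10.35 s, 53.26 s) recover the generating parameters to
within sampling error; `Q_min ≈ 0` says both moment conditions are
satisfied exactly, i.e. the classical solution exists and the GMM found it:

```r
cmm_solve(times, 2)
#> Classical method of moments, 2-step scheme (T = 500)
#> Real solution (s, sorted):
#> [1] 10.3513 53.2553
```

The histogram comparator agrees at this sample size, and the model-order
scan shows what overfitting looks like — the third step comes back
negative, while the slow step barely moves:

```r
nlsq_fit(times)
#> NL-LSQM fit: 2-exponential model, 23 bins, T = 500
#> Decay parameter estimates (s, sorted):
#> [1] 11.6467 49.6958
#> RSS = 452.973; 10/10 starts converged

model_order_scan(times, 3)
#> Just-specified model-order scan (T = 500)
#>   1 step(s): (63.607) s
#>   2 step(s): (10.351, 53.255) s
#>   3 step(s): (-2.8936, 14.227, 52.273) s [negative -> overfit]
```

Note the conservation law visible in the scan: at every just-specified
order the estimates sum to the sample mean (63.607 s).

A command-line front end over the same functions lives in
`exec/dwellgmm.R` (subcommands `simulate`, `gmm`, `cmm`, `nlsq`, `bench`,
`scan`, `make-cov-table`; run it with `help` for usage).

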