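---
title: "Moment-based estimation of multi-step dwell-time kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based estimation of multi-step dwell-time kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwellgmm)
```

# The model

A dwell time is the total time a molecular system takes to reach its final
state from its initial state. `dwellgmm` models it as an n-step
irreversible chain whose step residence times are independent exponentials
with means $\tau_1,\dots,\tau_n$ (seconds). Two facts make this model
tractable with moments alone:

* cumulants of a sum of independent variables add, and
* the order-$m$ cumulant of an exponential with mean $\tau$ is
  $(m-1)!\,\tau^m$,

so the population cumulants of the dwell time are
$\kappa^{(m)}(\tau) = (m-1)!\sum_j \tau_j^m$ — polynomials in the
parameters, known in closed form for any number of steps.

A two-step scheme with a *reversible* first step (rates $k_1, k_2, k_3$)
has a dwell-time density of exactly the same biexponential form; the
effective decay constants are

$$\frac{1}{\tau_{B/A}} = \frac{k_1+k_2+k_3}{2} \pm
  \sqrt{\frac{(k_1+k_2+k_3)^2}{4} - k_1 k_3},$$

implemented in `rates_to_decay()`. `simulate_reversible()` therefore draws
from the two-exponential convolution of the mapped constants rather than
simulating state-resolved trajectories: the two are distributionally
identical for the observable (the total dwell time), and the convolution
is exact and fast. Reversible schemes with more than two steps are out of
scope — their dwell-time densities no longer reduce to the irreversible
form.

# The estimator

On the sample side the package uses *k-statistics* — the unique symmetric
unbiased estimators of the cumulants — up to order 4 (`k_statistics()`).
The moment functions
$g_m(\tau) = \kappa^{(m)}(\tau) - k^{(m)}(\mathbf t, T)$ have zero mean at
the true parameters at every sample size, which is what gives the method
its small-sample advantage over histogram fitting. The estimate minimises

$$Q(\tau) = \sum_{m,m'=1}^{M} W_{mm'}\, g_m(\tau)\, g_{m'}(\tau),$$

with $M$ the order of the method ($n \le M \le 4$) and $W$ a fixed
positive-(semi)definite weight matrix built once from the sample before
minimisation. Orders above 4 are refused rather than approximated:
unbiased cumulant estimators beyond order 4 would have to be derived and
validated separately, and silently substituting biased ones would change
the estimator's defining property. This caps the model-order scan at four
steps.

## Weight matrices

Four schemes (`weights =` in `gmm_fit()`):

* **identity** — no weighting; simple, scale-inconsistent across orders.
* **jackknife_diag** (default) — diagonal of the leave-one-out jackknife
  covariance of the k-statistics, inverted. The best bias performer in the
  package's own simulation studies, and cheap: the leave-one-out sweep is
  computed from downdated power sums in $O(TM)$.
* **jackknife_full** — the full jackknife covariance, inverted.
* **mc_interp** — the inverse of a covariance interpolated from a
  precomputed Monte-Carlo table (`build_covariance_table()`), used mainly
  as the second pass of `gmm_two_pass()`.

The jackknife uses the standard convention
$v = \frac{T-1}{T}\sum_i (\hat\theta_i - \bar\theta)(\hat\theta_i -
\bar\theta)^{\top}$. The scaling sentence this derives from could also be
read with an extra $1/T$ inside the sum; the standard form was chosen
because it yields the exact identity $v_{11} = s^2/T$ for the jackknifed
mean and the canonical large-$T$ limit (the identity is regression-tested).

Degenerate samples must not crash the estimator, so `invert_to_weight()`
falls back: a covariance with reciprocal condition number below $10^{-12}$
is replaced by its diagonal; a zero diagonal entry gets unit weight; both
emit warnings. A sample of identical values therefore ends up with the
identity weight — and still produces an estimate (a double root; see
below).

Covariance tables interpolate element-wise and multilinearly in
$\log_{10}\tau_j$ and $\log_{10} T$, because cumulant covariances vary
over decades along each axis and parameter grids are naturally
logarithmic. Queries are indexed by the *sorted* parameter tuple (the
covariance is permutation symmetric), out-of-hull queries clamp to the
boundary with a warning, and node queries return the stored matrix
exactly. Node placement and per-node trial counts (default $10^5$) are
configurable; linear interpolation between sparse nodes is crude — for
accurate weights place nodes within a factor of ~3 of the expected
parameters.

## Minimisation

$Q$ is a multi-polynomial in $\tau$, so the surface is smooth and not
rough. The global minimum is located by BFGS (`stats::optim`) with the
analytic gradient

$$\frac{\partial Q}{\partial \tau_j} =
  2 \sum_m (Wg)_m \, m!\, \tau_j^{\,m-1},$$

run from every point of a logarithmically spaced grid of starts:
per-dimension factors of `grid_factor` (default 10) across `region`
(default $[1, 1000]$ s, i.e. starts $\{1, 10, 100, 1000\}$). Choose the
region about one decade beyond the plausible extremes of your time scales.
Since $Q$ is symmetric under permutation of the parameters, duplicate
unordered start tuples are pruned (16 → 10 starts for two steps, 64 → 20
for three) with identical search coverage.

Numerical choices, made once:

* convergence by `optim`'s relative function reduction (`reltol = 1e-12`,
  `maxit = 500`), plus one polish restart from the winning start —
  `optim`'s BFGS does not expose a gradient-norm stopping rule;
* `parscale` set to the starting point so decades-apart parameters are
  conditioned comparably;
* ties between multi-start minima within $10^{-12}$ relative $Q$ resolve
  to the lexicographically smallest sorted estimate vector (determinism);
* estimates are reported sorted ascending; the labels carry no physical
  order information (any permutation fits equally well).

Parameters are deliberately **not** constrained positive during descent.
Negative returned constants are the working overfit diagnostic in the
model-order scan, and constraining them away would destroy that signal.
Only the *starting points* are positive.

## Relation to the classical method

When $M = n$ (just-specified) and the classical moment equations
$g_m = 0$ have a real solution, that solution zeroes $Q$, so the GMM
returns it regardless of the weight matrix. `cmm_solve()` computes it
exactly: power sums $p_m = k^{(m)}/(m-1)!$, Newton's identities for the
elementary symmetric polynomials, and `polyroot()` for the companion-matrix
roots. Roots with $|\mathrm{Im}| \le 10^{-8}(1+|\mathrm{Re}|)$ count as
real (root finders leave tiny imaginary dust); negative real roots are
reported, flagged, and *not* treated as errors.

When the classical solution is complex — which happens often for
two-step data at small $T$, whenever $2k^{(2)} < (k^{(1)})^2$ — the
second-order GMM's minimum lies on the diagonal $\tau_1 = \tau_2$: a
*double root*. `gmm_fit()` flags adjacent sorted estimates within
$10^{-4}$ relative as `double_root`; the band exists because theory
predicts exact coincidence but finite optimizer precision does not. One
consequence worth knowing: double roots sit between the true constants, so
across trials the lower estimate is biased up and the upper estimate
biased down. Another conservation law helps interpretation: any real
just-specified solution has $\sum_j \hat\tau_j$ equal to the sample mean
exactly.

# The histogram comparator

`nlsq_fit()` implements the conventional alternative so comparisons stay
in-package: counts in $\lceil\sqrt T\rceil$ equal-width bins spanning
$[0, \max t]$ (the range is a documented package choice; the protocol it
follows does not state one), fit by Levenberg–Marquardt
(`minpack.lm::nls.lm`) from the same start grid as the GMM, unweighted
least squares on counts. The finite-bin-width correction is exact: the
expected count per bin is $T[F(e_{i+1}) - F(e_i)]$ with $F$ the model CDF,
not a midpoint-density approximation — it is parameter-free and makes
merged-bin expectations exactly additive (tested). A fit is flagged
`negative_or_failed` when no start converges, an estimate is nonpositive
or non-finite, or an estimate exceeds $10^4 \times$ the data range (such a
value carries no information at the sample's scale). At $T \le 10$ a few
per cent of fits flag while the moment estimator returns values for every
trial; that asymmetry, not large-$T$ accuracy, is the method difference
that matters.

# The simulation harness

`run_batch()` simulates each trial once and hands the *same* draws to
every configured method (paired comparison), recording per-trial failures
without aborting. `summary()` reports, per method and sorted-parameter
index: the mean estimate over successful trials and the **mean absolute
deviation about the trial mean** as the dispersion measure. Mean deviation
about the *truth* would conflate bias with spread; the two are reported
separately (bias is visible as mean − truth). Failed trials are excluded
from means and tallied — imputing zeros would drag means toward
nonsense.

The generator emulates exactly the study conditions of the reference
protocols: exponential steps, independent draws, no measurement noise. It
does **not** emulate frame-rate discretisation, missed events, detection
dead time, or heterogeneity between molecules — passing tests therefore
demonstrate estimator correctness under the model, not robustness to those
artefacts. Trial streams derive from a base seed by offsetting
(`seed + i`), so batches are bit-reproducible and individual trials can be
re-simulated in isolation.

Default protocol sizes follow the reference studies (1000 trials; sample
sizes 5–1000; parameter sets such as (10, 50) s and (10, 30, 100) s). The
package's test suite runs reduced designs — typically 60–400 trials and
$T \le 1000$, chosen as the smallest batches whose expected effects exceed
their Monte-Carlo noise by a comfortable margin — while the acceptance
script runs the full 1000-trial batches.

# Known limitations

* Orders and step counts above 4 are unsupported (see above); the
  model-order scan caps there and says so.
* The GMM sandwich standard-error formula is not implemented; uncertainty
  is quantified by simulation dispersion, matching the protocols this
  package reproduces.
* Estimates are only defined up to sorting; when two true constants are
  equal or close, individual sorted estimates are biased (the double-root
  geometry above) even though their sum is not.
* The continuously-updated weight matrix variant of the GMM is
  deliberately not implemented; only fixed-weight and two-pass variants
  are.
* Covariance-table interpolation is linear between nodes; sparse tables
  give approximate weights (harmless for just-specified fits, which are
  weight-independent when a real classical solution exists).
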