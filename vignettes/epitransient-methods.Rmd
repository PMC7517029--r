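---
title: "Methods: epidemic transients, entropy, and the log-normal reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epidemic transients, entropy, and the log-normal reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitransient)
```

## The model family

The package treats every infection curve as a solution of the scalar
first-order model
$$\dot I(t) = \alpha(t)\, I(t), \qquad
  \alpha(t) = -c\,\frac{\ln(g(t)/E)}{h(t)},$$
with $c, E > 0$ and $g, h$ continuous, differentiable and positive on
$(0,\infty)$.  The factorized form is what carries the transient
information: $\alpha$ vanishes exactly where $g$ crosses the threshold
$E$, which is therefore the first infection maximum $D$; convexity at the
origin ($\alpha^2(0) + \dot\alpha(0) > 0$) forces an inflection time
$L \in (0, D)$.  `alpha_peak_preconditions()` evaluates these conditions
numerically on a dense grid; functions singular at the origin (the Gibrat
coefficient has $\alpha(0^+) = +\infty$) are probed at $10^{-8}$ of the
scan range instead of at zero, and a divergence to the correct side counts
as satisfying the condition.

Three concrete models are built in:

* **Gibrat** (`gibrat_params()`): $g = h = \mathrm{id}$, $E = D$, with
  $c = (1 - \ln(L/D))/\ln^2(L/D)$ so that the curve
  $I(t) = I_{peak}\,e^{-(c/2)\ln^2(t/D)}$ has its peak at $D$ and its
  rising inflection at $L$.  The curve is anchored at its *peak* value:
  $I(0^+) = 0$, so anchoring at the origin is impossible, and the peak
  normalization is the one that identifies the curve with the log-normal
  reference below.
* **SIR without demography** (`sir_params()`): $\dot S = -\beta S I$,
  $\dot I = (\beta S - \gamma) I$, $\dot R = \gamma I$.  The initial
  regime is classified by comparing $S_0$ with $\gamma/\beta$
  (`classify_sir_case()`): below threshold the infection decays from the
  start; above it the curve rises to an interior maximum reached exactly
  when $S$ falls to $\gamma/\beta$.
* **SIS with feedback controls** (`sis_params()`): vaccination removes
  susceptibles at rate $k_V S$ and treatment removes infectious at rate
  $k_T I$ into an explicit recovered compartment, kept so that
  conservation $S + I + R = N_0$ is checkable.
  `sis_peak_preconditions()` evaluates the three sufficient conditions
  for an interior maximum (initial growth, bounded $I_0$, initial
  convexity); the maximum occurs where $S$ crosses
  $(\gamma + k_T)/\beta$.

**Units.** All rates are per year; day conversions happen only at report
time through a 365-day year (`infectious_period_days()`).

## Numerical integration

No ODE-solver package is assumed: the package carries a Dormand–Prince
RK5(4) stepper with standard PI-free step control (accept when the
embedded-error RMS is below one, grow/shrink by $0.9\,\mathrm{err}^{-1/5}$
capped to $[0.2, 5]$).  Defaults are `rtol = 1e-10`, `atol = 1e-12`,
chosen so transient times are resolved to about six significant digits as
the oracle tests require.  Output lands on a fixed grid of at least 2000
nodes; between nodes states are evaluated by cubic Hermite interpolation
anchored on the *analytic* right-hand side at the nodes, and the
derivatives $\dot I, \ddot I$ used for feature detection are always
computed analytically from the interpolated states, never by differencing.

Two transformations keep relative accuracy in extreme regimes:

* the Gibrat model is integrated as $d(\ln I)/dt = \alpha(t)$, because near
  its time origin the curve spans hundreds of orders of magnitude (the
  integration starts at $t_0 = 10^{-6} D$, initialized from the closed
  form);
* the SIR susceptible compartment is integrated as $\ln S$ whenever
  $S_0 > 0$, because $\dot S \propto S$ and in high-reproduction regimes
  $S$ collapses far below any absolute tolerance while remaining
  dynamically meaningful; this keeps the identity
  $S(t) = S_0 e^{-\beta \int_0^t I}$ accurate at any magnitude.

Tiny negative excursions (beyond $-10^{-12} N_0$) are clipped to zero;
larger ones abort with an error rather than masking a model bug.

## Feature detection

`find_first_maximum()` scans $\dot I$ on a dense grid (≥ 2000 nodes) for a
sign change and refines the bracketed root to a relative time tolerance of
$10^{-10}$; the candidate must have $\ddot I < 0$.  A grazing zero — a
touch without sign change — declares *no* maximum, consistent with the
exclusion of equilibria reached in finite time.  `find_first_inflection()`
applies the same machinery to $\ddot I$ and uses the sign-change test to
distinguish a true inflection from a mere undulation point; higher-order
degeneracies (chains of vanishing derivatives) are not resolved
symbolically — a zero of $\ddot I$ without sign change is simply not an
inflection here.  `check_alternation()` reports the zero sets of both
derivatives and whether they strictly interleave starting with an
inflection.

Cut times (`cut_times()`) locate the earliest time after which $|I|$,
$|\dot I|$, $|\ddot I|$ stay below $k_i\,\varepsilon$ with
$\varepsilon \in (0,1)$, $k_i \ge 1$.  The "for all later times" clause is
necessarily horizon-limited: the scan runs backwards from the simulated
horizon, which is recorded in the returned row.  A curve already below its
threshold cuts at the start of the support; a threshold still violated at
the horizon yields `NA`.

## Entropy functionals

The order-$\eta$ entropy
$S_I(\eta) = -\eta \int_0^\infty I \ln(t^{1-\eta} I)\,dt$ is the Riemann
form of the Stieltjes integral against $dt^\eta$.  All improper integrals
are computed under the substitution $u = \ln t$ with adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-11}$); for plain functions
the integration window is found automatically by trimming where the
$u$-integrand falls below $10^{-15}$ of its peak, and a tail still alive
at the scan edge raises a non-integrability error.  The convention
$0 \ln 0 = 0$ applies wherever the curve vanishes, including the $t = 0$
endpoint of simulated supports.  The normalized variant divides by
$\int I$ first (making values comparable to the unit-mass reference and
scale-invariant); the truncated variant $-\int_0^t I \ln I$ has its
inflection exactly at the infection maximum, since its second derivative
is $-\dot I (1 + \ln I)$.

The entropy error against a reference curve uses the pointwise kernel
$\delta(t) = I^I / I_r^{I_r} \cdot t^{(\eta-1)(I_r - I)} - 1$, evaluated
in log space.  $\tilde S_I = -\eta \int \ln(1+\delta)$ splits into the
linear part $-\eta\int\delta$ and the Newton–Mercator tail
$\sum_{n\ge2} (-1)^{n+1}\delta^n/n$, integrated termwise on a fixed
Simpson grid in $u$ (8193 nodes) so that the decomposition identity is
exact up to series truncation; terms stop below $10^{-12}$ or at 200
terms.  The series is valid only when $\max|\delta| < 1$: non-convergence
is *reported* (`series_converged = FALSE`, tail `NA`), never silently
summed.  Note that $\delta$ compares curves through $I^I$, so it is only
tame when curve values are $O(1)$; comparisons of sharply peaked densities
should be made in peak-rescaled time (as the tests do).

## The log-normal reference and matching

The reference family is the unit-mass log-normal parameterized by its
*mode*: $\mu = \ln D_r + \sigma^2$, so the reference peak time is exactly
$D_r$.  The maximum-dissipation principle fixes the width at
$\sigma_r(\eta) = 1/\sqrt{2\eta}$.  Writing $\ln t = \mu + \sigma^2 v$,
the curvature zeros solve $(1+v)^2 + (1+v) - 1/\sigma^2 = 0$; the rising
branch takes the smaller root, giving closed forms for $L_r$, the time
ratio $D_r/L_r$ and the value ratio
$I_r(D_r)/I_r(L_r) = e^{9\sigma^2/2}$.  Printed renderings of these
constants in the literature are not always unambiguous about radicals
($\sqrt{2\pi}$ vs $2\pi$, $1/\sqrt{2\eta}$ vs $1/2\eta$); the package
adopts the readings anchored by the one unambiguous quoted decimal
($0.408 = 1/\sqrt6$) and cross-validates each against quadrature oracles
in the tests.  One residual discrepancy is documented rather than
resolved: the historically quoted value ratio 2.120 differs from the
analytic $e^{3/4}$ by about 0.15%; the package reports the analytic
value.

Matching a computed curve to the family proceeds one quantity at a time
(`match_reference()`):

* $D_{rm}$ inverts the fixed-width reference entropy from the curve's
  normalized entropy.  Two inversion constants circulate — $\pi$ (the
  printed relation) and $\sqrt\pi$ (the one consistent with the
  closed-form entropy at $\sigma = 1/\sqrt2$).  The printed form is the
  default; the other is selectable (`variant = "sqrt_pi"`) and the choice
  is recorded in the result.
* $\sigma_{rm}$ solves the closed-form entropy equation at the curve's own
  peak time $D$; the equalization target is the $\sigma$-parameterized
  entropy family, the only reading that yields a solvable equation in
  $\sigma$.  The closed form is strictly increasing in $\sigma$, so the
  bracketed root on $[10^{-4}, 10]$ (expanded once to $[10^{-6}, 100]$) is
  unique.
* $\sigma_{rmv}$ solves $D^2(e^{\sigma^2}-1)e^{3\sigma^2} = \mathrm{var}(I_n)$,
  again strictly monotone and unique.

On the reference family itself both solvers recover the generating width
exactly (to root tolerance), which is the package's self-consistency
check; on multi-compartment epidemics the matched widths drift from
$1/\sqrt2$, increasingly so as $S_0/I_0$ grows — the coupling of the
infectious compartment to the others is what the drift measures.

## Presets and the stated experimental world

The built-in presets fix the package's "experiments": the controlled-SIS
demonstration uses $\beta = 30$, $\gamma = 50$, $k_V = 1$, $k_T = 50$ per
year.  With these rates the susceptible threshold is
$(\gamma + k_T)/\beta = 10/3$, so *no* unit-population initial condition
can satisfy the peak preconditions; the demo preset therefore uses
unnormalized initial conditions ($S_0 = 10$, $I_0 = 0.2$) that genuinely
satisfy all three, and the precondition predicate reports honestly for any
input rather than guessing.  The SIR presets use $\beta = 13065$,
$\gamma = 50.1$ per year with one percent of a unit population initially
infectious (the epidemic case) or a below-threshold susceptible level (the
decay case).  Control-gain sweeps use the same rates with gains on a
$\{0, 145, 290\}$ grid — from no control through a strong effort of 290
per year — applied symmetrically to both gains so their effects are
comparable.

## What the synthetic generators emulate — and what they do not

`fixture_curve()` produces closed-form Gibrat, log-normal, oscillatory
($\alpha = a\cos\omega t$, whose derivative zeros strictly interleave) and
seeded perturbed curves (a base curve times $1 + A\,p(t)$ with a smooth
random Fourier bump, $\max|p| \le 1$, so positivity and
$\max|\delta| < 1$ are guaranteed by construction for small $A$).  These
fixtures exercise the detection, entropy and matching machinery against
exact oracles; they are smooth, noise-free, deterministic curves.  They do
*not* emulate observation noise, reporting artifacts, weekly seasonality,
or stochastic epidemic variability — a green test establishes correctness
of the numerics on the stated model family, not robustness to real
surveillance data.  Likewise the compartmental models here are
deterministic, homogeneously mixed and demography-free; network, stochastic
and birth–death extensions are out of scope.

## Known limitations

* Feature detection needs the trajectory horizon to contain the feature;
  an asymptotic approach to an endemic equilibrium (e.g. the uncontrolled
  SIS preset) has no interior maximum and is reported as not-found.
* The entropy-error kernel saturates (or overflows) when curve values are
  far from $O(1)$; rescale time so densities are order one before
  comparing sharply peaked epidemics to the reference.
* Cut times are horizon-limited by construction.
* The variational derivation behind the maximum-dissipation width is not
  implemented; only its consequence $\sigma_r = 1/\sqrt{2\eta}$ is, and it
  is verified through the reference geometry it implies.
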