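# epitransient

Entropy-based characterization of epidemic transients in R.

## The problem

Early in an outbreak, two time instants matter most to planners: the time
`D` of the first infection maximum (the peak load on hospitals) and the
preceding inflection time `L`, where interventions first visibly bend the
curve.  `epitransient` is built around a simple unifying idea: any
infection curve obeying the first-order model

    dI/dt = alpha(t) I(t),     alpha(t) = -c * ln(g(t)/E) / h(t)

has its peak where `g` crosses the threshold `E` and — under checkable
conditions on `c`, `g`, `h` — an inflection strictly before it.
Multi-compartment models can be cast into this same form: for SIR,
`alpha(t) = beta*S(t) - gamma`; for an SIS model with vaccination and
treatment feedback controls `V = kV*S`, `T = kT*I`, it is
`alpha(t) = beta*S(t) - gamma - kT`.

With `g(t) = h(t) = t` and `E = D` the model solves in closed form to the
Gibrat-type curve

    I(t) = I_peak * exp(-(c/2) * ln^2(t/D)),      c = (1 - ln(L/D)) / ln^2(L/D),

which is shape-identical to a log-normal density with `sigma^2 = 1/c` and
mode `D`.  That identification motivates a *reference family*: the
unit-mass log-normal whose width is fixed by the principle of maximum
entropy dissipation, `sigma_r = 1/sqrt(2*eta)` for entropy order `eta`
(`0.408` at `eta = 3`, `1/sqrt(2)` at `eta = 1`).  The package measures how
far a simulated epidemic sits from this reference by

* the Shannon-type entropy `S_I(eta) = -eta * int I ln(t^(1-eta) I) dt`,
  its normalized and truncated variants,
* the entropy error against a reference curve, decomposed into a linear
  part and a Newton–Mercator series tail in the pointwise kernel
  `delta(t)`, and
* matched reference parameters: the peak time `D_rm` inverted from the
  normalized entropy, the entropy-matching width `sigma_rm`, and the
  variance-matching width `sigma_rmv`.

Everything is tibble-first and pipe-friendly; fitted matches support
`tidy()`/`glance()`, and trajectories and curves have `autoplot()`
methods.

## Worked example

An above-threshold SIR epidemic (`beta = 13065`, `gamma = 50.1` per year —
a 7.29-day infectious period — with 1% of a unit population initially
infectious):

```r
library(epitransient)

traj <- run_simulate("sir_epidemic")
transient_features(traj)
#> # A tibble: 1 × 6
#>   found_D found_L        D        L   I_D   I_L
#>   <lgl>   <lgl>      <dbl>    <dbl> <dbl> <dbl>
#> 1 TRUE    TRUE    0.000784 0.000352 0.975 0.495

glance(match_reference(traj))
#> # A tibble: 1 × 8
#>          D        L S_In1    D_rm sigma_rm sigma_rmv   var_In variant
#>      <dbl>    <dbl> <dbl>   <dbl>    <dbl>     <dbl>    <dbl> <chr>
#> 1 0.000784 0.000352 -2.91 0.00639     1.55      1.29 0.000398 printed
```

The peak arrives at `D ≈ 0.00078` years (about 7 hours of model time — the
reproduction ratio here is an extreme 258) and infects 97.5% of the
population at its maximum; the inflection happens at `L ≈ 0.00035` years
at roughly half that load.  The matched widths `sigma_rm = 1.55` and
`sigma_rmv = 1.29` sit far from the reference `1/sqrt(2) ≈ 0.707`,
quantifying how strongly the susceptible-infectious coupling distorts this
epidemic away from the first-order log-normal ideal; the gap grows with
the initial susceptible-to-infectious ratio (see the sweep tests).

Presets: `sir_epidemic`, `sir_decay`, `sis_demo`, `sis_no_peak`,
`sis_uncontrolled`, `gibrat_unit` (see `?epi_preset`).  A thin CLI is
installed as `exec/epitransient` with `simulate`, `features` and
`fixtures` commands.

## Acceptance script

`scripts/acceptance.R` recomputes the reference-geometry quantities from
scratch — the maximum-dissipation width at `eta = 3`, and the peak-to-
inflection time and value ratios of the resulting log-normal reference
curve, both located by numerical optimization and root finding on the
curve itself — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
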