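---
title: "Methods: coupled epidemic and trait dynamics behind evodisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled epidemic and trait dynamics behind evodisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`evodisp` studies how a parasite adapting to a heterogeneous host population
changes transmission dispersion — the tendency of a few infections to drive
most new cases. This vignette documents the model, its assumptions, the
numerical choices, and what the package's tests do and do not establish.

## Model structure and assumptions

The host population has exactly two types. High-yield hosts (`H`) give the
parasite high reproductive output (high transmission set point `cH` and/or a
shallow virulence slope `yH`); low-yield hosts (`L`) the converse. This is a
deliberate idealization of the two extremes seen in disease systems —
tolerant, highly infectious hosts versus hosts that suffer badly and
transmit little; real populations also contain intermediate types, which the
model does not represent.

Epidemiology is a susceptible–infected system with demographic turnover:
constant influx `lam` (proportion `p` low-yield), background mortality
`delta`, recovery `gamma`, and mass-action transmission where the rate
depends on the *infecting* host's type and mean trait. There is no latency,
no immunity after recovery, and no demographic stochasticity: the model is a
deterministic ODE system, so every run is exactly reproducible.

The evolving trait is the parasite's mean within-host growth rate in each
host type, `epsH` and `epsL`. The trade-off functions are

* transmission `beta_j(eps) = rho * (c_j + eps^x)`, increasing and concave
  for `x < 1` (all shipped presets use `x = 0.5`; the exponent is restricted
  to `0 < x <= 1`, the range where the trade-off stays concave);
* virulence `alpha_j(eps) = y_j * eps`, linear with no intercept.

Note `beta_j(0) = rho * c_j > 0`: a host with no parasite growth would still
"transmit" at the set-point rate. This is harmless in practice because every
analysis starts from positive trait values and selection never drives the
trait to zero.

Trait dynamics follow the Price equation without mutation: the change in the
mean trait is the trait–fitness covariance within a host type plus terms for
trait values imported by between-type transmission. The covariance is
approximated as `var_j(eps) * (dr/deps)` — standing variance times fitness
gradient — and `var_j(eps)` is **held constant in time**. This is the
central structural assumption: a real polymorphic population's variance
erodes under directional selection, so the approximation is trustworthy only
while variance is roughly stable. The multi-strain oracle (below) makes that
statement quantitative.

## Parameters

| name | meaning | units | default |
|------|---------|-------|---------|
| `cH`, `cL` | transmission set points | – | 1, 0.1 |
| `yH`, `yL` | virulence slopes | per trait per time | 0.1, 1 |
| `x` | trade-off concavity | – | 0.5 |
| `rho` | transmission scaling | per density per time | 0.01 |
| `lam` | susceptible influx | hosts per time | 50 |
| `p` | proportion born low-yield | – | 0.5 |
| `delta` | natural mortality | per time | 0.02 |
| `gamma` | recovery rate | per time | 0.6 |
| `varH`, `varL` | trait variances | trait² | 1, 1 |

Densities and times are in the arbitrary "model units" implied by
`lam/delta` (disease-free total density 2500). Defaults are the package's
baseline scenario; `preset_params()` provides the baseline plus the
quality-gap variants used in the worked examples.

Default initial conditions put susceptibles at the disease-free equilibrium
with a seed of 0.1 infected hosts of each type and both traits at 0.25.
Published analyses of this model family do not fix the seed size; the
package default is small enough that the early epidemic shows the
characteristic abundant-susceptible phase, and it is exposed as an argument
everywhere.

## Dispersion statistic

Parasite fitness is `Re = betaH*sH/(delta+gamma+alphaH) +
betaL*sL/(delta+gamma+alphaL)`; at any endemic equilibrium `Re = 1` exactly,
which the test suite uses as a consistency check. Dispersion is
`vmr = var(Re)/Re` where `var(Re)` weighs each host type's squared deviation
from `Re` by its share of current infections.

Two variants of the per-type value are implemented. The default
(`form = "expanded"`) uses `beta_j*(sH+sL)/(delta+gamma+alpha_j)` — the
reproduction number a type-`j` infection achieves across the whole
susceptible pool. A `form = "compact"` variant uses the type's own
susceptible pool `beta_j*s_j/(...)`. The two differ, and with the expanded
form `Re` equals the infection-weighted mean of the per-type values only
when `sH = sL` *and* `iH = iL`; elsewhere `var(Re)` is a second moment about
`Re` rather than a central variance. The expanded expression is implemented
as the default because it is the fully written-out form; the compact variant
exists for sensitivity analysis.

When no infections remain (total below `1e-10`), `vmr` is reported as 0 with
`vmr_defined = FALSE` rather than erroring, so trajectory annotation never
aborts. A caution on limits: at fixed susceptible densities, emptying one
infected class does *not* send `vmr` to zero — the surviving class still
deviates from `Re` whenever the other type's susceptibles remain. Dispersion
vanishes when a host *type* disappears (its susceptible and infected pools
together), as along the `p -> 1` family of equilibria.

## The multi-strain oracle

`simulate_multistrain()` integrates an explicit N-strain version of the
model: each strain has a fixed trait, its own infected compartments in both
host types, and competes through the shared susceptible pools. The mean
trait of this system is the ground truth the Price equations approximate.

The strain grid discretizes a normal trait distribution truncated to
`(1e-3, mean + 3 sd]` into `N = 41` midpoint cells, each strain carrying its
cell's probability mass. Using cell masses (rather than point densities)
means every `N` targets the *same* continuous distribution; doubling `N`
changes the mean-trait trajectory by about 0.03%, so the default grid is
effectively converged. The truncation inflates the realized mean and
shrinks the variance relative to the nominal normal; `compare_to_price()`
therefore matches moments at `t = 0`, giving the Price run the grid's
empirical means and variances.

Agreement is only expected while the oracle's variance is stable, so the
comparison horizon is capped at the first time either type's empirical
variance drifts more than 20% from its initial value. Under the baseline
scenario that horizon is short (about 0.05 time units — directional
selection erodes variance quickly at the epidemic's outset) and the maximal
relative mean-trait error within it is below 3%. With a linear trade-off
(`x = 1`) the covariance identity is exact and the residual error shrinks to
zero with the horizon, which the property tests verify; with `x = 0.5` the
curvature of `eps^x` across the strain distribution adds a bias the tests
quantify but the Price model cannot remove.

## Numerical choices

* **Integration.** `deSolve::ode` with `lsoda` (stiff-capable, automatic
  method switching), `rtol = 1e-8`, `atol = 1e-10`, both exposed. Halving
  tolerances changes final states by far less than `1e-6` relative (tested).
* **Negative undershoot.** Densities may undershoot zero by roughly the
  solver tolerance; values are clipped to zero, with a warning when the
  undershoot exceeds `atol` and a hard error beyond `1e-6` (which would
  signal a real defect, not roundoff).
* **Adaptive horizons.** When `t_end` is omitted, simulation runs in chunks
  of 500 time units until the scaled right-hand side falls below `1e-8`,
  then reports the full trajectory.
* **Equilibria.** Root-finding (Newton via `pracma::fsolve`, residual
  tolerance `1e-8`) polishes a seed obtained by integrating to near-
  stationarity; the tests verify root-found equilibria against independent
  long integrations to `1e-4` relative. With `p` exactly 0 or 1 the absent
  type's compartments are held at their exact zero solution and the reduced
  system is solved. If the disease-free state has `Re <= 1` or no positive
  root exists, the disease-free equilibrium is returned and flagged.
* **Division-by-zero in the trait equations.** The between-type terms carry
  `iL/iH` and `iH/iL`. When an infected class sits below a floor (`1e-10`),
  its *entire* mean-trait derivative is frozen at zero: the mean trait of an
  absent infection class is undefined, and freezing it avoids both the
  singular ratio and a spurious virulence-driven decay of a trait that no
  infection carries (which matters for single-type populations, `p` = 0
  or 1).
* **Trait positivity.** `eps^(x-1)` diverges as `eps -> 0` for `x < 1`. A
  trait of an *active* class falling to `1e-6` is a hard error rather than a
  silent clamp, since in this model selection should never drive the trait
  to zero — hitting the floor means the scenario is outside the model's
  intended regime.

## Problem sizes

The shipped tests and scans run at deliberately modest sizes chosen for the
package's examples: trajectories of 500–2000 output points, composition
scans over 5–11 values of `p`, quality grids of 2–3 values per axis, the
41-strain oracle, and variance scans over 4 values. All scan drivers are
resolution-agnostic; finer grids simply take proportionally longer.

## Known limitations

* Trait variance is a fixed parameter, not a dynamical variable; long-run
  predictions inherit the Price approximation's blind spot to variance
  erosion and replenishment (there is no mutation term).
* Exactly two host types; no intermediate or continuous host heterogeneity.
* Deterministic dynamics only — the model cannot speak to stochastic
  extinction or individual-level offspring distributions; `vmr(Re)` measures
  between-type dispersion, not the full offspring-variance decomposition,
  and no negative-binomial dispersion parameter is estimated.
* Not every parameter set has a stable endemic equilibrium: with a
  sufficiently steep low-yield virulence slope (e.g. baseline with `yL = 2`)
  the coupled system sustains slow oscillations, and `evo_equilibrium()`
  reports non-convergence rather than returning a point on a cycle.
* At baseline parameters the mean trait surges, peaks early and then relaxes
  monotonically to its equilibrium; dispersion (`vmr`), by contrast, shows
  the characteristic peak–dip–rebound. Whether the *trait* itself dips below
  its equilibrium before rebounding is parameter-dependent and should not be
  treated as a general prediction.
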