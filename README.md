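# stochallee

Simulation and analysis of single-species population dynamics under
environmental stochasticity and Allee effects, built around the stochastic
difference equation

```
X[t+1] = f(X[t], xi[t]) * X[t]
```

where `X[t]` is population density, `f(x, xi)` is fitness as a function of
density and the environmental state, and `xi[t]` is an i.i.d. sequence of
environment draws. The package is for population ecologists and
mathematical biologists studying when such populations persist, go extinct
from every starting density, or persist only conditionally — and how
environmental noise moves populations between those fates.

## What it computes

The growth-relevant average of fitness under multiplicative dynamics is the
**geometric mean** `G(x) = exp(E[log f(x, xi)])`. The package computes `G`
by closed form, Gaussian quadrature, or Monte Carlo, and applies the
criteria that govern the long-run outcome:

* **Negative density dependence** (`f` decreasing in `x`, e.g. stochastic
  Ricker `f = exp(r - a x)`): `G(0) < 1` gives extinction with probability
  one; `G(Inf) > 1` unbounded growth; `G(0) > 1 > G(Inf)` stochastic
  persistence.
* **Positive density dependence** (`f` increasing, e.g. mate limitation
  `f = lambda x / (h + x)` or predator saturation `f = exp(r - P/(h+x))`):
  `G(Inf) < 1` gives unconditional extinction; `G(0) > 1` unbounded
  growth; `G(0) < 1 < G(Inf)` a strong stochastic Allee effect —
  extinction and escape both occur with positive probability.
* **Mixed density dependence** (`f = exp(r - a x) x/(h + x)` and
  relatives): `G(0) > 1` with a decreasing high-density tail gives
  persistence; with `G(0) < 1` the fate depends on the noise. Unbounded
  multiplicative noise forces extinction from everywhere; small compactly
  supported noise defers to the **deterministic skeleton**
  `F0(x) = x f(x, xi_bar)`: with smallest positive fixed point `M` and
  critical point `C`, `F0(F0(C)) > M` gives a positive attractor
  (conditional persistence), `F0(F0(C)) < M` essential extinction.

Monte-Carlo machinery (seeded, bit-reproducible) turns these criteria into
experiments: persistence-probability curves over initial density,
asymptotic-dynamics scatters over noise amplitude or predation intensity,
regime maps over parameter grids, and invariant-interval certificates for
small-noise persistence.

## Worked example

The mate-limitation–Ricker model with growth rate `r` uniform on
`[4, 5]` (competition `a = 1`, half-saturation `h = 10`):

```r
library(stochallee)
m <- build_model("mate_limitation_ricker", params = list(a = 1, h = 10),
                 env = list(r = env_dist("uniform", center = 4.5, halfwidth = 0.5)))

geo_mean_fitness(m, 0)
#> <G(0) = 0  [closed_form, log-scale error 0]>

classify_skeleton(m)
#> <skeleton_report: POSITIVE_ATTRACTOR>
#>   M   = 0.12785545
#>   C   = 1.8442888
#>   F(C)    = 4.0879878
#>   F(F(C)) = 1.7910382
#>   attractor hull = [1.7942, 4.08495]

classify_regime(m)
#> <regime_report: CONDITIONAL_PERSISTENCE>
#>   rule: mixed: G(0) < 1, small compact noise, skeleton has a positive attractor
```

`G(0) = 0` (mate limitation makes fitness vanish at zero density), so
extinction threatens low densities; but the noise-free skeleton has
`F0(F0(C)) = 1.79 > M = 0.128`, a positive attractor, so populations
inside its basin persist under this small noise: a strong Allee effect
with conditional persistence.

Noise can also *help*. For the pure mate-limitation model
(`lambda` lognormal with log-mean 0.1, log-sd 0.5, `h = 10`), whose
deterministic Allee threshold is `h/(lambda - 1) = 95.08`:

```r
persistence_curve(mate_limitation_model(0.5), c(25, 50, 95, 200),
                  T = 1000, n_reps = 1000, threshold = 100, seed = 1)
#>    x0  phat         lo         hi n_reps
#> 1  25 0.034 0.02365865 0.04718944   1000
#> 2  50 0.176 0.15287829 0.20104651   1000
#> 3  95 0.346 0.31650688 0.37640313   1000
#> 4 200 0.592 0.56080532 0.62265142   1000
```

A deterministic population starting at 50 is doomed (`phat = 0`); with
log-sd 0.5 noise it escapes the extinction vortex 17.6% of the time.

A thin CLI wraps the same functions:

```sh
exec/stochallee models
exec/stochallee skeleton --model model.yaml
exec/stochallee figure1 --seed 1 --out out/
```

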