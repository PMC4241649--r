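---
title: "Allee effects under environmental stochasticity: models, criteria, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allee effects under environmental stochasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochallee)
```

## The model

`stochallee` studies scalar stochastic difference equations

$$X_{t+1} = f(X_t, \xi_t)\, X_t,$$

where $X_t \ge 0$ is population density, $f(x, \xi) \ge 0$ is fitness, and
$(\xi_t)$ is an i.i.d. sequence of environment states. Two standing
assumptions shape everything downstream: the environment is *uncorrelated in
time* (so $(X_t)$ is a Markov chain — temporally autocorrelated noise is out
of scope), and $f$ is continuous in both arguments. Zero is absorbing:
an extinct population stays extinct.

The environmental state is a finite-dimensional real vector; each
coordinate fluctuates independently with one of five families
(`point_mass`, `normal`, `lognormal`, `uniform`, `gamma`), composed by
`env_product()`. Which parameters of a fitness form fluctuate and which
are constants is part of the model specification, not hard-coded: the
bundled experiments fluctuate the growth rate $r$ (uniform) or the
predation intensity $P$ (uniform) while holding $a$ and $h$ fixed, but any
placement can be requested.

## The fitness catalogue

| name | $f(x,\xi)$ | density dependence |
|---|---|---|
| `ricker` | $e^{r - a x}$ | negative (decreasing) |
| `beverton_holt` | $a/(1 + b x)$ | negative |
| `mate_limitation` | $\lambda x/(h + x)$ | positive (increasing) |
| `predator_saturation` | $e^{r - P/(h + x)}$ | positive |
| `mate_limitation_ricker` | $e^{r - a x}\, x/(h + x)$ | mixed |
| `predator_saturation_ricker` | $e^{r - a x - P/(h + x)}$ | mixed |
| `liebhold_bascompte` | $e^{\gamma(x - C) + \xi}$ | positive |

Here $h$ is a half-saturation constant (the male density at which half the
females find a mate, or the prey density at which predation is half
saturated), $\lambda$ the number of daughters per mated female, $r$ the
intrinsic growth rate, $P$ the predation intensity, and $a$ the strength of
intraspecific competition.

The `liebhold_bascompte` form deserves a caveat: it is a *reconstruction*
from the qualitative properties its originators rely on — fitness
increasing in density, a deterministic Allee threshold $C$ at which fitness
crosses one, additive mean-zero normal noise on the log scale, hence
$G(0) < 1 < G(\infty)$. The cited source's exact algebraic form was not
available when this package was written; the form here reproduces those
properties and is intended for qualitative use only.

## Geometric-mean fitness and the regime criteria

Under multiplicative dynamics the right average of fitness is geometric:

$$G(x) = \exp\!\big(E[\log f(x, \xi)]\big).$$

An Allee effect is *weak* when $G(0) > 1$ (the population still replaces
itself at vanishing density) and *strong* when $G(0) < 1$. Because
$G(0) \ne f(0, \bar\xi)$ in general, fluctuations alone can push a weak
Allee effect across the line into a strong one; `jensen_gap()` quantifies
the arithmetic–geometric gap responsible. For example, a predator whose
half-saturation constant $h_t$ fluctuates log-normally depresses
$G(0) = \exp(r - P\,E[1/h_t])$ below the fitness at the mean environment,
since $E[1/h_t] > 1/E[h_t]$.

`classify_regime()` applies the decision rules:

* **decreasing $f$** — trichotomy: $G(0) < 1$ unconditional extinction;
  $G(\infty) > 1$ unbounded growth; $G(0) > 1 > G(\infty)$ stochastic
  persistence (the trajectory spends arbitrarily little long-run time near
  zero, from every positive start).
* **increasing $f$** — trichotomy: $G(\infty) < 1$ unconditional
  extinction; $G(0) > 1$ unbounded growth; $G(0) < 1 < G(\infty)$
  conditional persistence: extinction with positive probability for low
  starts, escape with positive probability, with the extinction
  probability tending to 1 as $x_0 \to 0$ and to 0 as $x_0 \to \infty$.
* **mixed $f$** — $G(0) > 1$ together with a pivot $x_c$ beyond which $f$
  decreases for every environment and the tail geometric mean falls below
  one gives stochastic persistence. With $G(0) < 1$ the noise decides:
  if the fitness factors as $\xi\,g(x)$ with a lognormal/gamma factor
  (so one step can shrink the log density by any amount) and $x f(x)$ is
  bounded, extinction is *accessible* from everywhere and occurs with
  probability one; if instead the noise has small compact support, the
  deterministic skeleton decides (next section).

Numerical choices embedded in the classifier:

* $G(\infty)$ uses the model's declared high-density fitness limit when
  one exists; otherwise $G$ is evaluated at $10^6$ and $10^8$ and the two
  must agree, else the verdict is `INDETERMINATE`.
* Any criterion within numerical error of $G = 1$ — specifically
  $|\log G| \le \max(3 \cdot \text{error}, 10^{-6})$ — yields
  `INDETERMINATE`: classification at criticality is statistically
  meaningless.
* The mixed-case persistence check uses the *sufficient* form of the tail
  condition (decreasing tail with tail geometric mean below one), not the
  sharpest integral condition; the pivot $x_c$ is located on a grid as the
  smallest density beyond which no sampled environment's fitness
  increases. The grid must cover the model's turning point; that is the
  caller's responsibility and the reports carry the grid used.
* The boundedness of $x f(x, \bar\xi)$ is a grid heuristic (log–log tail
  slope below 0.5 over four decades past the analysis window), reported
  as such, never a proof.

The formal notions behind these rules — accessibility of the extinction
set, invariance — are represented in the package only through their
sufficient conditions and through the Monte-Carlo probe
`min_density_probe()` ($P[\min_{t \le T} X_t \le \gamma]$); nothing here
is proof-grade.

## The deterministic skeleton and small noise

The skeleton is the noise-free map $F_0(x) = x f(x, \bar\xi)$ at the
*coordinatewise mean* environment $\bar\xi$. For the uniform noise
families used by the bundled experiments the mean is the natural center of
the noise interval; other reference environments can be had by building a
point-mass model. With smallest positive fixed point $M$ and critical
point $C$ (the maximizer of $F_0$, assumed and verified unimodal):

* $f(0, \bar\xi) > 1$: a positive attractor whose basin is every positive
  density (no Allee threshold);
* $f(x, \bar\xi) < 1$ for all $x$: global extinction;
* otherwise $F_0(F_0(C)) > M$ gives a positive attractor in $(M, \infty)$,
  and $F_0(F_0(C)) < M$ essential extinction — almost every initial
  density goes extinct despite infinitely many unstable positive periodic
  orbits (which the package makes no attempt to enumerate).

Root and maximum finding use log-spaced bracketing grids refined by
bisection; the critical point is additionally refined through the sign
change of a central-difference derivative because golden-section search
stalls at square-root-of-machine-epsilon accuracy on a flat maximum. A
`BOUNDARY` verdict is returned when $|F_0(F_0(C)) - M| \le 10^{-8}
\max(1, M)$. The default analysis window is $x \le 50$, which contains
the dynamics of every catalogue skeleton; it is configurable.

Under *small compact* noise the skeleton's verdict transfers to the
stochastic system in both directions, and the package corroborates each
numerically:

* a positive attractor yields a positive invariant set:
  `invariant_interval()` searches for $[\alpha, \beta]$ containing the
  attractor hull with $F(x, \xi) \in [\alpha, \beta]$ for every grid
  density and every corner of the noise support box (corners bound $F$
  because every catalogue fitness is monotone in each environmental
  coordinate). The certificate is a numerical invariance check on a
  4000-point grid, not interval arithmetic; absence of a certificate is
  reported as `NULL`, never as a claim of non-existence.
* no positive attractor plus the low-density assumptions (strong
  stochastic Allee effect at zero, fitness increasing near zero) plus
  numerically confirmed dissipativity forces extinction from every start:
  `small_noise_extinction_check()`. The theory guarantees a noise size
  below which this holds but not a computable bound for it, so the
  package reports, for the noise actually supplied, which conclusion the
  simulations support rather than computing a critical noise width.

## The experiments

Three ensemble protocols probe the regimes numerically; their defaults are
the package's study conditions.

**Persistence curves** (`run_figure1`): mate limitation, $\lambda$
lognormal with log-mean 0.1 and log-sd $\sigma \in \{0, 0.25, 0.5, 1\}$,
$h = 10$, persistence judged by final density above 100 after $T = 1000$
steps (the full-size protocol uses 10,000 replicates; the default here
is 1,000, and the curves are insensitive to doubling $T$ — a test asserts
this). The $\sigma = 0$ curve is a step at the deterministic Allee
threshold $h/(\lambda - 1) \approx 95.08$; noise makes the curve sigmoidal
and lifts persistence below the threshold. Two honest caveats found while
validating: the lift is *not* strictly ordered in $\sigma$ everywhere
(between log-sd 0.5 and 1.0 at $x_0 = 50$ the persistence probability
plateaus near 0.18, and just below the threshold the ordering reverses),
and saturation toward 1 is slow at large $\sigma$ — strong noise keeps
a non-trivial extinction risk even for high starts (from $x_0 = 10^4$
with $\sigma = 0.5$ about 2.4% of runs still go extinct, in quantitative
agreement with the ruin probability $e^{-2\mu d/\sigma^2} \approx 0.024$
of the high-density log-scale random walk).

**Noise-amplitude scatter** (`run_figure2`): mate-limitation–Ricker with
$r$ uniform on $[4.5 - \varepsilon, 4.5 + \varepsilon]$, $a = 1$,
$h = 10$ (the half-saturation matches the persistence-curve experiment
and is configurable). One
trajectory per initial density, last 1,000 of 10,000 points kept. Small
$\varepsilon$ confines orbits to the skeleton attractor; $\varepsilon$
near 4.5 extinguishes everything.

**Predation scatter** (`run_figure3`): predator-saturation–Ricker
$\exp(4 - 4x - P_t/(1/12 + x))$ with $P$ uniform on
$\bar P[1 - \varepsilon, 1 + \varepsilon]$. The defaults
$\varepsilon = 0.2$ and $\bar P$ grid
$\{0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.85, 1.0\}$ were chosen from the
skeleton analysis before any stochastic runs: $f(0, \bar\xi) > 1$ for
$\bar P < 1/3$ (persistence from every start, since
$G(0) = e^{4 - 12\bar P}$), a positive attractor up to $\bar P \approx
1.1$, global extinction beyond — so the grid straddles all three
deterministic regimes. At $\varepsilon = 0.2$ the stochastic ensembles
show the striking non-monotone pattern: every start dies for
$\bar P \in [0.35, 0.6]$ while conditional persistence returns at
$\bar P \ge 0.7$. The persisting starts at high $\bar P$ sit inside the
attractor basin (around densities 0.5–1); *high* starts crash through
overcompensation, so "persistence at higher predation" means persistence
from some start, which is what conditional persistence asserts. Default
starts are $\{0.05, 0.5, 2, 5\}$; the generic scatter default is a
geometric grid of 8 points on $[10^{-2}, 10]$, recorded in the output
metadata.

## Randomness, reproducibility, and numerics

* Every stochastic operation takes an explicit integer seed; nothing
  touches or depends on the caller's RNG state. Internally the
  L'Ecuyer-CMRG generator is used, and replicated operations (one
  ensemble per grid point) draw independent substreams spawned with
  `parallel::nextRNGStream()`, so ensembles never share or overlap
  streams. Fixed seed means bit-identical output, which the suite
  asserts across every exported stochastic operation.
* Expectations: Gauss–Legendre on bounded supports, Gauss–Hermite for
  normal coordinates (and for lognormal on the log scale, where the
  integrand templates are polynomial and the rules are exact),
  generalized Gauss–Laguerre for gamma; 128 nodes per coordinate by
  default, tensorized over product environments. The reported quadrature
  error is a node-increase difference; Monte-Carlo estimates report a
  standard error. Requesting a closed form that is not registered is an
  error, never a silent fallback.
* $E[\log f] = -\infty$ (mate limitation at $x = 0$) propagates as
  $G = 0$ rather than raising.
* Densities evolve in linear scale with clamp-to-zero below $10^{-300}$
  (clamp counts are recorded); trajectories that overflow are absorbed at
  `Inf` and classified as explosions. Run classification uses the final
  density only (cutoffs $10^{-8}$ and $10^{8}$, always reported),
  mirroring the final-density protocol of the persistence curves; it is a
  finite-horizon proxy for the asymptotic limits, never an exact
  computation of them.

## What the simulations do and do not show

The synthetic ensembles realize exactly the model assumptions: i.i.d.
environments, scalar density, no demographic stochasticity, no spatial or
stage structure, infinite-precision densities (apart from underflow).
Passing tests therefore validate the implementation of this theory, not
the theory's fit to field data: real populations experience
autocorrelated environments, integer-valued small-population effects, and
finite-time extinction, none of which are modeled here. Quasi-stationary
behaviour, structured populations, and continuous-time analogues are
explicitly out of scope.

Problem sizes in the shipped tests are scaled for a single CPU: ensembles
of 200–1000 runs over horizons of 2,000–10,000 steps, one 100-run ensemble
of $10^5$ steps for invariant-interval soundness, and scatter grids of 8
parameter values; the full-size protocols (10,000 replicates, 10,000-step
scatters) are available through the exported functions' arguments.
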