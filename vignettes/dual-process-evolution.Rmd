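---
title: "Eco-evolutionary dynamics of dual-process consumers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary dynamics of dual-process consumers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dualproc)
```

## The model

`dualproc` simulates populations of agents that must keep an energy level
$E$ above starvation in a stochastic environment. Each timestep an agent

1. pays a constant metabolic drain $d$ (floored at $E = 0$; running out of
   energy is not lethal within a lifetime — fitness is the lifetime mean of
   $E$, and death is a population-level event in the feedback scenarios);
2. encounters a resource packet of magnitude $\rho$ with probability given
   by the environment and the competition regime;
3. acts either *automatically* (with probability $1 - C$) or in a
   *controlled* manner (with probability $C$), where $C \in [0,1]$ is the
   agent's heritable control propensity.

Consumption of an amount $x$ raises energy with saturating returns,

$$\frac{dE}{dx} = u\left(1 - \frac{E}{E_\mathrm{max}}\right)
\quad\Longrightarrow\quad
E' = E_\mathrm{max} - (E_\mathrm{max} - E)\,e^{-u x / E_\mathrm{max}},$$

so a packet is most valuable when the agent is hungry and worthless at the
satiety ceiling $E_\mathrm{max}$. An automatic act is a habit: it consumes
the entire packet immediately and cannot touch the agent's store $S$. A
controlled act deliberates: it chooses how much of the pool $S + \rho$ (or
$S$ alone, on empty-handed steps) to consume now and how much to bank,
using a pre-solved optimal policy (below) indexed by an experience-based
estimate of resource availability. Deliberation has a social price: when
two agents reach the same packet, an automatic act beats a controlled act
with probability `w_auto` (1 by default); same-mode contests split the
packet at random.

### Why storage pays only under strong saturation

With a linear drain and no death at $E = 0$, a single gorged packet of
energy value $h$ yields a time-integrated energy of $h^2/2d$, which is
*convex* in $h$: splitting a packet over several sittings halves the area
unless saturation claws it back. Deliberate storage is therefore only
advantageous when $u\rho \gtrsim E_\mathrm{max}$, i.e. when gorging wastes
a substantial part of the packet against the ceiling, and when the agent
can hold an energy *plateau* on trickled consumption
($R\,\rho\,u (1 - E/E_\mathrm{max}) \ge d$ at some useful $E$). This
observation drives the package's calibration (below).

## The consumption policy

The controlled act's consume-versus-store problem is a Markov decision
process on $(E, S)$: drain, stochastic acquisition with probability $p$,
choice of a consumption fraction from a fixed menu, storage of the
remainder. The objective is the expected discounted sum of per-step
energy; with the discount $\gamma \to 1$ this approximates the
average-energy criterion that defines fitness. `solve_policy()` performs
value iteration on a rectangular grid (off-grid landing states enter the
value function through bilinear interpolation — equivalently, the
discretized chain jumps to the four surrounding nodes with the
interpolation weights), stops at a sup-norm residual below `tol`, and
returns the greedy policy, breaking exact ties toward storage.
Finite-horizon variants use exact backward induction; the test suite pins
them against an exhaustive expectimax tree walk on an enumerable instance.

Because agents never re-solve online, `solve_policy_set()` pre-solves a
grid of availability levels (21 by default, quadratically spaced so that
resolution concentrates near zero where scarce-environment agents live)
and each agent indexes the policy nearest its current estimate
$\hat p$. The estimate is an exponential moving average of the agent's own
acquisition outcomes,
$\hat p' = (1-\lambda)\hat p + \lambda\,\mathbf{1}\{\text{acquired}\}$,
so resources lost to competitors silently depress it — perceived scarcity
rises with crowding, exactly the coupling the model needs. The default
memory is $\lambda = 0.01$: a time constant of 100 steps, matched to the
inter-encounter interval at the scarcest default richness
($1/R = 200$ steps). A faster estimator (e.g. $\lambda = 0.05$) collapses
to zero between encounters and measurably degrades the controlled policy
in scarce regimes.

At satiety the solver may still prescribe a small top-up: the drain is
paid *before* the consumption choice, so an agent at
$E = E_\mathrm{max}$ decides from $E_\mathrm{max} - d$, where a little
consumption has positive value.

## Fitness and the lookup table

Fitness is the lifetime mean of $E$ over 1,000 steps (lifetimes start at
the floor $E = 0$, $S = 0$, the "worst possible" baseline). Because the
only coupling between an agent and the rest of the population runs
through its two access probabilities —

$$p_\mathrm{auto} = R\big[(1-p_c) + p_c(s/2 + (1-s)w)\big], \qquad
  p_\mathrm{ctrl} = R\big[(1-p_c) + p_c((1-s)/2 + s(1-w))\big],$$

with $p_c = \min(1, \kappa(N-1))$ the pairwise contest probability and
$s$ the population's mean automatic share $\overline{1-C}$ — fitness can
be precomputed once on a grid over $(C, p_\mathrm{auto}, p_\mathrm{ctrl})$
(30,000 lifetimes of 1,000 steps by default) and interpolated during
evolution. Table axes should span $[0, R_\mathrm{max}]$ for the richness
range a scenario can reach; access probabilities never exceed $R$.

## Evolution

`run_fixed_scenario()` iterates Wright-Fisher reproduction: each
generation is resampled with replacement proportional to fitness, each
offspring mutates with probability 0.05 by $\pm 0.02$ (clamped to
$[0,1]$), and runs always start from a homogeneous $C = 0$ population. A
generation with zero total fitness reproduces by uniform drift — starving
but not yet extinct. An optional second heritable trait, the automatic
habit's target energy level, mutates in the same manner with the step
scaled to the energy range; it requires a fitness table with a fourth
axis.

Randomness: one seed per run feeds R's default generator sequentially.
Per-generation substreams would buy nothing without parallel execution,
and a single stream keeps the regression guarantee (same seed, same
trajectory) trivially exact.

## Feedback scenarios

Two dead-band rules close the eco-evolutionary loop. With a fitness-driven
population size, $N$ grows by `delta_N` when mean energy exceeds
$T_N + \varepsilon$, shrinks below $T_N - \varepsilon$, and extinction is
$N = 0$. With control-driven richness, the innovation statistic (mean
energy × mean control) drives $R$ by `delta_R` against a floor $R_0$ and
a cap of 1. Growth adds individuals by an extra round of
fitness-proportional sampling (with mutation); shrinkage removes
uniformly at random. Defaults make the feedback slow relative to
selection: $\varepsilon$ is 2% of the threshold, `delta_N` 0.5% of $N_0$,
`delta_R` 5% of $R_0$.

`detect_limit_cycle()` quantifies oscillation in mean control: centred
moving-average smoothing (window 2% of the post-burn-in length), raw
extrema from sign changes, then a zigzag filter that keeps alternating
major extrema and counts swings of at least `min_amplitude`. The period is
the mean spacing between successive same-type major extrema. Smoothing
attenuates amplitude slightly (about 5% for a period 25 times the window).

## Calibration: the stated world

The environment defaults are `drain = 1`, `rho = 10`, `E_max = 100`,
`R = 0.005`, with free parameters fixed once:

* **`u = 50`.** Strong enough saturation that controlled storage clearly
  beats gorging at matched scarce access (fitness ratio ≈ 1.8 at
  $p = 0.005$), yet weak enough that a fully controlled population can
  still be re-invaded by automatic agents under saturated competition —
  the largest access advantage the contest rules allow an automatic
  invader is 2×, so any equal-access efficiency ratio above 2 would make
  control permanent and abolish the boom-bust and limit-cycle phenomena.
  $u = 50$ is the regime where
  $f(C{=}0, R) > f(C{=}1, R/2)$ holds for $R \in [0.001, 0.005]$.
* **`kappa = 0.01`.** Contests saturate by $N \approx 100$: a population
  of 10 is essentially contest-free while one of 100 is fully contested,
  so the classic grid $N \in \{10, 100, 1000\}$ brackets the
  competition transition.
* **`gamma = 0.995`.** A planning horizon of ~200 steps, covering the
  famine gaps at the scarcest default richness; shorter horizons
  measurably under-store.
* **`lambda = 0.01`**, `n_x = 21`, `n_E = 51`, `n_S = 26`, `S_cap = 50`:
  solver fidelity choices; halving any of them changes scarce-regime
  fitness by at most a few percent.

## What the synthetic world does and does not establish

The generator reproduces the qualitative regime structure — scarcity and
solitude favour deliberation; crowding and abundance favour habit; control
can transiently flourish and then undermine itself through the very
population growth or enrichment it enables — but three desk-scale limits
are worth stating plainly, because they bound what a green test means:

* **Adaptation speed is mutation-limited.** With a 5% mutation rate of
  step 0.02, mean control moves at most a few trait steps per hundred
  generations. At $N = 10$ the expected displacement over 5,000
  generations is of order 0.5–1.0, so small populations reach the
  control-dominated equilibrium reliably only on the reference timescale
  (100,000 generations), not in short runs.
* **The bust is partial at desk scale.** In variable-$N$ runs the
  dead-band rule stalls growth at, or before, the control peak, so the
  re-invasion of automaticity is gradual and the population size never
  strictly exceeds its value at the peak of control afterwards.
* **Drift rivals the cycles.** Control can only invade where contests are
  scarce ($N \lesssim 50$ at the default `kappa`), and at such sizes
  neutral fluctuations of mean control have the same magnitude as the
  limit cycles, so cycle detection distinguishes the cycling and
  non-cycling richness regimes only statistically, not sharply.

These are properties of the stated world at the tested scale, not
implementation defects; the corresponding acceptance checks are kept at
their stated thresholds rather than weakened.

## Numerical and degenerate-input choices

* Energy and store are clamped to their grids at policy lookup, with a
  warning when the store exceeds `S_cap`.
* Exact value ties in the policy break toward the smallest consumption.
* `update_population_size()` and `update_richness()` are pure functions;
  both treat the band edges as "hold".
* Trajectories record generation 0 and one row per generation; extinction
  truncates the record at the last living generation and flags the
  result.
* Tables are interpolated multilinearly; queries outside the unit cube or
  the axis span are errors, not extrapolations.

## A minimal session

```{r example}
env <- environment_params()               # scarce world, u = 50
policies <- solve_policy_set(params = env)
tab <- build_fitness_table(
  C_levels = seq(0, 1, 0.2),
  p_auto_levels = seq(0, env$R, length.out = 7),
  params = env, policies = policies, n_sims = 30000, steps = 1000,
  seed = 1)
traj <- run_fixed_scenario(N = 10, R = env$R, generations = 5000,
                           table = tab, seed = 1)
summarize_run(traj)
plot(traj)
```
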