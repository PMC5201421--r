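---
title: "Modelling dendritic cargo transport with sushibelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dendritic cargo transport with sushibelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sushibelt)
library(dplyr)
```

## The model

Neurons move mRNAs, receptors and other cargo from the soma into dendritic
arbors on microtubules, pulled simultaneously by kinesin (anterograde) and
dynein (retrograde) motors. The "sushi belt" picture holds that cargo
circulates bidirectionally and is captured locally wherever a synapse or
compartment signals demand. `sushibelt` implements this picture at two
levels.

**Single particles.** A cargo particle steps $-1$, $0$ or $+1$ lattice
sites per timestep with base probabilities $(p_-, p_0, p_+)$. A memory
parameter $k \in [0, 1]$ linearly mixes the base distribution with a point
mass on the previous step,
$$p(v' \mid v) = (1 - k)\, p_{v'} + k\, [v' = v],$$
so $k = 0$ is a memoryless biased walk and $k \to 1$ produces the long
unidirectional runs seen in tracking experiments. With the default
1 µm / 1 s lattice and $(0.2, 0.35, 0.45)$, the drift is
$p_+ - p_- = 0.25$ µm/s $= 15$ µm/min, a typical microtubule transport
speed.

**Bulk cargo.** For many independent particles, the concentration obeys a
mass-action chain on a compartmentalised morphology:
$$u_1 \underset{b_1}{\overset{a_1}{\rightleftharpoons}} u_2
      \underset{b_2}{\overset{a_2}{\rightleftharpoons}} \cdots, \qquad
  u_i \xrightarrow{\;c_i\;} u_i^{\ast}, \qquad
  u_i^{\ast} \xrightarrow{\;d_i\;} u_i,$$
where $u_i$ is cargo on the microtubules, $u_i^{\ast}$ delivered
(detached) cargo, $a_e, b_e$ per-edge trafficking rates, and $c_i, d_i$
detachment and reattachment rates. The generator of this linear system is
a Hines-patterned sparse matrix whose columns sum to zero (mass
conservation); degradation is deliberately omitted, so total mass is an
invariant that the test-suite checks to $10^{-8}$ relative.

Moment matching connects the two levels: the drift and diffusion of the
memoryless walk give
$$a = \tfrac{1}{2}\left(2 p_+ - (p_+ - p_-)^2\right), \qquad
  b = \tfrac{1}{2}\left(2 p_- - (p_+ - p_-)^2\right),$$
which `walk_analytic_rates()` evaluates and `fit_walk()` recovers from
simulated ensembles by regressing the ensemble mean and variance of
position on time (both through the origin, since all particles start at
one point).

### Walk calibration conditions

Two calibration choices deserve explanation because they change the
fitted numbers appreciably.

* **Boundary.** `simulate_walk()` supports a free (infinite-cable) walk
  and a *reflecting* walk bounded below at the soma end ($x \ge 0$, the
  physically sensible picture for cargo released at the soma into a
  neurite; a suppressed step also resets the run memory). The package's
  calibration examples use the reflecting walk.
* **Fit window.** For memoryless walks the position moments are linear in
  time from the first step, and a long window (600 s) recovers the closed
  form to well under 5 %. For run walks ($k > 0$) the position variance is
  *not* asymptotically linear over short windows, and the effective rates
  depend on the observation window; the package standardises on a 100 s
  window for run-length fits, which is the window over which the
  mass-action approximation is customarily judged. Under these conditions
  the $k = 0.5$ walk fits to $a \approx 0.79\ \mathrm{s^{-1}}$,
  $b \approx 0.54\ \mathrm{s^{-1}}$, versus $0.42 / 0.17$ without runs:
  runs roughly double the effective diffusion coefficient while leaving
  the drift unchanged.

## Steady states, delivery, and timescales

With detachment off, the trafficking steady state satisfies the local
balance $u_p / u_c = b / a$ on every edge; `steady_state()` builds it by
the exact ratio recursion from the root (on a log scale, because tuned
bias profiles span many decades) and normalises to the initial mass. With
reversible detachment the pools additionally balance compartment-wise,
$u_i^{\ast} / u_i = c_i / d_i$. Irreversible systems ($d = 0$) deliver all
mass eventually; the delivered distribution has the closed form
$\mathrm{delivered}_i = c_i\,[-M^{-1} u(0)]_i$ with $M$ the bound-block
generator, which `delivered_distribution()` solves sparsely.

Exact time courses use the matrix exponential stepped between the points
of a logarithmic grid. Two numerical notes:

* For irreversible systems the full $2N$ generator is *defective* (its
  zero eigenvalue has multiplicity $N$), and for strongly biased cables
  the eigenvector matrix is catastrophically ill-conditioned, so
  `evolve_transport()` never eigendecomposes: it uses scaling-and-squaring
  `Matrix::expm()` on the bound block and accumulates the detached pool
  through the exact integral $c \odot M^{-1}(u(t) - u(0))$.
* Values more negative than $-10^{-10}$ of the total mass abort with an
  error; smaller negatives are clipped to zero.

The relaxation timescale of a trafficking system is $1/|\lambda_2|$ from
the generator spectrum (`convergence_timescale()`); the suite verifies it
against directly simulated relaxation within 20 %. A demand profile that
approaches zero anywhere throttles DDT trafficking through that region (a
*transport bottleneck*): in the three-compartment fixture
`bottleneck_system(eps)` the timescale grows as $1/\epsilon$ without
bound, which is why `demand_profile()` floors zero demand at
$\epsilon_{\mathrm{rel}} = 10^{-3}$ of the smallest nonzero demand for
trafficking-based strategies — a hard zero must be an explicit user
choice.

## Demand-driven strategies

Given a normalised demand profile $\tilde u^{\ast}$:

* **DDT** (`ddt_system()`): demand sets the edge ratios,
  $b/a = \tilde u^{\ast}_p / \tilde u^{\ast}_c$, detachment is uniform.
  The microtubule distribution itself converges to demand and then
  transfers unchanged.
* **DDD** (`ddd_system()`): trafficking uniform ($a = b$), detachment
  proportional to demand, $c_i = c_{\max} \tilde u^{\ast}_i / \max
  \tilde u^{\ast}$. Zero-demand compartments get $c_i = 0$ exactly, so
  DDD tolerates hard zeros and avoids bottlenecks.
* **Mixtures** (`mixed_system()`): trafficking targets
  $F \tilde u^{\ast}_i + (1 - F)/N$ and detachment is proportional to
  demand over that mixture; $F = 1$ and $F = 0$ reproduce DDT and DDD
  exactly (asserted, not approximately, in the tests).

Two rate normalisations are provided. `"unit"` sets $a + b = 1$ per edge,
the convention used for morphology-independent timescale comparisons.
`"physical"` (default) sets $a_e + b_e = 2D/\Delta_e^2$ for midpoint
spacing $\Delta_e$, so the local diffusion coefficient is $D$ everywhere
(`scale_rates_to_geometry()`); the default $D = 10\ \mathrm{µm^2 s^{-1}}$
is a deliberately optimistic experimental estimate, so the delay
predictions below are lower bounds in spirit. Under this scaling the
model is invariant to how finely the cable is compartmentalised,
*provided* demand is attached to fixed stretches of cable rather than to
single compartments — a per-molecule detachment rate on a compartment
that shrinks with resolution is a vanishing sink. The suite checks both
the delivered distribution (< 2 % change) and the 90 %-delivery time
(< 10 % change) across a tenfold resolution change with 8 µm hotspot
stretches.

`tuned_bias_rates()` implements the fine-tuned anterograde profile
$a_i = R/2 + \beta (N - 1 - i)/(N - 2)$ (soma edge $i = 1$), which keeps
$a + b$ — and hence $D$ — fixed while adding a drift that decays linearly
with distance; $\beta < R/2$ is required so no retrograde rate goes
negative. `demand_from_signal()` maps a local biochemical signal (for
example calcium) through a monotone trafficking-arrest function $f$ to
the implied demand $\tilde u_i \propto 1/f(s_i)$.

## Tradeoffs

`tradeoff_sweep()` rebuilds a strategy across a parameter grid and
records, per operating point, the mean percent error of the delivered
distribution, the delivery or convergence time, and the steady-state
excess (in-transit) fraction. Error is averaged over nonzero-demand
compartments after normalising both vectors to unit mass
(`mean_percent_error()`); delivery speed defaults to the time to detach
95 % of cargo for irreversible systems and to the time to stay within
10 % mean error for reversible ones.

On the reference cable (100 compartments, 800 µm, $D = 10$, six even
hotspots) the acceptance suite reproduces the headline severity of the
speed-precision tradeoff: the detachment scale that achieves 10 % mean
error needs more than a day to deliver 95 % of cargo, and the 1 % scale
needs more than a week, while a grid-searched tuned-bias model reaches a
few percent error within 200 minutes — at the price of fragility, since
its across-pattern error spread is far larger than the untuned model's
(checked over ten seeded random hotspot patterns).

For reversible systems the package exposes a clean structural fact that
emerged from the exact solutions: along a reattachment sweep at any fixed
detachment scale, both the diffusive-trap slowdown and the steady-state
pool ratio scale with $\bar c / d$, so the product
$t_{\mathrm{conv}} \times \mathrm{excess}$ is approximately the
trafficking-only relaxation floor of the cable (about 5 h for the
reference cable at 10 % tolerance). Efficient operating points
(< 10 % excess) therefore converge only over multiple days, and the
convergence floor is reached only as essentially all cargo stays in
transit.

## The synthetic generators, and what passing tests do not show

`demand_hotspots()`, `demand_bottleneck()`, `demand_linear_gradient()`
and the SWC builders in the test helpers generate every fixture the suite
uses; nothing is downloaded. The hotspot convention is a centred grid
(`round((j + 1/2) N / n)`), chosen to give interior, symmetric sites.
Demand is per compartment by default; pass length-weighted demand (as the
morphology comparisons do) when "spatially uniform" should mean per µm.

These generators emulate the *spatial structure* of demand, not its
biology: demand is static, noiseless and known exactly, cargo particles
do not interact, low-copy-number fluctuations enter only through the
analytic binomial formula (`occupancy_cv()`), and degradation is absent.
Passing tests therefore bound what idealised local-signal trafficking can
achieve; real systems with noisy, delayed demand signals can only do
worse, which strengthens rather than weakens the delay conclusions.

The morphology comparison uses synthetic stand-ins (a compact
four-dendrite stellate cell versus a deep binary arbor with ~5 mm of
cable), built in code and labelled synthetic; reconstructed cells from
public archives can be analysed by pointing `read_swc()` at the
downloaded file and resampling with `resample_tree()` — spacing near 1 µm
reproduces the continuum limit, and coarser spacings are safe under the
physical normalisation.

## Problem sizes and defaults

The suite and the acceptance script run on: walk ensembles of 1000-10000
particles for 100-600 steps; cables of 30-1000 compartments; random trees
up to 60 compartments for the oracle comparisons (explicit RK4
integration at $10^{-6}$ relative agreement); and tradeoff sweeps of 6-16
operating points with 40-72 point logarithmic time grids. Time grids
default to 64 logarithmic points. These sizes were chosen as the smallest
at which every quantity of interest is converged (doubling any of them
changes no reported number at the tolerances used).
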