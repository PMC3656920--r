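---
title: "Spatial Moran dynamics with a diffusible public good: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial Moran dynamics with a diffusible public good: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranpg)
```

## The model

`moranpg` simulates competition between resource **producers** (P) and
**nonproducers** (NP) on a fully occupied `L x L` square lattice with
periodic boundaries. Cooperation is *non-local*: producers secrete a
diffusible resource that raises the growth rate of every cell near them,
producers and cheaters alike. The package exists to ask a population-
genetics question — does sharing a diffusible good create balancing
selection, and with it stable coexistence of producers and cheaters? — and
to provide the controls (a neutral model and a cross-feeding mutualism
model) needed to interpret the answer.

### Growth laws

Every cell has basal growth rate $g_0$; producers pay a production cost
$\kappa$ and everyone gains a benefit proportional to the local resource
concentration $c(\vec x)$:

$$ g_{NP}(\vec x) = g_0 + \alpha\, c(\vec x), \qquad
   g_{P}(\vec x) = g_0 - \kappa + \alpha\, c(\vec x). $$

The benefit enters additively. A multiplicative form at the default cost
$\kappa = g_0$ would pin producer growth at zero for all concentrations and
could never produce producer dominance at short diffusion lengths, so the
additive form is the only self-consistent reading; it also makes "one unit
of resource speeds growth $\alpha$-fold over basal" literally true.

The cost is capped at $g_0$ so that producer growth is never negative even
with no resource; $\kappa = g_0$ (the default) is the largest admissible
cost and hence the strongest test for coexistence — a smaller cost only
makes the two types more similar.

### The resource field

Each producer emits flux $p$; the resource diffuses (constant $D$) and
decays/is consumed at rate $\gamma$, uniform because every site holds a
cell:

$$ p\,\mathbf 1_{P}(\vec x) + D \nabla^2 c - \gamma c = 0, $$

with the 5-point discrete Laplacian at spacing $\Delta x = 1$ cell length.
Cell division (tens of minutes for bacteria) is far slower than diffusive
relaxation (seconds to minutes for a protein in a biofilm matrix), so the
field is always at steady state and only the combination
$\lambda = \sqrt{D/\gamma}$ — the diffusion length, in cell lengths —
matters. The package fixes $p = \gamma = 1$ by default, leaving $\lambda$
and $\alpha$ as the physical dials.

`steady_state_field()` solves the screened-diffusion problem **exactly** by
diagonalizing the operator on the torus (2-d FFT); the field of an
arbitrary producer set is the circular convolution of the producer
indicator with the single-source kernel. After each replacement the field
is updated by adding or subtracting one translated kernel
(`update_field_incremental()`), which is algebraically identical to a fresh
solve — the test suite holds the drift after $10^3$ events below
$10^{-9}$, and in practice it stays near machine precision for millions of
events. A direct sparse solve (`steady_state_field_direct()`, via
**Matrix**) is kept as an independent cross-check, and the unit tests add a
third, dense base-R solve at tiny `L`.

Two exact identities anchor the solver tests: flux balance,
$\sum_{\vec x} \gamma c = p\,n_P$, and translation invariance (an
all-producer grid gives the uniform field $p/\gamma$).

### Replacement dynamics

Only **boundary** cells — cells with at least one of their four cardinal
neighbors of the other type — can change the configuration: a divider
replaces a neighboring competitor with a daughter of its own type (a
spatial Moran process). Each directed cross-type pair is one event with
rate $g(\text{divider})/4$; the $1/4$ normalizes the per-event rate to the
per-cell growth rate, since a cell can initiate up to four events.
Same-type replacements are no-ops and are excluded from both the event set
and the clock; including them would rescale waiting times without touching
the configuration sequence, so the fixation probabilities and spatial
statistics are unaffected. Under this convention the neutral model's
selection bias is *exactly* 0.5 on any mixed configuration, by
construction: each undirected boundary edge contributes one NP-replaces-P
and one P-replaces-NP event of equal rate.

Waiting times and event picks follow the exact Doob–Gillespie algorithm:
$\tau \sim \mathrm{Exp}(\sum_i r_i)$ and event $i$ with probability
$r_i / \sum_j r_j$. The inner loop is compiled (Rcpp) and draws from R's
RNG, so a run is bit-reproducible from `set.seed()` / the config seed.

### Variants

* **neutral** — production and cost set to zero; every replacement equally
  likely. The negative control: a voter model whose invader fixation
  probability is exactly $1/L^2$.
* **competition** — the producer/nonproducer model above.
* **mutualism** — two symmetric types, each producing a resource that
  benefits only the *other* type: $g = g_0 - \kappa + \alpha\,c_{\text{other}}$,
  with $\kappa = g_0$. The positive control: growth concentrates where the
  complementary type is nearby, a balancing force that sustains coexistence
  and finite kin domains.
* **competition_saturating** — Michaelis–Menten uptake: the benefit becomes
  $\alpha\,c\,K_s/(K_s + c)$ and consumption $\gamma\,c\,K_s/(K_s + c)$.
  As $K_s \to \infty$ both revert to the linear forms.

## Numerical choices

* **Saturating steady state.** The nonlinear problem is solved by damped
  Picard iteration: consumption is linearized at the current iterate as an
  effective local rate $\gamma K_s/(K_s + c)$, the resulting
  variable-coefficient screened problem is solved exactly with a sparse
  factorization, and iterates are mixed with damping 0.5 (tolerance
  $10^{-10}$ on the max-norm residual, cap 10,000 iterations). A
  uniform-coefficient FFT solve cannot represent the linearized operator,
  and source-side splittings stall at strong saturation, which is why the
  sparse route was chosen. Saturating consumption is bounded by
  $\gamma K_s$ per site, so a steady state only exists while
  $p\,n_P < \gamma K_s L^2$; the solver checks this and fails loudly
  otherwise. Because superposition is lost, the saturating dynamics
  re-solve the field after every replacement and are intended for small
  lattices.
* **RDF binning.** `radial_distribution()` pools all reference-type centers
  across configurations (which weights each configuration by its number of
  reference cells) and uses minimal-image distances with unit bins centered
  on integers up to `L/2`; `binwidth = NULL` switches to exact distance
  classes, which is the right resolution for lattice-exact checks such as a
  checkerboard. The curve is computed by circular autocorrelation of the
  type indicator (FFT), so every pair is counted, without sampling.
* **Decay-length fits.** `fit_exponential_decay()` subtracts a plateau
  (default: mean of the outer quartile of bins) and fits
  $\log(c - \text{plateau})$ against $r$ by least squares. Note that the
  2-d screened Green's function is $\sim K_0(r/\lambda)$, i.e. the leading
  exponential $e^{-r/\lambda}$ carries a slowly varying prefactor whose
  local slope contributes $-1/(2r)$; over the window $[2\lambda, 4\lambda]$
  the fitted length is therefore about $0.86\,\lambda$, not $\lambda$. The
  test suite freezes the independently computed value (8.622 at
  $\lambda = 10$, `L = 256`) rather than pretending the prefactor away.
* **Critical-benefit search.** `critical_alpha()` bisects $\alpha$ against
  the producer-fixation probability from 50-50 mixed starts, with Wilson
  intervals per probe. The default bracket is
  $[0,\ 4\kappa\,\max(1, \lambda^2)\,\gamma/p]$: mean concentration at
  50-50 is $p/2\gamma$, so the benefit must reach about $2\kappa\gamma/p$
  to offset the cost, while the private-resource limit
  ($\lambda \to 0$) balances near $\kappa\gamma/p$; the $\lambda^2$ factor
  accommodates the growth of the balance point with diffusion length. The
  search stops when a probe's interval straddles 0.5 and the bracket is
  relatively narrower than `tol`, or after `max_probes` probes.
* **Caps and strides.** Default `max_events` is $50 L^4$, far above neutral
  absorption scales; hitting a cap is reported as `absorbed = FALSE`,
  never silently. Trajectories record every $L^2$ events by default.

## What the generator emulates, and what it does not

Initial conditions follow the study designs: `mixed_50_50` (equal numbers
placed uniformly at random; on odd $L^2$ the extra cell is a nonproducer),
`segregated_halves` (two vertical blocks), and `single_invader`. The
simulated system is a fully occupied, strictly two-type, immutable-strategy
lattice with instantaneous resource equilibration. Passing tests therefore
say nothing about vacancy/expansion dynamics, mutation, more than two
strategies, payoff-matrix games, or regimes where division is not slow
compared to diffusion — all outside the model by construction.

## Design choices where the design was genuinely open

* **Cross-type-only event clock** (see above): the alternative no-op-
  inclusive clock changes only the time scale; it can be emulated by
  rescaling time and was not made a runtime switch.
* **Benefit at the divider's site.** Rates depend on the resource at the
  dividing cell, not at the site being colonized; this is the reading under
  which division is driven by the divider's own growth.
* **Mutualism defaults** (`lambda = 2`, `alpha = 10`): kin domains a few
  cells across fit many times into even a 16×16 lattice, and since both
  types share the same law $g = \alpha\,c_{\text{other}}$, $\alpha$ only
  sets the clock relative to the neutral control — the configuration
  dynamics depend on $\lambda$ alone. These values sit well inside the
  coexistence regime exercised by the test suite.
* **Coexistence horizon.** Persistence claims are measured against
  `horizon_mult` (default 10) times the *measured* mean neutral absorption
  time at the same `L`, making the property scale-free.
* **Configuration files** are a flat `key = value` subset of TOML parsed by
  the package itself (scalars, quoted strings, booleans, comma-separated
  numeric lists); unknown keys are errors.

## Scales used by the test suite

The suite runs everything at sizes a laptop handles in minutes: solver
cross-checks on 16×16 grids (50 random configurations), neutral fixation
at $L = 3, 4$ with 50,000 runs each, the balanced-vs-neutral comparison at
$L = 16$ with 150 runs per arm and the balance point taken from the
package's own `critical_alpha()` search at that size, and the mutualism
control at $L = 16$ with 20 runs against 20 neutral controls. The
boundary-growth ratio is evaluated at the full 32×32 experiment scale,
where a single exact field solve is cheap.

## Known limitations

* The fitted decay length of the single-source field is systematically
  below $\lambda$ (prefactor effect above); quote $\lambda$ itself only as
  the screening length of the equation, not as a fitted slope.
* The balance point $\alpha^*(\lambda)$ is *ensemble-sensitive*: the
  concentration contrast across a boundary is several times larger for a
  flat segregated interface than for a well-mixed random configuration,
  with coarsened domains in between. The bisection value (from mixed
  starts) grows roughly like $\lambda^2$ and substantially exceeds the
  benefit value at which one unit of resource offsets the cost arithmetic;
  near the transition, fixation outcomes are decided by the early, weakly
  coarsened part of the trajectory. The unit tests pin the limits that are
  ensemble-free ($\alpha^* \to \kappa\gamma/p$ as $\lambda \to 0$;
  monotonicity in $\alpha$).
* The saturating variant re-solves the field per event (no superposition)
  and is priced accordingly.

## A worked example

```{r example, eval = FALSE}
library(moranpg)

sim <- run_until_fixation(L = 16, variant = "competition",
                          lambda = 10, alpha = 49, seed = 7)
print(sim)
#> Spatial Moran simulation (competition), 16 x 16 lattice
#>   lambda = 10, alpha = 49, kappa = 1, g0 = 1
#>   absorbed: NP fixed at t = 10.55 after 2,690 events

tab <- build_event_table(make_grid(16, initial_condition("mixed_50_50", seed = 1)),
                         growth_params("neutral"))
selection_bias(tab)
#> [1] 0.5
```
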