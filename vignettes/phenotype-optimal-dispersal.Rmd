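---
title: "Modelling species range dynamics under phenotype-optimal dispersal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling species range dynamics under phenotype-optimal dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optidisp)
```

## The model

`optidisp` simulates the joint evolution of three population fields over a
continuous one- or two-dimensional habitat: population density $n(x,t)$,
the mean $q(x,t)$ of a fitness-related quantitative trait, and its
intraspecific variance $v(x,t)$. The habitat carries an optimum trait field
$\mathrm{Q}(x)$ (typically linear, with slope the *environmental
gradient*) and a carrying capacity $\mathrm{K}(x)$.

Individuals disperse in two ways. Random dispersal is diffusion with
coefficient $\mathrm{D}$. *Phenotype-optimal dispersal* — an idealisation
of matching habitat choice — is advection along the gradient of the
optimum, with velocity proportional to the propensity $\mathrm{A}$, to the
phenotypic potential $(p - \mathrm{Q})/\mathrm{V}$ (mismatch scaled by the
utilisation variance $\mathrm{V}$), and to the *perceived* gradient

$$\widetilde{\nabla \mathrm{Q}} \;=\;
  \frac{\Pi}{\Pi + \lVert\nabla \mathrm{Q}\rVert}\,\nabla \mathrm{Q},$$

which saturates at magnitude $\Pi$: beyond some steepness, a steeper
gradient cannot push an individual any harder. Growth is logistic with
phenotype-dependent competition (Gaussian kernel of variance
$2\mathrm{V}$, giving the population-level factor
$\sqrt{\mathrm{V}/(v+\mathrm{V})}$), stabilising selection of strength
$\mathrm{S}$ penalises both mean mismatch and standing variance (the
phenotypic load), and mutation feeds variance at rate $\mathrm{U}$.

Assuming the phenotype distribution is Gaussian at every occupied point
closes the moment hierarchy exactly, yielding three coupled
reaction–advection–diffusion equations. `model_rhs()` assembles them term
by term and exposes every term in a registry (`t14`–`t28`), so that the
contributions of random versus directed gene flow can be inspected
separately (`gene_flow_decomposition()`).

All quantities are expressed in the model's natural units: time `T` (one
generation), space `X` (root-mean-square single-generation dispersal
distance over $\sqrt 2$, so that $\mathrm{D} = 1$), abundance `N` (the
carrying capacity of one `X`$^m$), and trait `Q` (one standard deviation
of the core population's trait). Parameter defaults in `model_params()`
are the typical values used in all shipped experiments:
$\mathrm{D}=1$, $\mathrm{A}=4$, $\mathrm{K}=1$, $\mathrm{R}=2$,
$\mathrm{V}=4$, $\mathrm{S}=0.2$, $\mathrm{U}=0.02$, $\Pi=1$, $\delta=2$.

## Validating the closure: the phenotype-resolved oracle

The closed equations rest on the Gaussian-phenotype assumption. The
package therefore ships a brute-force reference simulator
(`step_phenotype_density()`) that evolves the full phenotype-resolved
density $f(x,p)$ on a small $(x,p)$ grid: diffusion in space, advection
with the per-phenotype velocity, growth with the competition convolution
computed by quadrature, and mutation as phenotype diffusion with
coefficient $\mathrm{U}/2$ (so that variance grows at exactly rate
$\mathrm{U}$ in isolation — the only consequence of the mutation kernel
that the closed model retains). For Gaussian initial data,
`oracle_moment_rates()` extracts $(\dot n, \dot q, \dot v)$ and the test
suite verifies they converge to the closed right-hand sides under grid
refinement. The oracle uses centred advection: it runs only on smooth
Gaussian data, where upwinding would contaminate the trait moments with
phenotype-dependent numerical diffusion. It is a validation instrument,
not a production solver.

## Numerical scheme

The solver (`integrate_model()`) uses a cell-centred method of lines:

* second-order central differences for all diffusive and gradient terms;
* the density advection flux in conservative form with donor-cell
  (upwind) face values, which keeps density nonnegative at steep fronts;
* the pure advection terms of the trait equations (transport of $q$ and
  $v$ by the mismatch velocity) are also donor-cell upwinded by default.
  Central differencing of these terms is selectable
  (`advection_scheme = "central"`) but produces odd–even oscillations in
  the nearly empty exterior of the range, where the mismatch — and hence
  the local mesh Péclet number — grows large;
* Heun's explicit second-order Runge–Kutta in time, with the step chosen
  each step as a safety fraction (default 0.9) of the harmonic
  combination of the diffusive bound $1/(2\sum_i \mathrm{D}_i/\Delta
  x_i^2)$ and the advective bound $\Delta x_i/\max\lVert u\rVert$. The
  harmonic combination matters: taking the minimum of the two bounds is
  not stable when diffusion and advection are comparably strong, which is
  exactly the regime after an abrupt optimum shift. The effective
  advection speeds entering the bound include the mismatch velocity, the
  $v/\mathrm{V}$-weighted directed-flow velocity, and the asymmetric
  gene-flow velocity $2\mathrm{D}\nabla\log n$.

$\nabla \log n$ is regularised as $\nabla n / \max(n, 10^{-10})$: in an
exponential tail this equals the physical decay rate, and where the
density has collapsed to the floor it vanishes, so the regularisation
never manufactures transport. Trait variance is meaningful only inside
the effective range; it is evolved everywhere, clipped to $[0, 10^4]$ as
a solver safeguard, and capped at $100\,$`Q`$^2$ for reporting only
(`cap_variance()`). Negative densities produced by round-off are clipped,
with the clipped mass logged; a run aborts if clipping exceeds $10^{-6}$
of total mass in one step.

Boundaries are reflecting (zero normal flux) on axis 1 — and in 1D — and
periodic on axis 2 in 2D. Because individuals are assumed to sense a wall
within distance $\delta = 2$ `X` and avoid it, the boundary-normal
component of the perceived gradient is multiplied by the smooth ramp
$\sin^2(\pi d / 2\delta)$ of the distance $d$ to the wall. This ramp is
this package's own construction: it is $C^1$, vanishes exactly at the
wall (so directed dispersal never pushes through it), and leaves the
interior untouched.

## Scenario generators and what they emulate

* `expansion_initial_state()` seeds a sech-shaped pulse
  ($n = 0.5\,\mathrm{sech}(|x|/\sqrt2)$, trait gradient 0.6 of the
  environmental gradient, perfectly adapted at the centre, $v = 1$) — the
  standard range-expansion experiment.
* `shift_schedule()` + `fluctuation_initial_state()` implement abrupt
  periodic climate fluctuations: the optimum is raised by the amplitude
  for the first half of each period and lowered back for the second,
  starting from a population established by a 4 `T` preliminary run of a
  denser seed (peak 0.8, trait gradient 0.7).
* `fragmented_scenario()` builds the 2D fragmented landscape: a
  $(-50,50)^2$ habitat, optimum gradient 1 `Q/X` along axis 1, and
  carrying capacity tiled with width-2 patches whose lengths are drawn
  deterministically (seeded) from $\{10,\dots,15\}$ `X` — gradient-aligned
  on the right half, gradient-perpendicular on the left — plus a 20×20
  central seeding patch. Within a patch, capacity rises from 0.05 at the
  edge to 1 at the centre as a half-cosine bump in each direction.

Two fragmentation choices were genuinely open. First, the reference
layout is not published, so patch lengths are drawn from a seeded uniform
grid over $\{10,\dots,15\}$; identical seeds give identical landscapes.
Second, the within-patch capacity profile: the default tensor bump
concentrates core capacity at the patch centre and reproduces the
steady-state in-patch density levels (and their ordering between strong
and absent optimal dispersal); an alternative ridge profile
(`end_ramp = 1`) carries full capacity along the patch's long axis and
reproduces instead the ~10% advantage of gradient-perpendicular over
gradient-aligned patches, at the price of in-patch densities about 0.1
`N/X`$^2$ higher. One profile cannot currently deliver both observations;
the package defaults to the tensor profile and exposes the ramp length.

The 2D seeding state is not prescribed anywhere; the package reuses the
1D expansion seed (radially symmetric sech pulse, trait gradient 0.6,
$v = 1$), which establishes the population inside the central patch
within a few generations. The final steady in-patch densities are
insensitive to this choice (a fully adapted seed gives the same values to
four decimals at $t = 40$).

## Equilibrium analytics

Far from the boundary the expanding population converges to a homogeneous
adapted state $(n^*, \mathrm{Q}, v^*)$. `equilibrium_variance()` returns
$v^*$ as the positive root of a cubic combining mutation, gene-flow
inflation by the gradient, directed-dispersal deflation and selection;
the root is tracked continuously from the zero-gradient branch, which
resolves any multiplicity. `equilibrium_density()` then gives
$n^* = (\mathrm{K}/\mathrm{R})\sqrt{(v^*+\mathrm{V})/\mathrm{V}}
(\mathrm{R} - \mathrm{S}v^*/2)$, competitive release times growth net of
phenotypic load. Setting $n^* = 0$ (at which $v^* = 2\mathrm{R}/
\mathrm{S}$) yields the *critical environmental gradient* beyond which
the species cannot persist; for $\mathrm{A} > 0$ the defining equation is
implicit because the perception saturation factor is evaluated at the
solution, and `critical_gradient()` solves it by bracketed root finding
on the interval where the denominator is positive (for $\mathrm{A} = 0$
the closed form $\sqrt{2\mathrm{R}^2/(\mathrm{S}\mathrm{D}) -
\mathrm{U}/(2\mathrm{D})}$ applies). The test suite checks that a
simulation initialised at $(n^*, \mathrm{Q}, v^*)$ stays put, and that
long-run wave amplitudes and core variances match the analytic curves to
a few percent.

```{r}
equilibrium_density(model_params(A = 0), grad_mag = 1.5)
critical_gradient(model_params(A = 0))$grad_mag
critical_gradient(model_params(A = 10))$grad_mag
```

## Problem sizes and tolerances

The shipped experiments use $\Delta x = 0.25$ `X` in 1D (400 cells over
$(-50,50)$) and $\Delta x = 0.5$ `X` in 2D (200×200 cells), horizons up
to 40 `T`; at these sizes every 1D experiment runs in seconds and a full
2D fragmented run in about a minute and a half. Self-convergence of front
positions is first order in $\Delta x$, as expected with donor-cell
upwinding; halving the mesh moves a 6 `T` front position by about half a
cell-width times the front speed. Closure-validation tolerances in the
tests were measured from the discretisation-error decay itself (the
relative error roughly quarters per joint refinement) and are not
physical claims.

## What the synthetic experiments do and do not show

The generators emulate the idealised study conditions: deterministic
dynamics, a linear (or patch-modulated) environment, spatially constant
parameters, and an asexual (or effectively locally-mating) population
whose phenotypes stay Gaussian. They do not emulate demographic
stochasticity, genetic drift, dispersal cost, plasticity, nonlocal
habitat assessment, or evolving dispersal propensity. Two consequences
deserve emphasis. First, extinction under violent environmental
fluctuations proceeds here as an asymptotically slow deterministic decay
(a few percent per ten generations once the population is tiny); a real
— finite — population would be finished off by stochasticity long before
that, so the extinction classifier's density floor should be read as "has
lost essentially all of its density and keeps losing", not as a hitting
time this model reaches quickly. Second, passing the closure-validation
tests shows the moment equations are internally consistent with their
phenotype-resolved parent under the Gaussian assumption — not that real
phenotype distributions are Gaussian.

## Known limitations

* Diagonal diffusion tensors, spatially constant
  $\mathrm{A},\Pi,\delta,\mathrm{S},\mathrm{U},\mathrm{V}$; asymmetric
  competition is out of scope.
* Explicit time stepping only; settings far stiffer than the shipped
  parameter ranges (e.g. $\mathrm{D} \gg 1$ on fine meshes) would warrant
  an implicit-explicit scheme.
* The trait fields outside the effective range are numerically defined
  but biologically meaningless; diagnostics mask them via the effective
  edges (density-profile inflection points).
* Gridded-field exchange uses long-format CSV (plus YAML run
  configurations); trajectories are kept in memory.
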