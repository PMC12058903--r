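# optidisp

Deterministic PDE simulation of species range evolution under **matching
habitat choice** — dispersal biased toward habitat whose optimum phenotype
matches the disperser's own phenotype. The package is for quantitative
ecologists and evolutionary modellers who want to ask *when* this
"phenotype-optimal" dispersal mode materially changes range expansion,
local adaptation, trait variation and persistence, relative to purely
diffusive dispersal.

## The model

Three fields evolve jointly on a 1D or 2D habitat: population density
*n(x,t)*, trait mean *q(x,t)* and trait variance *v(x,t)*. With a
Gaussian phenotype distribution the dynamics close exactly into three
coupled reaction–advection–diffusion equations, schematically

```
∂t n = div(D ∇n) − div(n·u) + [R − (R/K)√(V/(v+V)) n − (S/2)((q−Q)² + v)] n
∂t q = div(D ∇q) + 2⟨∇log n, D ∇q⟩ + (directed gene-flow terms) − S (q−Q) v
∂t v = div(D ∇v) + 2⟨∇log n, D ∇v⟩ + 2⟨∇q, D ∇q⟩ + (directed terms)
       + (R/K)√(V/(v+V)) n v²/(2(v+V)) − S v² + U
```

where `u = A·((q−Q)/V)·Υ∇Q` is the directed-dispersal velocity:
propensity `A` times the phenotypic potential (mismatch over the
utilisation variance `V`) times the *perceived* environmental gradient,
saturated at magnitude `Π` by the factor `Υ = Π/(Π+‖∇Q‖)`. Each named
term of the equations is exposed individually, so random and directed
gene flow can be compared (`gene_flow_decomposition()`).

Alongside the solver the package provides

* a phenotype-resolved brute-force simulator on an *(x, p)* grid that
  validates the Gaussian moment closure term by term;
* closed-form / root-finding analytics for the adapted homogeneous
  equilibrium *(n\*, v\*)* and the **critical environmental gradient**
  beyond which the species cannot persist;
* scenario generators for the shipped experiments: linear optima,
  abrupt periodic optimum shifts, and fragmented (patchy carrying
  capacity) 2D landscapes;
* trajectory diagnostics: effective range edges (density inflection
  points), travelling-wave speed and amplitude, adaptation times,
  fluctuation-cycle mean density, extinction classification.

## Worked example

Range expansion over a steep environmental gradient (1.5 Q/X) with
strong optimal dispersal, on the standard habitat (−50, 50):

```r
library(optidisp)

g    <- habitat_grid(c(-50, 50), nx = 400)
p    <- model_params(A = 10)                   # strong matching habitat choice
env  <- linear_optimum(g, slope = 1.5, params = p)
s0   <- expansion_initial_state(g, env)        # sech seed, adapted at the centre
traj <- integrate_model(s0, env, p, g, solver_options(t_end = 20, record_every = 1))

wave_metrics(traj, window = c(10, 20))
#> wave_metrics: speed = 1.949 X/T, amplitude = 1.063, core variance = 1.002 Q^2

equilibrium_density(p, grad_mag = 1.5)
#> equilibrium at g = 1.5: v* = 1.002 Q^2, n* = 1.062

adaptation_time(traj, location = c(1.25, 0))
#> [1] 2

critical_gradient(model_params(A = 0))$grad_mag
#> [1] 6.323765
```

Reading the numbers: the expansion wave travels at ≈1.9 X per generation
and its plateau density (1.063) and core trait variance (1.002) agree
with the analytic equilibrium (n\* = 1.062, v\* = 1.002) to a fraction of
a percent. The core's margin reaches the local optimum within two
generations; rerunning with `A = 0` takes more than three times longer
and leaves the wavefronts permanently swamped. A purely diffusing
population with typical parameters cannot persist at gradients steeper
than ≈6.32 Q/X; optimal dispersal pushes that threshold far higher.

The same experiments can be driven from YAML presets in `inst/configs/`
via `run_scenario()`, or from a shell through the thin CLI at
`inst/cli/optidisp.R`.

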