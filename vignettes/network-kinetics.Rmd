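---
title: "Methods: network-structured kinetic models in netkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-structured kinetic models in netkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkin)
```

## The modelling ladder

`netkin` implements one model three times, at three levels of description,
and the package's correctness story is that the levels agree where theory
says they must.

**Microscopic.** `N` agents hold a structural variable `x` (a position on a
spatial domain or a node of a discrete network) and a state `v`. Positions
are *fixed for all time*: the network is infrastructure, not dynamics. An
ordered pair — active agent `i`, passive agent `j` — interacts at rate
`w(x_i, x_j)/N`; the `1/N` mean-field scaling keeps the total interaction
pressure on one agent bounded as `N` grows. The active agent acts according
to its own state and does not change; the passive agent jumps by an
increment drawn from the interaction measure `ν`. `simulate_boltzmann()`
realizes this jump process exactly with the Gillespie algorithm
(exponential waiting times at the aggregate rate, pair selection
proportional to the rates, then an increment draw). We chose exact
event-driven simulation over tau-leaping deliberately: rates at the scales
we target are modest, and exactness makes the invariant tests sharp — the
spatial marginal returned by `empirical_marginals()` is *identically*
constant along a run, not constant up to discretization.

**Mean field (Vlasov).** When one event moves the passive state only by a
small factor (the dialect memory weight `γ/(1+γ)`, the social increment
`h = 1/J`), rescaling time by that factor and keeping first moments gives a
drift-only kinetic equation. `vlasov_coefficients()` assembles the drift
`W(z, z̃) = w(x, x̃)(E[a | z,z̃] + E[b | z̃,z])` and the Fokker–Planck
diffusion matrix `A` from the rule's moment functions;
`solve_vlasov_particles()` integrates the characteristics of the Vlasov
equation as a weighted particle method (states move, positions and masses
do not). The Fokker–Planck equation itself is not solved — `A` is exposed
and tested for symmetry, positive semidefiniteness and agreement with
sampled second moments, and a PDE solve in `(x, v)` space is outside the
package's scope.

**Monokinetic closure.** Measures concentrated at one state per position,
`μ = η ⊗ δ_{V(x,t)}`, close the Vlasov dynamics into a nonlocal equation
for the field `V`. For the dialect model this is a nonlocal
reaction–diffusion equation whose reaction `−κ(V − p(V))` is multistable
with stable states at the corners of the simplex, and whose nonlocal
diffusion acts on `p(V)` — the structure behind spatial phase separation
and coarsening. The closure is not an assumption we merely hope for: with
`κ(x) ≥ κ₀ > 0` the quadratic variation of the Vlasov solution obeys
`𝒱(t) ≤ e^{−2κ₀t} 𝒱(0)`, with equality for constant `κ`. The test suite
verifies the equality numerically (fitted decay rate 2 within 2% for
`κ ≡ 1`) and verifies that spread particle clouds track the concentrated
trajectory in the metric of `concentration_metric()` — the explicit form
the Wasserstein distance takes against a concentrated target.

## Interaction kernels and their local limits

Kernels are symmetric, nonnegative rate functions `w(x, x̃)`. On the
periodic unit interval distances are wrapped,
`d(x,y) = min(|x−y|, 1−|x−y|)`; the reference epidemic kernel has support
radius 0.2 < 1/2, so the wrap is unambiguous. Discretization
(`discretize_kernel()`) uses the rectangle rule with weight equal to the
grid spacing, matching the uniform grids used throughout; the diagonal
(self-interaction) entry is *included* for continuum-derived quadrature
(the integrals include `x̃ = x`) and *excluded* for agent-pair sums and
discrete node networks (the microscopic double sum runs over `i ≠ j`).
Both behaviours are explicit flags.

The scaled local kernel `w = ε⁻¹ k(·/ε)` concentrates as `ε → 0`;
expanding the nonlocal operator gives `(Cε²/2) Δ` with `C` the second
moment of the profile `k`, so the induced diffusion length is
`σ = √C ε` (`local_limit_sigma()`). Three profiles ship: box (`C = 1/3`),
triangle (`C = 1/6`), Epanechnikov (`C = 1/5`). The convergence tests use
a continuous profile: rectangle-rule quadrature of the box profile's jump
at the support edge carries an `O(h)` boundary error that would mask the
`O(ε²)` trend under study. That is a property of the quadrature, not of
the model; the box profile remains the documented default elsewhere.

## Parameters that matter

* `M` — number of variants / representations (dimension of the simplex
  `K`). Tests mostly use `M = 2` (where the state is effectively scalar)
  and `M ∈ {3, 4}` for the social model.
* `alpha_exp` (`α ≥ 1`) — conformity exponent of
  `p_i(v) = v_i^α / Σ v_j^α`. At `α = 1`, `p` is the identity and nothing
  separates; for `α > 1` the corners of `K` are stable and the symmetric
  state is unstable with linear growth rate `κ(α − 1)` (for `M = 2`),
  which the tests verify within 5%. Default 2 throughout.
* `gamma` (`γ > 0`, dimensionless) — weight of one heard utterance against
  the long-term memory. Small `γ` is the regime in which the Vlasov
  approximation is derived; mean-field time = simulator time × `γ/(1+γ)`.
* `J`, `h = 1/J` — social-model rescaling: `J` observations make one unit
  of `s`. The monokinetic influence factor `1/(s⁰ + λ_k t)` encodes norm
  entrenchment; `λ_k = Σ_ℓ w_{kℓ} ρ_ℓ` is verified against the observed
  `s`-drift in agent simulation.
* `beta` (`β ≥ 0`, per unit time) — SIR removal rate, realized as a unary
  channel in the simulator: a documented extension of the purely pairwise
  framework.
* Kernel amplitude and the mass-action coefficient are deliberately
  separate objects (`amplitude` vs `row_integral`): the reference kernel's
  amplitude is 0.3 while its row integral `α(x) = ∫w dx̃ = amplitude ×
  cutoff² = 0.012`; conflating the two symbols would silently change the
  epidemic's reproduction ratio.

## Numerics

Fixed-step explicit integrators (Euler and RK4) are implemented in the
package: the explicit Euler scheme with `dt = 0.01` *is* the reference
epidemic's numerical contract, and every step may be followed by a
projection. The drifts of the simplex-valued models are tangent to `K`
analytically (their components sum to zero pointwise); the projection only
renormalizes floating-point drift beyond `1e-12` and clips negative parts
below `1e-10` with a warning. `choice_probabilities()` tolerates
infinitesimal (`> −1e-9`) negatives because RK4 trial substeps are taken
before the projection. Corner states use the convention `0^α = 0` with
renormalization over nonzero entries, making each corner a fixed point by
continuity from the interior. Local PDEs use the second-order central
Laplacian on the periodic grid with default `dt = 0.2 h²/σ²` and a warning
when the explicit diffusion stability bound is violated.

Two places are deliberately non-smooth or ill-posed, and are shipped as
such:

* The social action map is a discontinuous argmax (ties broken uniformly,
  equality decided after rounding to 12 decimals), so monokinetic
  solutions need not be unique. `solve_social_monokinetic()` offers the
  argmax field with a fixed small step for qualitative runs and a
  power-law regularization (`p` with a large exponent, default 40) for
  quantitative ones; the two agree away from ties. We note without
  resolving it that the argmax rule is the concentration limit of the
  power-law choice map as the exponent grows large.
* The degenerate local SIR system (`∂_t u = −αuv − uΔv`) is a
  demonstrator, not a production solver: where the infected profile is
  concave enough that `Δv < −αv`, `∂_t u > 0` and susceptibles locally
  *increase*, violating the modelling assumption the nonlocal system
  provably satisfies. `solve_sir_local()` flags the offending grid points
  and does not enforce positivity, since breaking it is the point. The
  leading-order local approximation (classical SIR reactions) is the
  well-behaved alternative.

Design choices made where the design was genuinely open:

* The probability-variable form of the local dialect equation is advanced
  directly in `P` with right-hand side `−κ(V(P) − P) + (σ²/2)ΔP`, `V(P)`
  the closed-form inverse of the choice map, and converted back to `V` for
  output.
* The reference epidemic's initial infected "peak at 0.5" is a Gaussian of
  height 0.05 and width 0.02 by default; every structural assertion
  (conservation, monotonicity, positivity) is shape-independent, and the
  shape is configurable.
* The comparison reaction-diffusion epidemic's diffusivities are not part
  of the reference configuration; the default `D₁ = D₂ = 1` lets the
  nonlocal Laplacian carry the kernel's own scale. The qualitative
  network-vs-comparison contrast (more cumulative infections in the
  network model, no susceptible transport) is asserted for this default
  and is configuration-dependent.
* Ordered pairs: `(i, j)` and `(j, i)` are distinct events, matching the
  `i ≠ j` double sum of the master equation; all shipped rules leave the
  active agent unchanged (`a ≡ 0`), though the simulator supports general
  increments.

## The synthetic-data generator

All inputs are generated in code (`generate_fixture()`), deterministically
in the seed: uniform random agent positions with flat-Dirichlet simplex
states; two-community networks (intra-weight 1, inter-weight 0.05) as the
canonical phase-separation substrate; Gaussian peaked fields; interior
simplex fields from concentrated Dirichlet draws. These emulate the
*mathematical* conditions of the models — well-spread structural marginals,
interior initial states, localized seeds — and none of the confounders of
real social data: no sampling bias in who is observed, no heavy-tailed
degree distributions, no temporal network change, no model misspecification.
Passing tests therefore certify the implementation against its own theory
(conservation laws, decay rates, limit consistency, simulator-to-mean-field
convergence), not the models' fit to empirical dialect maps or epidemics.

Problem sizes are chosen at desk scale and stated in the tests themselves:
the variance-decay run uses 50 nodes × 10 particles to `t = 2` at
`dt = 0.01`; the simulator-to-Vlasov comparison uses `N ∈ {50, 200}`
agents on 10 nodes, `γ ∈ {0.2, 0.05}`, three fixed-seed replicates, with
trend assertions pooled over the other factor (at `N = 50` the Monte-Carlo
noise of per-node means is comparable to the `O(γ)` bias, so pooled
comparisons are the statistically honest reading of "error decreases");
the epidemic reference runs 100 grid points × 500 Euler steps.

## Known limitations

Only one spatial dimension is exercised (interfaces do not preclude more);
the Fokker–Planck equation is assembled but not solved; Wasserstein
machinery beyond the concentrated-target closed form is out of scope;
networks do not evolve in time; and the monokinetic closure is the only
macroscopic closure provided. The agent simulator is `O(N)` per event —
adequate for the tested scales (≤ a few thousand agents), not for
population-scale runs.
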