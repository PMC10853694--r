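---
title: "Optimal enzyme allocation: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal enzyme allocation: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzalloc)
```

## The optimization problem

`enzalloc` studies an unbranched chain of uni–uni reactions
S₀ ⇌ S₁ ⇌ … ⇌ Sₙ at steady state, where every reaction rate is proportional
to its enzyme level, `v_i = ε_i k_i(s_{i-1}, s_i)`. The question is how to
allocate a fixed enzyme budget `Σ w_i ε_i ≤ ε_tot` so that the common
steady-state flux J is maximal. Because flux scales linearly with a uniform
scaling of all enzymes, this is equivalent to minimizing the total enzyme
demand at unit flux, `Σ_i w_i / k_i(s_{i-1}, s_i)`, over the metabolite
concentrations — and that objective is convex in the log-concentrations,
which is what makes the numerical problem benign.

Key assumptions, inherited by every solver:

* steady state with equal flux through all reactions (no branching, no
  moiety conservation);
* rates strictly linear in enzyme level (single specific enzyme per
  reaction, no enzyme–enzyme interactions);
* dilution of intermediates by growth is ignored, also in the cell model;
* units are agnostic: ε may be molar or mass concentration, with kcat a
  turnover number or a specific activity — the code never converts units,
  it only requires consistency. Weighted budgets are handled by rescaling
  `kcat_i → kcat_i/w_i` internally ("effective" turnover numbers) and
  un-scaling the reported ε_i, so all solvers assume unit weights.

## Rate laws and their parameters

The reversible saturable (Haldane) law is the reference:
`v = ε kcat⁺ (1 − e^{−θ}) η_sat` with driving force `θ = ln(K_eq s/p)`
(dimensionless; the gas constant and temperature are absorbed) and
`η_sat = (s/K_S)/(1 + s/K_S + p/K_P)`. Its constants are tied by the Haldane
relationship `K_eq = (kcat⁺/kcat⁻)(K_P/K_S)`, which the constructor enforces
to relative 1e−9 (and uses to derive `kcat⁻` when it is omitted). The
simplified laws — Michaelis–Menten, thermodynamic, mass-action, trivial —
are limiting cases, and the package verifies these reductions numerically
rather than assuming them. A product concentration of zero is mapped to
θ = +∞ and η_for = 1 (the irreversible limit), not treated as an error.

Reactions with co-substrates at known concentrations reduce exactly to this
uni–uni form. For convenience kinetics A + B ⇌ P + Q with fixed b and q the
reduction derived here is, with `D₀ = 1 + b/K_B + q/K_Q`:
`K_S' = K_A D₀/(1 + b/K_B)`, `K_P' = K_P D₀/(1 + q/K_Q)`,
`kcat⁺' = kcat⁺ (b/K_B)/(1 + b/K_B)`, `kcat⁻' = kcat⁻ (q/K_Q)/(1 + q/K_Q)`,
and `K_eq' = K_eq·b/q` follows from the Haldane relation. The reduction is
validated by a grid-equality test (20×20 grid in s and p, relative 1e−10)
against the full bi-bi formula, not taken on faith.

## Analytic optima

With `α_i = 1/kcat_i`, `β_i = K_M,i/kcat_i`, `γ_i = β_i Π_{j≥i} K_eq,j` and
`‖x‖_{1/2} = (Σ√x_i)²`:

* **Trivial**: ε_i* ∝ α_i, J* = ε_tot/‖α‖₁. Turnover times add along the
  pathway, like series resistances.
* **Michaelis–Menten**: without a metabolite bound the optimum runs away
  (s_i → ∞) — the solver raises a typed "unbounded metabolite paradox"
  error, with an explicit option to return the trivial-limit values flagged
  as a limit rather than a state. With the bound, free substrate levels are
  √β-proportional shares of s_tot. The downstream product never enters the
  rate, so sₙ is excluded from the bound; in the fixed-s₀ variant s₀ is
  excluded too, and reaction 1 contributes `α₁ + β₁/s₀` directly.
* **Thermodynamic**: the optimal split of θ_tot is
  `θ_i* = 2 asinh(√(Ψ α_i))` with Ψ the unique root of
  `2 Σ asinh(√(Ψ α_i)) = θ_tot`. The identity
  `α/(1 − e^{−θ*}) = α(1 + √(1 + 1/(Ψα)))/2` connects the demand form of the
  solution to the Ψ form; the implementation uses the demand form directly
  because it makes the steady-state invariant `v_i(ε_i*, s*) = J*` exact by
  construction, and the convex oracle arbitrates the algebra. The allocation
  depends on the K_eq,i only through their product: intermediate
  concentrations absorb any redistribution, which is tested as an
  invariance property.
* **Mass-action**: ε_i* ∝ √γ_i, J* linear in s₀ — no saturation, hence no
  Monod parameters can exist for this law (see below). Identical-γ chains
  lose flux as 1/n², and an a-fold kcat improvement lets that enzyme shed
  only a factor √a of its allocation.

## Numerical machinery

**Ψ root.** The left-hand side of the Ψ equation is strictly increasing, so
the root is bracketed by doubling from 1 upward and then polished with
safeguarded Newton steps (bisection fallback) to relative residual 1e−14;
the closed form Ψ = kcat sinh²(θ_tot/2) for n = 1 is recovered to 1e−12.

**Convex solver.** `min_enzyme_demand()` optimizes in transformed
coordinates rather than raw log-concentrations:

* For reversible laws the decision variables are the per-reaction driving
  forces on the simplex `Σθ_i = θ_tot`, via a softmax map with the last
  coordinate pinned at 0. This keeps every reaction thermodynamically
  feasible *by construction* (the demand itself diverges as θ_i → 0, acting
  as a natural barrier), and because θ is an affine function of the
  log-concentrations the convexity of the objective is preserved.
* For the irreversible saturable law the bound is always active at the
  optimum, so the free metabolites are parameterized directly on the
  simplex `Σs = s_tot`.
* A metabolite bound that an unconstrained reversible optimum violates is
  handled by log-barrier continuation: the iterate is pulled just inside
  the bound (an interpolation between the unconstrained optimum and the
  most-interior driving-force split, chosen so gradients stay on the
  optimum's scale), then the barrier weight is tightened from 1e−1 to 1e−13
  of the objective.
* Quasi-Newton (`nlminb`, PORT) with analytic gradients is followed by a
  Newton polish on the gradient (Hessian by central differences). The
  polish matters: an objective-based stopping rule leaves the *argument*
  at ~√tol accuracy because optima are flat, and the package promises the
  enzyme profile, not just the flux, to 1e−6 against the analytic forms.

**Steady states.** Mass-action is closed-form
(`J = (s₀K_eq,tot − sₙ)/Σγ_i/ε_i`; the chain is a positive linear system, so
the reconstructed concentrations are positive whenever the boundaries are).
The thermodynamic law solves `Π(1 − J/(ε_i kcat_i)) = sₙ/(s₀K_eq,tot)` by
bisection plus Newton polish on the unique root below the smallest capacity.
Michaelis–Menten propagates the fixed upstream inflow down the chain and
names the bottleneck reaction when a downstream capacity is insufficient.
The Haldane law uses a damped Newton relaxation (analytic tridiagonal
Jacobian in log-concentrations, step halving, at most 200 iterations) to
relative balance 1e−13.

**Control coefficients.** All elasticities and control coefficients are
unscaled internally; flux control is normalized as
`C^J_l = (∂J/∂ε_l) ε_l/J`, under which the summation theorem reads
`ΣC^J = 1` and the connectivity theorem `Σ_l C^J_l E_{l,i} = 0` with the
elasticity `E_{l,i} = ∂v_l/∂s_i` including the enzyme factor. That
convention is the one under which the enzyme-elasticity rule
`Σ_j ε_j E_{j,i} = 0` holds algebraically at the mass-action optimum, which
fixed the interpretation. Numeric derivatives use central differences at
relative step 1e−4 with Richardson extrapolation — the step balances the
~h⁴ truncation against the ~1e−15/h roundoff so the theorem residuals sit
near 1e−11; a smaller step would push roundoff above the 1e−9 residual the
theorems are tested at. Concentration control coefficients
(`C^{s_i}_l = (∂s_i/∂ε_l) ε_l/J`, summing to zero over reactions by flux
homogeneity) are computed numerically only; no analytic form is offered.
The generalized enzyme-control rule is implemented for uniform enzyme and
metabolite weights only, matching how it is stated; heterogeneous weights
are untested territory and are rejected.

**Joint density optima.** For `a Σε + b Σs ≤ ρ` the whole residual budget
goes to enzymes at any fixed metabolite profile, so the problem collapses
to maximizing `(ρ − bΣs)/(a Σ demand(s))` over free log-concentrations.
With b = 0 the problem is delegated to the plain-budget solver (and hence
raises the paradox for Michaelis–Menten, as it must). Only free metabolites
count toward the b-term: a fixed boundary concentration is environment, not
cell content, and when a free boundary is later clamped at its optimum for
control analysis, the rule holds with the sum over the remaining dynamic
metabolites.

## The cell model

Transport → metabolism → translation as a three-reaction chain with fixed
external nutrient s_sugar (excluded from the internal bound s_tot), all
Michaelis–Menten. The fixed-s₀ solution then *is* the Monod curve:
μ_max = ε_tot/D and K_Monod = (K_M,t/kcat_t)/D with
`D = Σ 1/kcat + (√(K_M,m/kcat_m) + √(K_M,r/kcat_r))²/s_tot`. The package
tests this as a consistency contract between `growth_rate()` and
`solve_michaelis_menten()` on a nutrient grid (relative 1e−8) rather than
as two independent formulas. Because transport is irreversible, the
cytoplasm is informationally buffered: optimal internal metabolite levels
are independent of μ, so the metabolic and ribosomal sectors are straight
lines through the origin and the transporter takes the falling remainder.
At full saturation the transporter's optimal abundance is μ_max/kcat_t —
the transporter's *own* turnover number; this is the only reading
consistent with the steady-state balance, and the package implements it
that way. The mass-action variant has strictly linear μ(s_sugar) and the
growth-law constructor refuses to produce Monod parameters for it. The
thermodynamic variant gives `μ = μ_max(1 − (A/s_sugar)^B)` with
`A = sₙ/K_eq,tot` and `B = ‖α‖₁/‖α‖_{1/2} ∈ (0, 1]`, sensitive to product
accumulation in a way the Monod form is not.

The default `cell_model_spec()` is the didactic toy cell (all constants 1,
K_M,m = 2, ε_tot = s_tot = 1); it is a reference configuration for
exploring parameter effects, not a parameterization of any organism.

## Synthetic fixtures: what they emulate and what they do not

`generate_fixture()` draws kcat log-uniformly from [1, 100] time⁻¹, K_M
from [0.01, 10] and K_eq from [0.1, 1000] (concentration units are
arbitrary but consistent), then places the boundaries so that
θ_tot ~ U[0.5, 10] — pathways that are thermodynamically feasible by
construction, spanning near-equilibrium to strongly driven regimes.
ε_tot = 1 throughout (flux is exactly linear in it, so nothing is lost);
Michaelis–Menten fixtures get s_tot = n so the per-metabolite budget stays
of order one. Draws are deterministic in the seed and leave the session RNG
untouched.

These fixtures emulate the *spread* of kinetic constants seen across
enzymes, but not their correlations (real kcat and K_M co-vary), not
multi-substrate stoichiometry, not regulation, and not measurement noise —
passing the oracle-equivalence suite on them demonstrates the correctness
of the mathematics on its stated domain, not predictive accuracy on any
real pathway.

## Problem sizes and tolerances used in the tests

The oracle-equivalence suite runs 100 seeded fixtures per analytic law with
lengths cycling through 1–8, comparing (ε*, J*) against the convex solver
at relative 1e−6; limit reductions are tested at 1e−5; optimality rules at
1e−6 (1e−5 for the generalized rule) with 10%-perturbed profiles as
negative controls; the Ψ residual at 1e−12; and the closed-form
thermodynamic flux approximation within 5% of the exact optimum over
θ_tot ∈ [0.1, 10] — across this range its worst observed deviation is
about 1.2%, consistent with its construction to match both limits exactly.
The grid oracle is restricted to at most three free metabolites and is used
as an independent bracket on the convex solver, never as the solver.

## Known limitations

* Unbranched chains only; no branching, conserved moieties, or regulation
  with varying effector levels.
* Control analysis is local (first-order); states where control is
  undefined (the unbounded Michaelis–Menten optimum) raise typed errors
  rather than returning NaN.
* The barrier continuation for bound-constrained reversible problems
  assumes the feasible set has an interior; pathological bounds tighter
  than any driving-force split are reported as infeasible.
* The generalized enzyme-control rule supports uniform weights only.
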