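---
title: "Coupling qualitative regulatory steady states to flux balance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling qualitative regulatory steady states to flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualflux)
```

## The two models and the bridge between them

`qualflux` joins two steady-state formalisms.

**Qualitative regulatory networks.** Components take integer levels
`0..max_level` (Boolean models are the 2-level special case) and are updated
by logical rules over the levels of other components. No kinetic parameters
are needed; the price is that time is abstract and levels are coarse. A
component without a rule is an *input*: its level never changes and encodes
the environment.

**Flux balance analysis.** A metabolic network at steady state satisfies
`S v = 0` over its internal metabolites; fluxes are bounded,
`lb ≤ v ≤ ub` (mmol/(gDW·h)), and a linear objective — usually the biomass
reaction, whose flux is the growth rate in h⁻¹ — is optimised by linear
programming.

The bridge is the *regulatory steady-state analysis* (RSA): build the
initial regulatory state, iterate the synchronous update until the
trajectory revisits a state (this always happens: the update is a function
on a finite set), keep the closed cycle as the attractor, translate its
levels into continuous intervals through declared state/interval
equivalences, and average the interval bounds over the attractor states.
The averaged interval (or, for purely qualitative components, the mean
level) is the single steady-state constraint per component.

Averaging is a population-level reading: an unsynchronised culture whose
cells sit at different phases of a regulatory oscillation is modelled by the
mean of the per-state bounds, all states weighted equally because the
formalism offers no dwell times. Users who prefer per-state analyses can run
one FBA per attractor state instead; `attractor_to_steady_state()` on a
single-state attractor degenerates to exactly that.

### Coupling rules

Three component kinds act on the flux model (`apply_steady_state()`):

* **Reactions**: the RSA interval is *intersected* with the model bounds; an
  unbounded end defers to the model bound. An empty intersection is an error
  naming the reaction, never a silent repair.
* **Genes**: a reaction whose GPR evaluates false is fixed to zero flux. A
  gene counts as absent only when its constraint is exactly 0. A cyclic
  attractor that leaves a gene at a fractional mean (say 0.5) therefore
  leaves the reaction unconstrained: the population interpretation again —
  part of the culture expresses the enzyme, so flux is possible. This is the
  conservative reading of an on/off formalism; a proportional cap would
  require a quantitative expression–activity map the model does not carry.
* **External metabolites**: a constraint of exactly 0 caps the *uptake*
  direction of the corresponding exchange reaction at 0; secretion is
  untouched, so a product can still be excreted into an empty pool.

Exchange reactions are recognised structurally: a single-species
drain/source, or a transport-exchange touching exactly one internal
metabolite. The uptake sign is the flux direction that supplies the cell —
the direction producing the single boundary species, or producing the
internal metabolite in the two-species form.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `default_bound` | 9999 | mmol/(gDW·h) | magnitude for bounds the SBML omits and for intersecting unbounded RSA intervals |
| `max_iter` (attractor search) | 10^6 | steps | pure safety cap; termination is guaranteed within the state-space size, so hitting it is reported as an internal error |
| `gamma` (FVA) | 1 | — | fraction of the optimum retained; the lock is `obj ≥ γ·opt − 10⁻⁶·max(1, |opt|)`, sense-aware, so the optimum itself always remains feasible |
| `steps` (phase analysis) | 20 | grid points/axis | shadow prices are forward differences over one grid step |
| `dt` (dynamic FBA) | 0.1 | h | see the refinement check below |
| delays (dynamic FBA) | 0 | steps | per-species persistence requirement before a proposed level is adopted |

## Numerical and representational choices

* **Attractor identity.** Cycles are canonicalised by rotating to the
  lexicographically smallest state over id-sorted species, so the same cycle
  entered at any phase is one attractor — this defines grouping in the
  census. Ties cannot occur (cycle states are distinct).
* **LP solving.** Problems are solved by a dense two-phase primal simplex
  written in the package (Bland's rule, pivot tolerance 10⁻⁹), with
  `boot::simplex()` as a second, independently selectable backend; the test
  suite requires agreement within 10⁻⁶, and small polytopes are additionally
  checked against exhaustive vertex enumeration. Flux variability
  re-optimises from the previous optimal basis (the constraint set never
  changes between targets, so the basis stays primal feasible); warm and
  cold results are asserted identical within 10⁻⁶.
* **Degenerate optima.** Alternate optimal flux vectors are the rule, not
  the exception. Every assertion in the package's tests is therefore on
  objective values, FVA ranges or phase labels, never on individual fluxes
  of a degenerate optimum.
* **Shadow prices** are finite differences of the re-optimised objective,
  not solver duals, so phase labels cannot depend on the LP backend's choice
  of dual solution. At the last grid point along an axis the backward
  difference substitutes for the undefined forward one. Phases group
  shadow-price vectors equal after rounding to 6 decimals; labels are
  consecutive integers in scan order; infeasible points are labelled as
  such, never dropped.
* **Equivalence intervals** carry per-endpoint openness so partitions like
  `[0,0]`, `]0, 0.6]`, `]0.6, +inf[` are expressible; disjointness is
  asserted on every parse. Both `]a,b]` and `(a,b]` dialects are accepted.
  A quantitative value landing on a boundary shared through dialect mixing
  resolves to the lowest matching level. Openness is ignored once intervals
  become LP bounds — a measure-zero distinction a continuous optimiser
  cannot honour. Averaging over a member interval with an infinite end
  yields an infinite end, later intersected with the finite model bound.
* **Constraint file semantics.** File overrides *replace* SBML bounds (the
  file is the user's explicit word), a single value on a reaction fixes both
  bounds, on a regulatory component it is an initial value (translated
  through equivalences when present), and the single objective line replaces
  the model objective.
* **Dynamic FBA update.** Within a step, growth is exponential
  (`X' = X·e^{μdt}`) and each pool follows the matching closed form
  `S' = S − v·X·(e^{μdt}−1)/μ`, with the linear form below `μ = 10⁻⁹`;
  pools are clamped at 0 and uptake is pre-capped by `S/(X·dt)` so the clamp
  only absorbs the within-step curvature. An infeasible step is treated as
  starvation (zero growth, zero exchange) rather than an abort, because a
  transiently over-constrained regulatory state is a modelling fact worth
  seeing in the trajectory.
* **Update delays.** The synchronous update is the steady-state workhorse;
  for dynamics the package optionally delays individual species: a proposed
  level change is adopted only after the rule has proposed that same level
  for the species' declared number of consecutive steps (delay 0 is plain
  synchronous). This deterministic persistence rule is this package's
  definition of delay-based asynchrony; stochastic update orders are out of
  scope.

## What the synthetic fixtures emulate — and what they do not

`make_lac_operon()` is a deliberately minimal catabolite-repression motif:
glucose sensing (`E`), an active-repressor node `I` that lumps LacI with
catabolite repression (`I' = E ∨ ¬lactose`), and the operon products `P`,
`B` gating a lactose route whose GPR is `P and B`. Routing repression
through `I` makes a repressor knockout derepress the operon even in glucose,
which is the behaviour a KO scan should expose. Yields are round numbers
(glucose 1 carbon/mmol, lactose 2, biomass 10 carbon per unit growth, uptake
bounds 10 and 4 mmol/(gDW·h)) so every expected objective in the tests is a
hand-computable fraction. The default media (11.1 mmol/l glucose, 8 mmol/l
lactose) are ordinary batch-culture magnitudes.

`make_maltose_extension()` gives glucose three levels with the 0.6 mmol/l
induction threshold separating "low" from "high" glucose and a maltose
regulator repressed only at the high level; its Boolean control
(`boolean_glucose = TRUE`) shows the collapse: with two glucose levels the
0.3 mmol/l condition becomes indistinguishable from 22 mmol/l.

`make_random_boolean_network()` draws rules with at most `k` regulators;
`brute_force_attractors()` enumerates the full state graph with its own
evaluator and canonicalisation and is the oracle against which the sampling
census is checked wherever enumeration is possible.

What passing these tests shows: the algorithmic machinery — discretisation,
attractor search, averaging, coupling, LP, dynamics — is correct on networks
whose ground truth is enumerable or hand-computable. What it does not show:
that any particular published genome-scale reconstruction is accurate, that
real regulatory logic is Boolean, or that the population-mean reading of
cyclic attractors fits a given organism. The fixtures have no noise, no
measurement error and no unknown structure; real SBML models additionally
stress parser corners (annotation dialects, unit declarations) that the
supported subset intentionally does not cover.

## Problem sizes

The test suite works at desk scale, chosen so every oracle is exhaustive:
random Boolean networks of 3–10 species (full 2^n censuses for 50 networks),
LP polytopes of up to 6 reactions (vertex enumeration), batch simulations of
~120 steps. The acceptance script censuses a 12-species network from 20,000
sampled initial conditions and cross-checks an 8-species sibling against the
oracle. Genome-scale use (hundreds of components; the package guards
exhaustive enumeration above 2^16 states and offers seeded sampling instead)
exercises exactly the same code paths.

## Known limitations

* Only the documented SBML subset is read: qual species/transitions with the
  comparison-and-connective MathML vocabulary, fbc v2 or COBRA-notes bounds,
  GPRs and objectives. Anything else fails loudly (transitions) or degrades
  with a warning (GPRs).
* No MILP: regulatory logic is *not* folded into the optimisation (that
  would forbid feedback loops); the two layers meet only through the
  steady-state constraints or the dynamic loop.
* No stochastic asynchronous updating; determinism is a design commitment.
* The LP layer is dense and meant for models up to a few hundred reactions;
  it favours transparency and testability over raw scale.
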