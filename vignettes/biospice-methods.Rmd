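---
title: "Models and methods behind biospice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind biospice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biospice)
```

`biospice` simulates deterministic, well-mixed biochemical reaction
networks through an electrical-circuit analogy: concentration ↔ node
voltage, molecule flux ↔ current. A species is a storage node whose
capacitance is its compartment volume; natural degradation is a leak
resistor `1/d`; a reaction with `N` reactants and `M` products
contributes `N+M` signed controlled sources, all carrying the same
rate value with opposite signs on the two sides; passive diffusion
collapses to a single resistor `1/D` between two nodes. Node balance
gives, for every species `X`,

$$\frac{d[X]}{dt} \;=\; \frac{1}{V_X}\Big(\sum_r s_{r,X}\,\nu_{r,X}\, v_r \;-\; d_X [X]\Big)$$

with `s = ±1` for product/reactant, `ν` the stoichiometry, and `v_r`
the reaction's rate law. This vignette records the modeling
assumptions, the parameters that matter, and the numerical and design
choices made where more than one reasonable option existed.

## The netlist format

The textual format has four sections. The format's content (one line
per parameter/species/reaction, type selected by the reaction name's
first letter, brace-delimited comma lists, literal `0` for an empty
argument) is fixed; the surface syntax details below are this
package's choices:

* **Section markers** are dot-keywords (`.parameters`, `.species`,
  `.reactions`, `.simulation`), case-insensitive — the unambiguous,
  SPICE-idiomatic option.
* **Comments**: `*` starts a comment line, `;` an inline comment
  (kept as the documented optional comment field on parameter lines,
  discarded elsewhere).
* **Stoichiometry** is an optional integer prefix inside species
  lists, `{2*A,B}`, defaulting to 1. The binding rate law needs the
  exponents, so the format must carry them.
* **Raw simulator lines** are prefixed with `$` and passed through
  verbatim to the SPICE exporter.
* **Numeric literals** accept scientific notation and the engineering
  suffixes `k, m, u, n, p`.
* Identifiers are case-sensitive internally, but names that collide
  case-insensitively are rejected up front: SPICE node names are
  case-insensitive and a collision would silently merge nodes on
  export.
* No continuation lines and no include mechanism — each line is one
  object.

Parameters may be arithmetic formulas over other parameters; they are
resolved in topological order (declaration order is irrelevant for an
acyclic set) and a cycle is an error naming its members.

## Rate laws

The ten reaction types use standard mass-action, Michaelis–Menten and
Hill forms (see the README table). Three points deserve notice:

* **Transcription with no activators.** The occupancy form
  `k_TR·Σ_act/(1+Σ_act+Σ_rep)` is taken literally when activators are
  declared. With an *empty* activator list the literal numerator would
  be 0 and the promoter permanently silent, which contradicts the
  standard use of this law for constitutive promoters under repression
  (the toggle switch's three `T` reactions are exactly that). The
  numerator is therefore 1 when no activator is declared, reducing the
  law to `k_TR/(1+Σ_rep)` — the repressor-only Hill law.
* **Zero-concentration guard.** Hill terms evaluate `x^n` only for
  `x > 0` and return factor 0 otherwise, so `0^0` never arises and
  fractional Hill coefficients are safe at the origin.
* **Custom rates** (`X` reactions) accept `+ - * / ^`, parentheses,
  `exp, ln, log10, pow, min, max, sqrt`, species in brackets (`[S]`)
  and bare parameter names — the minimal closure of what the built-in
  laws need. Unknown symbols are reported at build time, not during
  integration.

Enzymatic (`E`) reactions support one substrate; several listed
enzymes act through the sum of their concentrations. An empty enzyme
list means the rate is interpreted per unit enzyme.

## Network assembly

* **Volumes** enter as the capacitance: fluxes are divided by the
  species' compartment volume. Degradation is part of the same
  per-species balance and is divided by the volume too, so a species'
  decay time constant is `V/d`-invariant under flux scaling.
* **Clamps.** A `FIX` directive is an algebraic clamp (ideal voltage
  source): the state is held and the derivative row zeroed.
* **Negative-concentration guard.** The right-hand side evaluates all
  rate laws on `max(x, 0)`. A stiff solver may transiently step a
  state slightly below zero; clipping inside the rhs avoids NaNs from
  fractional powers without constraining the integrator.
* **Inert accumulators.** A species whose concentration appears in no
  rate expression, has no degradation leak, is unreferenced by
  directives and unclamped is a pure accumulator: it integrates flux
  and influences nothing. Such nodes have no finite operating point
  when fed (their derivative is a nonnegative flux), and they
  contribute exact zero eigenvalues to every Jacobian. The
  steady-state solver and the stability test therefore exclude them,
  and `count_sources(prune_inert = TRUE)` removes them together with
  their attached sources — which is how the 7-species toggle switch
  reduces to its 5-node equivalent circuit. A readout species (GFP)
  is retained because the `PLOT` directive references it.
* **Jacobian.** Central finite differences with step
  `max(1e-8, 1e-6·|x_j|)`; at the nonnegativity boundary the stencil
  shifts to `[x, x+2h]` because a stencil straddling zero would
  differentiate the clipping, not the model. A dense analytic oracle
  on the self-inhibited fixture agrees to better than `1e-6`
  relative, which is the accuracy the Newton solver, the stability
  test and the Bode analysis need.

## The analysis engine

* **Integrator**: `deSolve::lsoda` (automatic stiff/non-stiff
  switching), moving to the sparse-Jacobian `lsodes` above 50 states;
  defaults `rtol = 1e-8`, `atol = 1e-12`, overridable per call.
  Ring-oscillator and buffer-binding systems in the test corpus are
  stiff (binding constants up to `1e8`), and these defaults resolve
  them without tuning.
* **Operating point**: damped Newton (step halving, nonnegativity
  projection) to `‖rhs‖∞ ≤ 1e-10`; on stalling, pseudo-transient
  continuation (integrate over growing horizons, then polish with
  Newton). Failures report the best residual reached.
* **Multistability search**: the model's initial state plus
  `n_starts = 32` log-uniform random starts over `[1e-3, 1e3]`
  scaled by the largest initial concentration (or 1), deduplicated at
  `1e-6` relative distance. A state is kept when all eigenvalues of
  the live-dimension Jacobian have real part below `−1e-9·‖J‖` —
  marginal cases are deliberately reported unstable.
* **Stimuli**: `PULSE` (one-shot when frequency is 0, periodic
  otherwise) and `WAVEFORM` (piecewise-constant) add molecule-source
  terms; the integrator is restarted at every discontinuity so no
  event is stepped over.
* **DC sweep** clamps the input at each grid value and warm-starts
  each solve from the previous solution (continuation), which is what
  makes hysteresis observable: forward and reverse sweeps of a
  bistable system follow different branches.
* **Transfer function**: `H(jω) = e_out^T (jωI − J)^{-1} b` at the
  operating point. The default input convention is a unit
  molecule-source at the input node (`b = e_in/V_in`), the current
  analog of the electrical small-signal setup; a unit-concentration
  convention is available via a flag. The one-pole closed form and an
  independent sinusoid-driven transient agree with it in the tests.
* **Truth table**: `2^k` segments in Gray-code order (one input flips
  per boundary) so each transition perturbs the system minimally;
  outputs are read at segment ends.

## SBML interchange

Import (Level 2/3) translates compartments, species (with volumes;
boundary/constant species become `FIX` clamps), global parameters,
reactions (kinetic-law MathML → the expression grammar, with
reaction-local parameters substituted by value), user-defined
functions (inlined at call sites), assignment rules
(parameter-targeted rules become dependent parameters;
species-referencing rules are inlined into every formula that uses
them — dynamically equivalent and representable in the netlist model)
and rate rules (extra source reactions). Identifiers are sanitized to
SId form with a reversible mapping table. Everything else — unit
definitions, algebraic rules, events of any kind, non-integer
stoichiometries — is recorded in the report's `dropped` partition
with a reason, or raises in strict mode; the report covers every
construct of the source document exactly once. Events are not
representable in the package's model container (parameters are
constants after resolution), so even time-only parameter events are
declined rather than approximated.

Export writes Level 3 Version 1: literal parameters as SBML
parameters, dependent ones as assignment rules, one reaction per
netlist reaction with a MathML kinetic law built from its type, and
one extra first-order reaction per species with nonzero degradation
(SBML has no native degradation field). Simulation directives have no
SBML counterpart and are omitted. The export→import round trip
preserves the assembled right-hand side to machine precision on all
fixtures (asserted at `1e-9` in the tests).

## SPICE export

The exporter targets the open-source simulator's behavioral-source
dialect (`B<name> n+ 0 I={...}`), since the rate laws are nonlinear;
`ln` is spelled `log` there. Node names are the species names
uppercased, with an `N_` prefix on reserved-word collisions and a
mapping comment block when any renaming happened. `deck_lint()`
checks node connectivity, the single-analysis rule and `.end`
placement. Running the external simulator is out of scope: the
package's own engine is the reference path, and the deck is plain
text a user can run elsewhere.

## Fixtures and generators

The fixture circuits reproduce published *structures and behaviors*;
the rate constants are package choices placed inside the intended
qualitative regime:

* **Toggle switch** (7 species, 5 reactions): symmetric, `n = 2`,
  `v_max/(d·K) = 10` — comfortably inside the bistable region of the
  mutual-repression model. Enzyme `I1` converts `R2` (and `I2`
  converts `R1`), so injecting `I1` erases state "1" and flips the
  memory to "0"; the readout GFP is repressed by `R1`.
* **Repressilator ring**: mRNA/protein two-stage genes with
  `k_TR = 216`, `K = 1`, `n = 2`, `d_mRNA = 1`, `k_TL = d_protein
  = 0.2` — the classic oscillatory operating point of the
  mRNA–protein repressilator (protein/mRNA lifetime ratio 0.2, strong
  maximal transcription). A 3-gene ring shows sustained, non-damped
  oscillation in the tests.
* **Band detector**: the output promoter is constitutive and
  repressed by two branches — one shut off by the input at a low
  threshold (0.03), one switched on at a high threshold (10) — so
  expression occurs only at intermediate input. This double-repressor
  arrangement is robust under the additive occupancy denominator,
  where a strong activator signal would otherwise swamp repression.
* **AND gate**: output activated by input A and repressed by a
  constitutive protein that input B shuts off; high output requires
  both.
* **Penicillin biosensor (reaction stage)**: 5 species (penicillin,
  penicilloate, H⁺, HPO₄²⁻, H₂PO₄⁻) instantiated in a chamber and at
  two sensor surfaces plus the chamber's penicillinase — 16 species,
  1 enzymatic + 10 diffusion + 3 buffer-binding reactions. Volumes
  make the chamber 100× each surface film; penicillin crosses the gel
  fast (`D = 0.5`) while ions exchange slowly (`D = 0.2`); the buffer
  sits at its pKa (7.2, `k_on/k_off = 10^{7.2}` l/mol) and the
  intermediate dose (2 mM against 10 mM total phosphate) keeps the
  buffer globally unsaturated. The surface proton trace then shows
  the three-phase response — buffered delay, acid excursion, recovery
  toward baseline as the substrate depletes — and pH is computed as
  `−log10[H⁺]` at reporting time, not integrated as a state.
* **Random pathways**: a linear enzymatic chain (the last reaction a
  pure sink) fed by a constant source, plus `M − N` random
  feedback/feedforward enzymatic edges, every reaction catalyzed by a
  random pathway species. Each node carries a first-order dilution
  (`d = 0.1`): a saturable enzymatic sink alone cannot absorb an
  arbitrary influx, and the dilution bounds total mass so the
  generated steady-state problems are always well posed. Generation
  is reproducible from the seed.

What the generators emulate is the *connectivity and kinetics* classes
of real systems, not their parameter heterogeneity: rate constants are
shared across a generated model, there is no cell-to-cell
variability, no noise, and no spatial structure beyond well-mixed
compartments. Passing tests therefore demonstrate correctness of the
translation and numerics, not predictive accuracy for any particular
organism.

## Problem sizes in the checked examples

The test suite and the acceptance script use: 100 random states for
the dynamics-equivalence oracles, 101-point trajectories for the
closed forms, 32 starts for the multistability search, ring GRNs of
3–101 genes for dynamics (204 states integrated at default
tolerances) and 4999 genes for generation-only size checks, and
pathways up to 35 reactions. These sizes make every check rerun in
seconds to a couple of minutes on one core while still exercising the
sparse-solver path.

## Known limitations

* Deterministic ODE semantics only: no stochastic simulation, flux
  balance or elementary-mode analysis.
* Compartments are well-mixed nodes; diffusion is a two-node exchange,
  not a spatial discretization.
* One substrate per enzymatic reaction; cooperative multi-substrate
  kinetics must use a custom (`X`) rate.
* SBML events and algebraic rules are reported, not translated.
* The custom-expression grammar is intentionally small; piecewise and
  trigonometric forms are not part of it.
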