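---
title: "Weaving concerns into gene-circuit designs and their models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weaving concerns into gene-circuit designs and their models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitweaver)
```

## The design model

A circuit is an ordered sequence of typed parts inside nested compartments.
Part and molecule types live in two rooted trees: `Part` with the built-in
categories `Promoter` (and its children `PositivePromoter`,
`NegativePromoter`, `ConstitutivePromoter`), `RBS`, `CodingRegion` and
`Terminator`; and `Molecule` with the built-in child `Protein`. Users declare
concrete subtypes (a specific BioBrick RBS, a transcription factor) at run
time; the subtype relation is ancestor-path membership, and identifier
matching is case-sensitive because BioBrick names are.

Compiling a circuit *linearizes* it: a depth-first, declaration-order walk
produces the execution flow, one step per part addition or molecule
declaration, each carrying its compartment path. Every step is a join point.
Molecule scope follows the compartment semantics: a closed compartment
resolves molecule references only locally, a permeable one also searches its
enclosing compartments, nearest first. We require a root circuit — molecules
cannot float outside any compartment.

## Point cuts and the signature language

A part signature is

```
['!'] [compartment '.' ...] name ['+'] [ '(' molecule-signature ')' | '()' ]
```

`*` matches any substring; `+` after a type name includes all subtypes; `()`
requires the part to have *no* associated molecule; a molecule signature in
parentheses requires at least one associated molecule to match, where a
part's associated molecules are its regulators plus its coded product. `%`
chains signatures over consecutive parts in one compartment; the match
context is the part matched by the last element of the chain.

Choices worth making explicit, because the grammar alone does not fix them:

* A bare type name matches that exact type; `+` is what extends it to
  subtypes.
* A name pattern is tried against the instance name first, then the type
  name, so a part *named* "Promoter" of type RBS would match the signature
  `Promoter`. This is a documented caveat, not a feature to rely on.
* Compartment chains match as a *suffix* of the part's full path, so
  unqualified signatures select across all compartments.
* `!` inverts the entire signature, so negation is exactly complementation
  over a flow — a property the test suite checks on randomized circuits.
* `%`-adjacency never crosses compartment boundaries.

## Weaving

`weave()` replays the design and, at each join point, applies every matching
advice in rank order: priority (descending), then position of the aspect in
the weave call, then declaration order within the aspect. At most one
`replace` advice fires per join point — the highest-ranked — and it receives
the replaced part in its context so regulation links can be copied. `before`
and `after` insertions bracket the element in rank order.

Parts inserted by advice are themselves join points for *other* advice
evaluated later at that position, but never re-trigger the advice that
inserted them; a weaving-depth cap (10 rounds of insertions) turns runaway
mutual triggering into an explicit cyclic-advice error naming the aspects
involved. This recursion policy is what lets aspects compose — the
repressilation aspect's inserted oscillator genes still receive RBS and
terminator parts from the design-rules aspect — while guaranteeing
termination. Structural weaving completes before any type advice runs, in
aspect order, because models must be built from the final design; a part can
carry many properties but the same property name may be set only once.

Provenance is total: every woven part records the aspect that inserted it
(or `"design"`), and dropping all advice-inserted parts while undoing
replacements recovers the declared flow exactly.

## Model generation

A regulation map links every coding region to its driving promoter: the
nearest preceding promoter in the same compartment with no intervening
terminator, so one promoter can drive an operon of several coding regions.
Orphan coding regions are structural errors.

Three kinetic strategies generate a reaction network from the map:

* **Protein-level mass action.** Each regulated promoter gets a reversible
  regulator-binding pair written as two irreversible reactions; the active
  promoter state (free for repressed promoters, each activator-bound state
  otherwise) catalyses protein synthesis; every coded protein degrades. One
  rate parameter per reaction, mass-action rate laws throughout. For the
  three-gene repressilator this gives 9 species and 12 reactions.
* **RNA + protein mass action.** As above with expression split into
  transcription and translation and an mRNA degradation per gene (12
  species, 18 reactions for the repressilator).
* **Shea–Ackers RNA.** No explicit promoter states; each promoter
  transcribes at `k_tx (a0 + Σ a_i K_i A_i^n) / (1 + Σ K_i A_i^n + Σ K_j
  R_j^n)`. The functional form is our instantiation of the occupancy
  formalism: `a0` defaults to 1 for repressor-only promoters and 0 when
  activators are present (no basal leak unless configured), and the
  cooperativity `n` defaults to 2 — the value needed for repressilator
  oscillation and toggle bistability with this form.

Under mass action, activator-bound promoters do not transcribe basally by
default; this is configurable. Degradation is generated for every mRNA and
protein species; promoter states are never degraded. Parameter naming is
deterministic and descriptive (`k_bind_P1_TF3`), and defaults are shipped so
every generated model simulates out of the box.

Models export to SBML Level 3 Version 1 (written and re-read with `xml2`,
rate laws as MathML); the exporter checks structural constraints — unique
ids, every symbol in a rate law defined — and the import path exists so
round-trips can be verified. Stoichiometry matrices, plain-text reaction
listings and CSV are also available.

## Rule-based models

The rule-generation aspect emits an agent/site model: promoters are agents
with an operator site, repressors have a DNA-binding site, and per gene the
schema instantiates repressor bind/unbind, transcription from the free
promoter, translation, mRNA degradation and free-protein degradation — a
promoter-bound repressor must unbind before it degrades (an optional extra
rule category is deliberately omitted in this version). Activator-regulated
promoters are outside this schema and are rejected explicitly. The
instantiated count is `4·genes + 2·regulated promoters`; the three-gene
repressilator yields 18 rules. (Counting conventions for rule models differ
— e.g. whether reversible rules count once or twice — so published totals
for equivalent models can differ by one or two; ours is fixed by the formula
above.) Export is a deterministic Kappa dialect with agent signatures,
labelled rules, `%init` and `%obs`; the package ships a parser for this
dialect that checks agent declarations and bond pairing, and the schema has
no polymerisation, so every rule model grounds to a finite mass-action
network for stochastic simulation.

## Context transforms

Growth contexts add a population species `N` with `dN/dt = μN` (exponential)
or `μN(1−N/K)` (logistic); lag-logistic growth adds a non-viable
subpopulation `N_dead` decaying at rate `d`, our instantiation of a verbal
description of early optical-density dips — the population model is a
package design choice, flagged as such. Every intracellular species is
diluted at the instantaneous per-capita growth rate; promoter states are not
diluted by default (DNA copy number per cell assumed constant),
configurable. Observables `OD = N (+ N_dead)` and `total_fluorescence =
[GFP]·N` are registered (maturation kinetics omitted). The transform never
touches a core reaction: the core model's reactions are a subset of the
transformed model's, checked by canonical fingerprints.

Protease coupling merges two models under `sw_`/`osc_` prefixes and replaces
the two tagged species' first-order degradations with competitive saturable
terms sharing one pool, `γV[A]/(Km+[A]+[X])` and `δV[X]/(Km+[A]+[X])`. The
form is monotone: raising either competitor strictly lowers the other's
degradation rate.

## Simulation and detectors

ODE integration uses `deSolve::lsoda` at tolerances 1e-8/1e-10; scenario
events (inducer addition) are instantaneous set/add operations applied
exactly at their times — a mechanism chosen because only the event *time* is
specified in the systems we reproduce. The SSA is the exact Gillespie direct
method with combinatorial propensities, reproducible under a seed, with the
caller's RNG state restored.

The oscillation detector discards the first 20% of a window as transient and
requires at least 100 remaining points, then classifies a signal as
oscillating when it has ≥5 maxima with prominence above 10% of the signal
range and inter-peak intervals with coefficient of variation below 0.2.
These four thresholds are detector policy, configurable, and chosen once:
5 peaks excludes damped transients, the prominence floor ignores solver
ripple, and the CV bound demands a stable period.

## The switchable oscillator

The shipped case study couples a bistable toggle switch and a
positive/negative-feedback oscillator through a shared protease. The toggle
is two mutually repressing proteins `A` and `B`; the external inducer is
modelled as a second repressor of the `B` gene — the way IPTG inactivates a
repressor — because under the occupancy form an activator on the `A`
promoter cannot overcome `B`-squared repression with plausible association
constants. The oscillator is one hybrid promoter (activated by AraC,
repressed by LacI) driving AraC, LacI and GFP. Both cores are generated with
the Shea–Ackers strategy.

Parameter sets are shipped, found by coarse grid search over the generated
models (no fitting machinery is included, by design). The working regime is
an *overloaded protease*: before induction `A ≈ 0`, so the protease
concentrates on tagged AraC, pinning the oscillator at a fixed point; after
induction `A`'s production exceeds the protease capacity `γV`, `A`
accumulates quasi-linearly (nothing dilutes it — growth-rate effects are
deliberately absent from these models), and the effective AraC degradation
`δV/(Km+A+AraC)` falls into the oscillator's permissive band, restoring the
limit cycle. `δ/γ ≈ 1300`, i.e. the protease must act far more strongly on
the oscillator species than on the switch protein. Tagging GFP instead
leaves the oscillator core untouched, so the readout already oscillates
before induction and the pre/post criterion fails — reproducing the
qualitative asymmetry between the two tagging choices.

The robustness check perturbs the shipped *coupling* set (`V`, `Km`, `δ`,
`γ`) by ±20% on 20 Latin-hypercube draws and requires the pre/post
classification to survive every draw; the core-concern rate constants are
not perturbed, since they play the role of the externally fitted parameter
sets that are out of scope here. The reference scenario runs to 420 min with
the inducer set at t = 90 min, the switch started in the low-`A` state and
the oscillator started on its limit cycle (so that window-based detection is
meaningful on both sides of the event), sampled every 0.5 min.

## What the synthetic fixtures do and do not show

The randomized circuit generator produces structurally valid designs —
well-formed transcription units, resolvable molecule scopes, bounded size —
with known ground truth for the signature matcher (a brute-force oracle
enumerating the path/name/molecule conditions). It emulates none of the
things that make real designs hard: sequence context, part crosstalk,
realistic parameter values or load effects. Green property tests therefore
certify the *machinery* (matching, weaving, counting, conservation), not
biological predictive power. Problem sizes used throughout the suite — 200
oracle circuits, 100 invariant draws, 100 birth–death runs, 50 mean-field
runs, 20 hypercube draws — are the package's chosen defaults and keep the
full suite under a minute on a laptop.

## Known limitations

* Multi-regulator promoters under the mass-action strategies bind one
  regulator at a time (no combined occupancy states); the Shea–Ackers
  strategy is the intended route for hybrid promoters.
* The design-rules aspect duplicates an RBS or terminator that is already
  present — deliberate, as the simplest statement of the rule.
* Two genes coding for the same protein share one mRNA species in the
  generated models.
* The Kappa dialect covers the emitted schema only (no polymerisation, no
  algebraic rates).
* Transcription/translation and molecule-bonding join points are represented
  in the data model but not dispatched by the weaver.
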