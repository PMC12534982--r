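---
title: "Methods: expression-constrained flux analysis and inhibition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-constrained flux analysis and inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxkin)
```

fluxkin re-implements, as a tested pipeline, the computational core of a
DHODH-inhibitor study design: genome-scale metabolic modeling constrained
by transcriptomics (with flux variability analysis, differential flux and
knockout transformation scoring) on one side, and enzyme-inhibition
analysis (IC50 fitting, Cheng–Prusoff Ki, inhibition-mode classification,
thermal-shift Tm) on the other. This vignette documents the models, the
tunable parameters, the numerical choices and the limits of what the
synthetic data can show.

## The constraint-based model and its curation

A `metabolic_model` is a stoichiometric network: metabolites, reactions
with flux bounds in mmol·gDW⁻¹·h⁻¹, gene–protein–reaction (GPR) boolean
rules, and a biomass objective reaction. Reversibility is encoded solely
by `lb < 0`; there is no separate flag, so directionality has a single
source of truth. Internally everything is indexed in declaration order;
all exported tables are keyed by string ids so external consumers never
depend on ordering.

Curation follows two steps. **Dead-end elimination**: a metabolite that
cannot both be produced and consumed (counting a reversible reaction as
both producer and consumer of every participant) can never carry
steady-state flux; `prune_dead_ends()` removes such metabolites together
with every reaction touching them, iterating to a fixpoint because
removals cascade. The operation is idempotent and independent of
declaration order, and refuses to remove the objective reaction.
**Sink insertion**: `add_sink_reaction()` appends a pseudo-reaction
`{metabolite: -1}` with reversible default bounds `[-1000, 1000]`, so a
sink can add or remove an intracellular metabolite — the probe used to
read net production or consumption of species such as orotate or DHO.

The order of the two steps is not canonical; the pipeline defaults to
prune-then-sink, because a sink inserted first would mask a genuine dead
end, and both stages are callable separately for the other order.

## Expression integration

Expression data enter as a gene-by-sample table. `normalize_expression()`
scales each sample to the mean library size, then divides each gene by
its mean across control samples, so control genes average 1 and treated
values read directly as fold changes against control. This anchoring
makes the downstream treated-versus-control flux comparison well posed:
control models approximate the unconstrained baseline. Genes with zero
control mean are set to 0 and flagged rather than producing infinities.

`evaluate_gpr()` maps a profile through a reaction's GPR tree: AND nodes
combine subunit values with `min` by default (a complex is limited by its
scarcest subunit), OR nodes with `max` (the best-expressed isoenzyme
carries the reaction). `mean`/`sum` are offered because several
condition-specific modeling methods sum isoenzyme contributions; the
choice is a config knob (`integration_config()`), not a guess baked into
the code. Genes missing from a profile default to the neutral value 1 so
absent annotation never silently blocks a reaction.

Bounds are then rescaled multiplicatively:

    lb'(i) = lb(i) * gamma * expr(i)
    ub'(i) = ub(i) * gamma * expr(i)

with `gamma = 2` by default. The rescaling is implemented literally: the
factor `f = gamma * expr` is non-negative, so signs are preserved,
`lb' <= ub'` always holds, an irreversible reaction stays irreversible,
`f = 0` blocks a reaction outright, and `f > 1` *widens* bounds. An
optional `cap_factor` clips `f` for users who prefer a
tightening-only reading. Reactions without a GPR receive the neutral
expression 1 (provenance-labelled `no-gpr-neutral`), so at `gamma = 2`
their bounds double along with everything else; because the same factor
applies to both conditions it cancels from every fold change. Since no
directional expression information exists, reversible reactions are
scaled symmetrically in both directions.

## FBA, FVA and differential flux

`optimize_biomass()` solves the flux balance LP
`max c'v  s.t.  S v = 0, lb <= v <= ub`. Flux variability analysis then
minimizes and maximizes each reaction flux subject to the same
constraints plus the biomass constraint `c'v = alpha * fmax`. The biomass
constraint is an **equality** by default, with a config switch to the
common `>=` relaxation; at `alpha = 1` the equality pins biomass at its
optimum in every extreme solution.

All LPs go through a bounded-variable two-phase dense simplex written for
this package (pivot tolerance 1e-9, Bland's rule for anti-cycling,
deterministic declaration-order variable ordering), so results are
bit-reproducible across runs on the same platform. The problems here are
tiny — tens of variables — so a dense basis refactorization per iteration
is well inside budget. The test suite cross-checks every FVA range
against an exact, solver-independent oracle: brute-force enumeration of
the vertices of the flux polytope (all bounds are finite, so the polytope
is bounded and a linear objective attains its optimum at a vertex).

For the differential table, each condition's per-reaction FVA interval is
summarized by its **midpoint**; the interval endpoints are also exported
so users can re-derive alternatives (min, max) — which summary the
original heatmaps displayed is not knowable, so all three are emitted.
Per-sample FVA ranges are averaged within condition before fold change,
and the per-sample tables are written alongside. The fold change is
guarded: with `eps = 1e-6` times the largest interval magnitude, entries
whose control midpoint is within `eps` of zero are flagged
`near-zero-denominator` and excluded rather than reported as huge ratios,
and a midpoint sign flip is flagged `sign-flip` rather than given a
meaningless negative ratio.

## Knockouts: MOMA and the simplified robust transformation score

A gene knockout disables every reaction whose GPR evaluates false with
that gene removed. The post-knockout flux state is predicted by
**minimization of metabolic adjustment**: the quadratic program
`min ||v - ref||²  s.t.  S v = 0, bounds, v_disabled = 0`, solved with
`quadprog`. Disabled reactions are eliminated from the QP by column
deletion (not extra equality rows) and the problem is rescaled to unit
bounds; both choices keep the active-set solver away from spurious
degeneracy failures. Feasibility of the knockout is established by an LP
first, so a genuine infeasibility is still detected and reported. A
second prediction engine re-maximizes biomass after the knockout (FBA
knockout); its deterministic simplex vertex is used as the predicted
state.

The transformation score asks whether a knockout moves the source
(treated) flux state toward the target (control) state. Per reaction, the
desired direction is `d_i = sign(target_mid - source_mid)` with a dead
band `tau` (default `1e-3` times the largest bound, so noise-level
changes never count); the achieved change is `a_i = v_i - source_mid`.
Successes move at least `tau` in the desired direction (or hold still
where no change is desired); violations move at least `tau` against it.
Contributions are weighted by the magnitude of the desired change (`1/n`
for steady reactions) and the score is normalized by the total weight so
it lives in `[-1, 1]`: a prediction matching the target midpoints scores
exactly +1 and a fully opposed one -1. Without the normalization, the
stated extremes would be unreachable whenever steady and moving reactions
coexist — that is the one place this implementation departs from a purely
literal reading of the score's definition, in favor of its stated
extremes. The published robust-transformation machinery (bTS/wTS/rTS) is
**not** reproduced — its exact weights live in a separate reference — but
its worst-case principle is honored: `robust_score = min(ts_MOMA,
ts_FBA)`, and outputs are labelled `simplified-rMTA`.

The MOMA reference must satisfy `S v = 0`, which FVA midpoints need not;
the reference is therefore the feasible vector closest to the source
midpoints (the same QP with no knockout). Ranking sorts by robust score
descending, ties broken lexicographically, and genes whose knockout is
infeasible are reported with a `-Inf` sentinel rather than dropped.

## Enzyme kinetics

Dose–response data are fitted to `V = Vmax / (1 + (I/IC50)^h)` by
Levenberg–Marquardt least squares, parameterized in `log(IC50)` and
`log(h)` so positivity is structural rather than enforced by bounds; the
IC50 start value comes from the half-maximal crossing on the log10
concentration axis. `I = 0` rows enter the fit directly (the model gives
exactly `Vmax` there) and anchor the plateau. The slope `h` is free by
default because nothing fixes it to 1 a priori. Designs with fewer than
5 distinct positive concentrations, or flat activity, return
`converged = FALSE` with a diagnostic instead of a number.

For a competitive inhibitor the apparent IC50 rises with substrate as
`IC50(S) = Ki (1 + S/Km)` (Cheng–Prusoff); for an uncompetitive one it
falls as `Ki (1 + Km/S)`. `classify_inhibition_mode()` reads the trend
from the fold shift `IC50(S_high)/IC50(S_low)` with a relative dead band
`rel_tol = 0.25` — chosen as typical inter-assay IC50 variability and
config-exposed — calling competitive above `1 + rel_tol`, uncompetitive
below its reciprocal, indeterminate between. A Ki is derived only for a
competitive call with an explicit Km; the Km is never defaulted, because
published Km values for this enzyme differ between constructs and the
choice belongs to the user.

Melt curves (350/330 nm fluorescence ratio versus temperature) yield Tm
by two methods. The default derivative method smooths the ratio with a
5-point Savitzky–Golay filter, differentiates, and localizes the
derivative peak with a quadratic fit over a ±2.5 °C neighborhood —
roughly one transition half-width; a 3-point parabola through the raw
peak transmits grid-level noise directly into the vertex, while the wider
window averages it out. The Boltzmann method fits a two-state sigmoid
with linear pre- and post-transition baselines and reports its midpoint.
Flat or featureless curves raise a "no transition detected" error in
both. `delta_tm()` is the signed difference holo − apo, positive for
stabilization.

## Synthetic data: what it emulates and what it does not

The toy pyrimidine network (16 reactions, 12 metabolites, 9 genes) is
hand-specified, not random, so closed-form expectations exist for every
test. It mirrors the interrogated biology: glutamine uptake feeding a
lumped CAD step to dihydroorotate; the DHODH reaction coupled to a
ubiquinone/ubiquinol cycle closed by a lumped ETC step; UMPS and a
nucleotide kinase to UTP; a uridine salvage branch entering at UMP;
glycolysis to lactate; a glutathione branch; and a biomass reaction
consuming UTP, pyruvate and GSH. Two structural choices carry the
design:

* the nucleotide kinase capacity (`ndpk_ub = 8`) sits *below* the
  combined de novo + salvage capacity, so the control state has slack in
  the salvage branch while a DHODH-constrained state must run salvage at
  full capacity — the flux signature of uridine rescue, and the reason a
  salvage-kinase knockout scores as the best reversion of the treated
  state;
* the built-in orotate and GSH sinks are forward-only (`lb = 0`).
  A reversible orotate sink could conjure orotate from nothing, so a
  DHODH knockout would not abolish biomass and the salvage-rescue logic
  would be unfalsifiable. User-added sinks keep the reversible default;
  only the toy's built-ins are restricted.

Expression noise is lognormal (positive, multiplicative), with the
treated condition applying a multiplicative effect per gene — the default
scenario is a 5-fold DHODH knockdown (`effect 0.2`) with three replicates
per condition, matching a small treated-versus-control design. Assay
activities follow the competitive or uncompetitive steady-state rate law
with lognormal noise; melt curves follow the two-state sigmoid with
optional linear drifts and gaussian noise. Every generator is a pure
function of its configuration and seed (default seed `20250233`,
recorded in outputs).

What passing these tests does **not** show: the toy network has no
compartments, no cofactor stoichiometry beyond the quinone pair, no
thermodynamic constraints, and a biomass of three terms — conclusions
about a curated human genome-scale model's specific fluxes do not follow.
The expression generator draws genes independently (no co-regulation, no
count overdispersion structure), and the assay generator assumes the
classical rate laws hold exactly (no tight-binding depletion, no slow
binding). The pipeline's correctness claims are therefore about the
*method implementations*, validated against closed forms and brute-force
oracles at small scale.

## Problem sizes and tolerances used in validation

The test suite checks FVA against exact vertex enumeration on 100 random
models of up to 8 reactions (agreement within 1e-6); MOMA against
closed-form chain/diamond cases and against 10⁴ random feasible samples
per model; IC50 recovery at 1% (noiseless closed form) and a 10% median
bound over 100 Monte-Carlo seeds at 2% multiplicative noise; mode
classification over 50 competitive plus 50 uncompetitive random parameter
draws; and Tm recovery within 0.1 °C noiseless and 0.3 °C under noise
with baseline drift. These sizes keep the whole suite under a minute of
LP time while exercising every degenerate case the fuzzers have found.

## Known limitations

* The LP solver is a dense simplex intended for networks of tens to a
  few hundred reactions; genome-scale models (thousands of reactions)
  would need a sparse revised simplex or an external solver behind the
  same interface.
* FVA here is not loopless; thermodynamically infeasible cycles, if
  present in a user model, widen ranges.
* The knockout score is the simplified worst-case described above, not
  the published bTS/wTS/rTS statistic; rankings agree in spirit, not
  necessarily in value.
* SBML support is read-only and limited to Level-3 FBC bounds, gene
  associations and the active objective; COBRA-style JSON is the
  canonical round-trip format because fixtures must be hand-writable.
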