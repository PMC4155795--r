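---
title: "arborsim: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arborsim: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`arborsim` grows virtual neuronal morphologies by simulating
phenomenological growth cones, called *fronts*. A front has a dual
identity: it is a physical object (a position and a radius, in
micrometers) and a small automaton that, once per clock tick, decides to
**extend** (one child front), **branch** (two children), or **terminate**.
The piece of neurite between a front and its parent is a *segment*,
collision-tested as a capsule: a line segment inflated by the child
front's radius. Growing many neurons simultaneously in one substrate
makes the morphologies *context-aware*: space that is already occupied
cannot be grown through, and every collision is either resolved by a
small random displacement or ends that branch.

The simulated substrate is an axis-aligned box `[0, dims)` tiled by a
grid of half-open sub-volumes (SVs). Each SV owns the fronts and segments
whose distal endpoint lies inside it. During one centrally clocked step,
every SV (in fixed lexicographic order, each with an RNG substream keyed
by seed, step and SV id) updates its active fronts in randomized order:

1. the front's growth rule proposes children from the *local context* —
   segments and secreted guidance entities in the host SV and its 26
   neighbors, partitioned into same-neuron / same-type / other, plus one
   averaged summary per cue name for anything farther away;
2. each proposed child is validated with the capsule test against every
   committed segment in the neighborhood, excluding only the parent
   segment and siblings sharing the proximal endpoint. A conflict
   triggers up to `resolution_attempts` (default 10) random
   perturbations, uniform in a ball whose radius defaults to the new
   segment's radius; if none resolves it, the proposal is dropped and the
   front becomes a terminal tip;
3. accepted children are committed, registered in (migrated to) the SV
   that contains them, and their new segments are scanned for *putative
   synapses*: any segment of another neuron whose surface gap (axis
   distance minus the two radii) is at most `synapse_max_distance`
   (default 2 um) yields one record at the closest-approach midpoint.

Because a front lives for exactly one update, each morphology is a rooted
tree by construction, and because overlap checks always run against all
previously committed segments, a post-hoc brute-force all-pairs audit
(`audit_overlaps()`) finds zero overlaps — that is the engine's headline
structural guarantee, and it is asserted, not assumed, in the test suite.

## Direction composition

A child's direction is the normalized weighted sum of cue vectors:
current heading, repulsion from the soma or from same-neuron segments
(the weighted sum of unit vectors from segment midpoints to the front,
weights `exp(-d/scale)`), attraction toward the superficial surface or
the pia (weighted by `exp(-d/scale)` of the pia distance), and a random
unit vector. The exponential form mimics the gradient of a secreted
molecule; the decay length `scale` is a per-cue parameter. A degenerate
(near-zero) sum falls back to a uniformly random unit vector so growth
never stalls silently.

Two geometric choices are the package's own:

* **Bifurcation angle.** Branch children are split symmetrically about
  the composed direction by a per-rule `branch_angle` (50–60 degrees), in
  a random plane through it. Without a guaranteed divergence the two
  siblings start collinear, overlap one step later (sibling exclusion no
  longer applies to their children), and both lineages die immediately.
* **Stem placement.** Stems are placed at `soma_radius + stem_radius`
  from the soma center rather than exactly on the soma sphere: the
  overlap test is strict (`distance < r1 + r2`), and a stem exactly on
  the sphere would make every grandchild segment overlap the soma
  capsule. Random stem directions are kept at least ~25 degrees apart.

## The three shipped rule sets

**Motor** (`motor`): 12–14 stems in random directions; thereafter a front
bifurcates with probability `min(1, branch_base/order)` (inversely
proportional to centrifugal order), terminates with a small fixed
probability or on leaving the substrate, else extends. Direction =
heading + soma repulsion + random.

**Granule** (`granule`): exactly two stems aimed at the superficial
surface; branching decreases with order (see below); direction = heading
+ same-neuron repulsion + superficial attraction + random.

**L5 pyramidal** (`pyramidal_soma` / `_basal` / `_apical` / `_oblique`):
the soma makes 5–7 basal stems (downward/lateral) plus exactly one apical
stem aimed at the pia. Basal fronts behave like motor fronts with a hard
branching cap above order 6. The apical trunk dispatches on the laminar
layer: in L5/L4 it extends toward the pia while oblique dendrites sprout
sideways with a per-layer probability and grow away from their stored
sprout point; in L3–L1 fronts branch with layer-specific probabilities as
long as the order increase within the current layer is below a per-layer
budget, may terminate stochastically, and terminate unconditionally
within 35 um of the pia.

## Parameters: units, defaults, provenance

All lengths are micrometers; probabilities are per update (one update
advances a front by `step_length`: 20 um for motor, 10 um otherwise).
The *functional forms* above follow the published description of each
cell class. The *numeric constants* are not recoverable from the source
material (the growth-rule listings are reproduced there only as images),
so the shipped defaults in `R/params.R` were calibrated **once** against
the published population medians (branch points, tip Euclidean
distances, total length, max order for the apical tree) and frozen;
`PARAMS_VERSION` is bumped if any value changes. Calibration notes:

* Granule branching uses `branch_base/order^2` (`branch_decay = 2`).
  The source only states that granule branching *decreases* with order;
  with exponent 1 no parameter choice reproduced branch-point count,
  total length and max order (5) simultaneously — branching has to be
  proximal, with long terminal runs toward the superficial surface.
* Oblique dendrites use a *flat* per-step branch probability. Their
  global centrifugal order is inflated by the trunk's sprout events
  (every sprout is a branch event for the trunk), so any `1/order` form
  would forbid oblique ramification entirely.
* The apical tuft is seeded by a near-certain "main bifurcation": a high
  branch probability (0.5) with a per-layer order budget of 2 in L3.
  This reduces the (large) run-to-run variance of the tuft cascade.

Substrate geometries for the shipped configurations: the granule forest
is 1300 x 300 x 225 um with 100 somata; granule isolation uses the
forest volume scaled down 20-fold (130 x 300 x 112.5 um), keeping the
full 300 um depth; motor isolation is a 1400 um cube (the box bounds,
together with volume-limited termination, set the tip-distance scale);
pyramidal setups use a laminar substrate with the pia at depth 1400 um
and boundaries L1 1300, L2 1150, L3 1000, L4 850 (somata at the top of
L5, 790–850 um). Layer geometry is only constrained loosely by the
source figures; these values were chosen once, with the apical tip
distances in mind, and frozen.

Depth axis: granule setups treat y as depth (superficial surface at max
y); pyramidal setups use z (pia at z = 1400), matching the printed
substrate dimensions. `laminar_structure()` carries an explicit
`depth_axis` field, so this is configuration, not code.

## What the generator does and does not emulate

A green stochastic test establishes that the *population medians* of the
generated trees match the published ones within the printed median
absolute deviations, that populations are reproducible from a seed, and
that the structural invariants (zero overlap, single rooted tree per
neuron, order bookkeeping, pia stop, branching caps) hold. It does not
establish biological realism of individual branches: tortuosity is a
byproduct of the per-step random component, radii follow a simple taper
(0.96–0.97, floor 0.3 um) rather than Rall-style relations, and axons,
spines, somatic geometry beyond a sphere, and explicit molecular
diffusion are not modeled. One known qualitative difference: in the
forest setting our granule cells come out slightly *larger* than in
isolation (isolated cells are wall-limited, forest cells can wander into
neighbors' territory), whereas the source reports slightly smaller
forest cells; only the forest's morphology count and zero-overlap audit
are acceptance-graded.

## Numerical choices

* Segment–segment distance uses the standard clamped closest-point
  algorithm; the parallel-overlap case returns the midpoint of the
  overlapping parameter interval, so closest-approach points are unique
  and deterministic. The test oracle is an independent dense-grid
  minimization (2001 x 2001 parameter grid, agreement to 1e-3).
* Overlap is strict: `distance < r1 + r2`. Equality is not an overlap,
  which is what makes the stem-placement convention exact.
* Unit-norm tolerances are 1e-9; degenerate direction sums below 1e-12
  trigger the random fallback.
* Half-open SV boxes and layer intervals; points on the global maximum
  boundary clamp to the last SV. The SV grid is auto-sized so each edge
  is at least twice (max soma radius + step length), capped at 40,000
  SVs; this guarantees host + direct neighbors cover every segment a new
  front could touch.
* Per-(step, SV) RNG substreams make runs bitwise reproducible for a
  fixed seed regardless of how many SVs are occupied; SVs commit in
  lexicographic order, and later commits see earlier ones, so same-step
  cross-SV overlaps cannot slip through.
* If a bifurcation loses one child to a conflict, the survivor is
  demoted to its parent's order: engine orders therefore always equal
  topological centrifugal orders (soma 0, stems 1, +1 below each branch
  point; a multifurcating soma is not a branch point).
* `summarize()` reports the raw (unscaled) MAD and type-7
  linear-interpolation quartiles; both conventions are frozen so
  comparisons are internally consistent.

## Known limitations

Synapse records are geometric proximity candidates ("Peters' rule"
style), not pruned or validated contacts. The engine is single-process;
the multi-agent architecture survives as the SV scheduler contract, not
as a transport. Medians of 10-replicate pyramidal populations remain
noisy (the published MADs — 10 branch points on a median of 40.5 — show
the same), so an unlucky seed can move a single apical target a few
percent outside a tight band while remaining within the printed MAD.
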