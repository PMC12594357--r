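---
title: "Curve-skeleton pore networks and graph-based mineralization: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curve-skeleton pore networks and graph-based mineralization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poreskel)
```

This vignette documents the models implemented in `poreskel`, the assumptions
behind them, and the numerical and design choices a maintainer should know
about. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Conventions

Voxel grids are logical 3D arrays indexed `(i, j, k)`, 1-based in R, `i` the
fastest axis in raw files; "planes" are constant-`k` slices, which is the
axis used by the plane-injection calibration benchmark. The pore object uses
26-connectivity and the background 6-connectivity — the standard dual pair
without which the topological tests below would be unsound. The array border
is background. All geometry is computed in voxel units; the voxel edge length
(`resolution`, µm) enters only when reporting physical volumes, areas and
distances and when converting the diffusion coefficient. This keeps the
discrete topology code free of floating-point drift.

## Curve skeletonization

The skeleton is obtained by homotopic thinning. A pore voxel is deletable
when

1. it lies on the boundary of the pore set (has a background 26-neighbour);
2. it is not an ending point — it has at least two pore 26-neighbours
   (isolated voxels are likewise never deleted, which preserves single-voxel
   components);
3. removing it leaves the Euler characteristic `χ = V − E + F − O` of the
   cubical complex unchanged;
4. removing it leaves the number of 26-connected components unchanged.

Conditions 3–4 are evaluated on the 3×3×3 neighbourhood. For `χ` this is
*exactly* the global condition: every complex cell incident to the centre
voxel lies inside the block, so the local difference equals the global one.
For the component count the local test asks whether the 26 neighbours form a
single 26-connected component; when they do, deletion cannot disconnect
anything globally, and when they do not, deletion either splits a component
or changes the cycle structure, which condition 3 detects. The test suite
verifies the local test against a brute-force global recomputation of `χ`
and component count on random volumes.

**Deletion order.** Thinning results are known to depend on the order in
which boundary voxels are considered. Each pass collects the current boundary
voxels, sorts them by *ascending 26-neighbour count* (ties broken
lexicographically in `(i, j, k)`), and attempts deletions sequentially
against the already-updated volume; passes repeat until a fixed point. The
weakest-connected-first order was chosen after comparing several
deterministic orders (plain and reverse lexicographic, alternating, parity
subfields, distance-transform-ordered): it is the only one tried that never
froze transient one-voxel spurs behind the ending-point protection, so a
solid tube thins to a simple path with exactly two endings and a solid torus
to a closed curve in which every voxel has exactly two neighbours. Any fixed
order preserves homotopy; this one also gives geometrically clean skeletons,
and the choice is deterministic, so results are reproducible bit-for-bit.

No pruning or λ-simplification of short branches is performed: in saturated
porous media small pores hold water and support diffusion, so removing them
would change the physics, not just the cosmetics.

The Euclidean distance transform (exact, via separable lower-envelope
passes) is provided as a diagnostic; the thinning itself does not consume it.

## Branches, partition, graph

Skeleton voxels are classed by their 26-neighbour count within the skeleton:
*ending* (≤ 1), *simple* (2), *interior* (> 2). Branches are the 26-connected
components of the simple voxels. Ending and interior voxels sit at branch
extremities and must still be owned by exactly one branch, because region
assignment measures distances *to branches*: an ending voxel joins its unique
neighbour's branch, an interior voxel the adjacent branch with the smallest
id, iterated until stable; leftover clusters with no reachable branch
(isolated voxels, junction-only blobs such as a tiny "+") become their own
branches. Branch ids follow the lexicographic order of each branch core's
minimal voxel — an arbitrary but reproducible convention.

Every pore voxel is assigned to the nearest branch (exact Euclidean feature
transform per branch, strict-improvement running minimum, so distance ties go
to the smallest branch id). Nearest-sets are occasionally disconnected; they
are split into 26-connected components (the count of such splits is logged),
which guarantees the defining invariant of the whole approach: **the region
labels partition the pore set exactly** — no voxel loss, unlike
primitive-based approximations. The geodesic-distance alternative to
splitting is out of scope.

The graph is built in one pass over the label image, examining only the
three positive-direction neighbours of each voxel, so adjacency is
face-based (6-connectivity): edge- and corner-contacts carry no area and
create no arc. Contact surfaces are stored as integer face counts and
converted to µm² only on export. Arc length is the distance between region
inertia centres, floored at one voxel: interlocking regions can bring
centroids arbitrarily close, and the diffusion coupling divides by this
distance. The floor is logged when applied.

## Microbial mineralization on the graph

Per node, five carbon pools (µgC): microbial biomass `MB`, dissolved organic
matter `DOM`, soil organic matter `SOM`, fresh organic matter `FOM`, and
CO₂. The reaction update over `δt` (operator splitting: reaction first, then
diffusion; only DOM diffuses) is

- growth: `v_DOM · c/(K_DOM + c) · MB · δt` from DOM to MB, with
  `c = DOM/v` the DOM concentration at the start of the step;
- mortality: `μ · MB · δt`, fraction `β` to DOM and `1 − β` to SOM;
- respiration: `ρ · MB · δt` to CO₂;
- hydrolysis: `v_SOM · SOM · δt` and `v_FOM · FOM · δt` to DOM.

All terms cancel pairwise, so carbon is conserved to machine precision.
Defaults (units per day) are the *Arthrobacter sp. 9R* set used for soil DOM
degradation: `v_DOM = 9.6`, `K_DOM = 0.001`, `ρ = 0.2`, `μ = 0.5`,
`β = 0.55`, `v_SOM = 0.001`; FOM is supported in code but default scenarios
set `FOM = 0` and `SOM₀ = 0`, tracking DOM and SOM only. `K_DOM` is a
concentration and therefore unit-bound to µgC/voxel³; scenarios at a
physical scale should convert it consistently with their resolution.

Two guards replace silent clamping (which would destroy conservation): the
step requires `(ρ + μ)·δt < 1`, and any pool driven negative aborts with the
offending node and the admissible step. The binding constraint in practice
is the Monod drain: a step is safe when `v_DOM·δt·MB < K_DOM·v + DOM` at
every node, which is why scenario tests integrate fast growth phases at
finer steps (e.g. 300 s) than slow tails (3600 s).

**Units.** Rates are per day; `δt` is supplied in seconds and converted
internally (1 d = 86 400 s); volumes are voxel³; the diffusion coefficient
`dc` is in voxel²/day, with `dc_voxel_day()` converting from cm²/s given the
resolution (6.73·10⁻⁶ cm²/s at 24 µm ≈ 1.0·10⁵ voxel²/day).

**Diffusion.** Each arc carries an exchange volume
`Θ_ij = α · D_c · s_ij · δt / d_ij`. The diffusive overall conductance `α`
multiplies the Fick flow identically in both schemes — the calibration below
is meaningless otherwise. The implicit (backward Euler) scheme solves
`(v_i + ΣΘ_ij) c_i' − Σ Θ_ij c_j' = v_i c_i`, a symmetric positive-definite
sparse system (diagonally dominant with positive diagonal by construction),
with a Jacobi-preconditioned conjugate gradient. The explicit scheme is
`c_i' = (1 − ΣΘ_ij/v_i) c_i + Σ (Θ_ij/v_i) c_j` and refuses to run when
`ΣΘ_ij > v_i` anywhere (it reports the largest admissible `δt`); it exists
to validate the implicit scheme's time step, mirroring the observation that
explicit stepping needs very small steps to avoid negative masses.

**CG tolerance.** The default relative-residual tolerance is 1e-12
(configurable), with at most `10·p` iterations and a Jacobi preconditioner.
The tolerance is deliberately tight: the per-step mass error of the implicit
solve is bounded by the residual, and the conservation suite requires total
carbon constant to 1e-9 *relative* over 1000 alternating steps, which a
looser solve would not guarantee. The implicit scheme also obeys the maximum
principle (an M-matrix property), which the tests assert.

**0D baseline.** `ode0d()` iterates the same reaction update on the
aggregate masses with the total pore volume as the single node volume. With
uniform initial DOM concentration and biomass distributed proportionally to
node volume, the spatialized model is *exactly* the 0D model (diffusion is a
no-op at uniform concentration and the reaction is homogeneous of degree one
in the pools), which the tests verify to solver precision; clustered
placements depart from it — the quantitative motivation for spatializing at
all. The clustered check uses 10 spots on a 200-node synthetic graph, the
same spots-to-nodes flavour as the published 1000-spot scenarios on
~18 500-node samples, at a size that runs in seconds.

## Conductance calibration

The benchmark injects a fixed mass into the regions of the first two
`k`-planes (proportionally to their voxel counts there), runs diffusion-only
dynamics, and compares per-plane mass profiles against a voxel-level
reference: explicit 6-neighbour finite differences on the voxel grid
(per-face exchange `D_c·δt·(c_j − c_i)`, no-flux walls, internal sub-stepping
to keep `D_c·δt ≤ 1/6`). Both solvers discretize the same diffusion
equation, so the voxel solution serves as ground truth at the resolution
limit. The fit score is the Pearson correlation between profiles (invariant
to uniform rescaling; SSE is available as an alternative), maximized over a
conductance grid (default 0.05–1.00 in steps of 0.05).

Two self-checks pin the machinery down. First, a reference generated by the
graph model itself at a planted `α` must be recovered exactly (score 1) —
run through the full skeleton pipeline on a random porous volume. Second, on
a straight tube *sliced into equal slabs* the region model is geometrically
exact: a slab chain of thickness `h` and cross-section `A` has
`Θ = α·D_c·A·δt/h`, identical to the 1D finite-difference coupling at
`α = 1`, so the calibrated graph profile must correlate > 0.99 with the
voxel reference. The slab partition is built with `partition_from_labels()`
rather than from the skeleton, because the skeleton of a straight tube is a
single branch — one region, a constant profile, and an undefined
correlation; the slab chain is the geometry where the benchmark has a sharp
known answer. Whether to score all planes or only the reached subset is
exposed as `plane_range`; all planes is the default.

## Synthetic fixtures

The generators provide shapes whose topology is known in closed form: solid
tubes (`χ = 1`), solid tori (`χ = 0`), Y-junctions (`χ = 1`, three skeleton
endings), a cube with a concentric cubic cavity (`χ = 2`), and correlated
random porous media — seeded white noise smoothed by an isotropic Gaussian
of the requested correlation length and thresholded at the empirical
quantile of the target porosity (achieved porosity within ±1%,
deterministic per seed). The random fields emulate the pore-space fractions
of real samples (17–57%) and produce branching, multi-component pore
systems, but they are *not* grain packings: they have no solid-phase
mechanics, no anisotropy, and their chord-length statistics differ from real
soils. Passing tests on them establishes the correctness of the geometry and
the solvers, not the field realism of any particular soil.

Problem sizes in the shipped suites were chosen to exercise every code path
within a desk-scale run: topology preservation on ten 64³ random volumes,
oracle equivalence on ≤ 16³ volumes (where brute force is exact and cheap),
conservation on a 100-node graph over 1000 steps, scheme convergence on a
50-pore chain with the coarsest step at the explicit stability edge, and
calibration on a radius-4, length-60 tube.

## Known limitations

- Pores are assumed water-filled; partial saturation, water films and
  microbial motility are out of scope.
- A single microbial functional group; no pore-space evolution during the
  dynamics.
- The conductance is a single scalar `α`; per-arc conductances would be more
  precise but require voxel-level fitting per region pair.
- Label TIFF export uses 32-bit float pages (exact for labels < 2²⁴) because
  the TIFF writer has no unsigned-32 integer mode; the raw+JSON export
  round-trips labels exactly.
- Very symmetric shapes admit several valid curve skeletons; the fixed
  deletion order selects one deterministically.
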