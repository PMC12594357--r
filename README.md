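# poreskel

Curve-skeleton pore-network modelling of soil micro-CT images, and graph-based
simulation of the microbial mineralization of soil organic matter.

## The problem

X-ray computed tomography resolves the 3D pore space of soil at micrometre
resolution, but the resulting binary volumes hold tens to hundreds of millions
of voxels, which makes voxel-scale simulation of biological dynamics (e.g. by
the Lattice Boltzmann Method) extremely expensive. Classical pore-network
models replace the pore space with idealized primitives (balls, cylinders,
ellipsoids) and lose 5–20% of the pore voxels at the edges. `poreskel`
implements the alternative: partition the pore space into connected regions
built on the **curve skeleton** (3D medial axis), so that *every* pore voxel
belongs to exactly one region and no connectivity is lost, then run the
biology on the resulting graph — typically 10–20× fewer nodes than a ball
network of the same sample.

The pipeline, for a binary pore volume `S`:

1. **Curve skeleton** — homotopic thinning: a boundary voxel `(i,j,k)` is
   deleted iff it is not an ending point (≥ 2 of its 26 neighbours remain)
   and its removal preserves both the Euler characteristic
   `χ = V − E + F − O` of the cubical complex and the number of 26-connected
   components (simple-point test on the 3×3×3 neighbourhood). Iterated to the
   fixed point, the result is a one-voxel-thick skeleton homotopy-equivalent
   to `S`.
2. **Branches** — skeleton voxels are *ending* (1 neighbour), *simple* (2) or
   *interior* (> 2); a branch is a maximal 26-connected set of simple voxels.
3. **Partition** — every pore voxel joins the branch nearest in Euclidean
   distance (exact feature transform); each nearest-set is split into its
   26-connected components, giving a label image `L` that partitions `S`
   exactly.
4. **Pore graph** — a one-pass scan of `L` over the three positive-direction
   neighbours builds an attributed relational graph: nodes carry inertia
   centre and volume, arcs carry the exact contact-surface area `s_ij` (voxel
   faces) and centre distance `d_ij`. The **global connectivity indicator**
   is `GCI = #arcs / #nodes`.
5. **Biology** — five carbon pools per pore: microbial biomass (MB),
   dissolved (DOM), soil (SOM) and fresh (FOM) organic matter, and CO₂.
   Each time step `δt` applies a reaction update
   (Monod growth `v_DOM·c/(K_DOM+c)·MB·δt` from DOM to MB; mortality
   `μ·MB·δt` split `β` to DOM and `1−β` to SOM; respiration `ρ·MB·δt` to CO₂;
   hydrolysis `v_SOM`, `v_FOM` feeding DOM) followed by DOM diffusion between
   adjacent pores with per-arc exchange volume `Θ_ij = α·D_c·s_ij·δt/d_ij`,
   solved implicitly (conjugate gradient, unconditionally stable) or
   explicitly (used to validate the time step). Total carbon is conserved
   exactly.
6. **Calibration** — the diffusive overall conductance `α` is fitted by
   matching graph-model depth profiles of a plane-injection benchmark against
   a voxel-level finite-difference diffusion reference (Pearson correlation
   over the per-plane mass profiles).

Everything is testable offline: seeded generators provide tubes, tori,
Y-junctions, cavity cubes and correlated random porous media with known
topology.

## Worked example

```r
library(poreskel)

vol <- make_random_porous(c(48, 48, 48), target_porosity = 0.4,
                          correlation_length = 2, seed = 42, resolution = 24)
vol
#> voxel_volume 48x48x48, resolution 24 um, 44237 pore voxels (40.0%)

sk <- curve_skeletonize(vol)                 # homotopic thinning
br <- segment_branches(sk)                   # maximal simple branches
br
#> branch set: 282 branches over 1772 skeleton voxels

pt <- assign_regions(vol, br)                # nearest-branch partition
#> assign_regions: 35 region(s) created by connectivity splitting
g <- build_graph(pt)                         # attributed relational graph
g
#> pore graph: 317 nodes, 863 arcs (GCI 2.72)
```

All 44237 pore voxels are accounted for: the 282 branches seed 317 connected
regions (35 extra regions come from connectivity splitting), and the graph's
GCI of 2.72 summarizes how interconnected this pore network is.

```r
init   <- place_initial_biomass(g, total_mb = 0.18, n_spots = 50,
                                mode = "spots", seed = 1, total_dom = 289.5)
params <- bio_params(dc = dc_voxel_day(6.73e-6, 24), dt = 30)  # ~1.0e5 voxel^2/day
sim    <- simulate_mineralization(g, init, params, duration_days = 0.25)
tail(sim$series[, c("time_days", "MB_pct", "DOM_pct", "SOM_pct", "CO2_pct")], 1)
#>     time_days MB_pct DOM_pct SOM_pct CO2_pct
#> 721      0.25 0.4171 99.5631  0.0105  0.0093
```

After six simulated hours the 50 microbial colonies have more than doubled
(0.06% → 0.42% of total carbon), consuming DOM and beginning to respire CO₂;
the column sums always total 100% (exact carbon conservation).

A command-line front-end is installed at
`system.file("scripts", "poreskel.R", package = "poreskel")` with subcommands
`synth`, `skeletonize`, `partition`, `graph`, `simulate`, `calibrate` and
`pipeline` driven by a YAML/JSON config.

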