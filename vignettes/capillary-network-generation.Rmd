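---
title: "Generating and quantifying synthetic cerebral capillary networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and quantifying synthetic cerebral capillary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
```

## The model

Cerebral capillaries form an interconnected, anastomosing mesh whose job is
to leave no point of the oxygen-consuming tissue further than a
diffusion-limited distance from the nearest vessel. `capnet` builds synthetic
networks from three organizational requirements — isotropy, predominant
three-connectivity, and space-filling coverage with approximately convex
extravascular domains — and then quantifies any vascular spatial graph with a
panel of architectural and functional metrics.

The generator works on a constrained Voronoi tessellation. Space is divided
into cubic cells of side $L_C$ (the *characteristic length*, roughly twice
the maximal inter-capillary distance, 50–100 µm in the cortex) and one seed
point is drawn uniformly in each cell. The bounded 3D Voronoi diagram of
these seeds partitions space into near-monodisperse convex polyhedra whose
volumes are Gaussian-like with mean close to $L_C^3$; the polyhedron edges
are the prospective capillaries. The raw tessellation is however too dense
and too highly connected (Voronoi vertices have degree 4, with many short
edges and sliver faces), so it is pruned:

1. **Face merging.** Faces smaller than `face_area_min` times the median
   face area lose their shortest edge (the face is merged with the
   neighbour across it), and edges at which two faces meet at a dihedral
   angle below `face_angle_min` are deleted. This removes sliver faces and
   sharp branching angles and is the main density control.
2. **Vertex merging.** Vertex pairs closer than
   `vertex_merge_dist`·$L_C$ are merged at their midpoint, removing very
   short capillaries.
3. **Excess-edge deletion.** Edges are deleted, in randomized order, only
   while both endpoints keep at least three connections. Junctions whose
   neighbours are all three-connected may thus stay multiply connected.
4. **Bifurcation enforcement.** Remaining junctions of degree $k>3$ are
   split into chains of three-connected vertices: the two most closely
   aligned incident edges move to a new vertex displaced by
   0.25·`vertex_merge_dist`·$L_C$ along their mean direction.
5. **Margin crop and final check.** Networks are generated on the target
   domain padded by one cell per side and cropped back, which removes
   unbounded cells and boundary artifacts; edges crossing the faces are
   clipped to boundary vertices exactly on the faces. A final close-vertex
   pass (at a quarter of the merge distance) cleans up degenerate
   crop products; the merges it performs are what leaves the small
   percentage of multiply-connected vertices seen in the output.

Degree-2 vertices arising transiently are dissolved into a single straight
edge, and dangling interior chains are removed, keeping the straight-vessel
semantics. All vessels carry a uniform diameter of 5 µm; tortuosity is
deliberately not modelled, and all lengths are straight endpoint distances.

The tessellation itself is computed in compiled code by sequential
half-space clipping of each cell against the bisector planes of its
neighbours (nearest first, stopping once no further bisector can cut the
cell). Tests validate it against independent geometric oracles: exact cube
cells for grid-centred seeds, exact partition of the box volume, and the
equidistance property of Voronoi vertices.

## Parameters and calibration

| parameter | default | meaning |
|---|---|---|
| `lc` | 75 µm | characteristic length; sets the scale of everything |
| `domain` | (240 µm)³ | target box |
| `margin` | 1 cell | generation padding removed by the final crop |
| `face_area_min` | 0.8 | relative face-area threshold of step 1 |
| `face_angle_min` | 20° | minimum inter-face angle of step 1 |
| `vertex_merge_dist` | 0.18 | merge distance, fraction of `lc` |
| `diameter` | 5 µm | uniform vessel diameter |

The three pruning thresholds are not physical observables; they were
calibrated once, on ensembles of ten networks, so that the converged network
statistics take their reference values — mean vessel length $0.49\,L_C$,
9.9 edges per loop, 5.7 loops per edge, and permeability
$0.017\,d^4/L_C^2$ at domain size $(9 L_C)^3$ — and the (240 µm)³, $L_C=75$
µm ensembles simultaneously land on length density ≈ 674 mm⁻², ≈ 10.3 edges
per loop, permeability ≈ 1.4·10⁻³ µm² and post-occlusion flow ratios ≈ 0.76
(converging) and ≈ 0.27 (diverging branch A). They are deliberately left as
configuration knobs. With `lc = 75` µm the generator emulates mouse cortical
capillary beds; `lc = 90` µm is the appropriate human scaling (matched by
length density; one source reports 95 µm in passing, but 90 µm is the value
consistent with the density match and is what this package documents).

`calibrate_lc()` inverts the fitted scaling $\text{density} = c_2/L_C^2$ to
choose $L_C$ for a target length density. For the cubic lattice the closed
form $c_2 = 3$ makes this exact; with `snap = TRUE` the result is rounded to
a whole micrometre, the convention used for the lattice baselines here (it
reproduces a 668 mm⁻² cubic-lattice density and 3.42·10⁻³ µm² permeability
when matched to a 673 mm⁻² anatomical mean).

## Metrics

**Extravascular distances.** `compute_evd()` maps the distance from every
voxel centre to the nearest vessel *surface* (centreline distance minus
radius); vessel-interior voxels are masked. Local maxima use the
26-neighbourhood rule with equal-valued plateaus collapsed to their
centroid. Box counting of the local maxima over grids anchored at the
domain origin (box sizes chosen as integer divisors of the domain so boxes
tile exactly) tests space-filling: the log–log slope reaches −3 at box
sizes of order $L_C$, with continuous slope variation (no fractal regime)
below. The convexity index is the slope of the small-scale log–log
histogram of *centreline* distances (voxel-width bins, at least 1 µm, from
1 µm to the histogram mode): near the wall of a 5 µm tube the level-set
growth scales with centreline distance, and using surface distances there
would saturate the slope near 0.4 for any network, destroying the
healthy-vs-tumour discrimination the index exists for. With uniform
diameters the two distance conventions differ by a constant 2.5 µm.

**Loops.** For every root vertex and every unordered pair of its
neighbours, the length-weighted shortest path avoiding the root (Dijkstra
with the root's edges removed) is closed through the root. Duplicates are
removed by canonical cyclic form. Shortest-path ties are resolved by the
graph library's deterministic search; on length-weighted random geometric
graphs ties have probability zero, but on exact lattices they are common,
which is why lattice loop metrics are reported but not treated as reference
values. The mean loops-per-edge is taken over edges participating in at
least one loop: edges ending in boundary stubs of the cropped region cannot
lie on any cycle and would otherwise dilute the statistic with a
domain-size-dependent zero mass (the all-edge mean is also returned).
Loops are searched in the cropped network only; paths may not leave the
region.

**Flow.** Poiseuille conductance $g = \pi d^4 / (128 \mu \ell)$ per vessel
and mass conservation at junctions give a sparse symmetric system. A
pressure drop is applied between the two domain faces perpendicular to one
axis; all other boundary vertices are sealed. The permeability
$K_x = \mu\,(Q_x/A_x)/(\Delta P_x/L_x)$ is independent of both $\Delta P$
and $\mu$ (tested to 10⁻¹⁰ relative). Components not connected to both
faces are excluded from the solve and carry no flow. Transit times are
$\ell/v$ per vessel with the median reported; velocities scale with the
applied $\Delta P$, which is a free parameter, so they are reported but not
treated as reference values.

**Occlusions.** Each inflow edge of every flowing three-connected junction
is occluded in turn by a hundredfold diameter reduction (conductance
×10⁻⁸, keeping the system nonsingular), the flow re-solved, and the postto
pre-occlusion ratio recorded in the outflow branch(es). Junctions qualify
only if all baseline flows exceed $q_{tol}$ = 0.001 % of the total inflow.
Converging junctions lose one of two inflows (mean ratio ≈ 0.76);
diverging junctions lose their only inflow, the two outflow magnitudes
equalize by mass conservation, branch A keeps its direction and branch B
reverses. Diverging outcomes where both post-occlusion flows drop below
tolerance ("zero-flow", ~14 % of cases) enter the branch-A mean as 0 and
are counted separately; excluding them instead raises the mean from ≈ 0.27
to ≈ 0.31, bracketing the reference 0.29, and the choice is documented
rather than tuned.

**Exchange.** The vessel–tissue mass exchange coefficient $h$ uses a
two-medium volume-averaging closure with a well-mixed vessel phase: solve
$D_t \nabla^2 s = -1$ in tissue with $s = 0$ on the vessel surface and
no-flux domain boundaries, then $h = \varepsilon_t / \langle s \rangle$.
This is exactly linear in the tissue-to-vessel diffusivity ratio, vanishes
when tissue cannot diffuse, grows with interfacial area (hence length
density), and is rotation invariant. Absolute values of $h$ are
convention-dependent (units and normalization of published values are not
fully specified), so only these structural properties are asserted.

## What the generator does and does not emulate

The synthetic ensembles reproduce the space-filling statistics, loop
topology, Darcy permeability and occlusion robustness of cortical capillary
beds at matched length density. They do **not** contain tortuosity,
diameter heterogeneity (and hence no Fåhræus–Lindqvist rheology), arteriolar
or venular trees, capillary-free periarterial zones, or depth-dependent
density gradients. Passing tests therefore demonstrate fidelity of the
*mesh statistics*, not of any property driven by those omitted features;
mean vessel lengths in particular run ~8 % short of anatomical means at
matched density, a known trade-off of calibrating on density.

## Numerical choices

- Ensembles default to 10 networks per condition; convergence studies use
  domain sizes up to $(9 L_C)^3$ (about 5,300 vessels per network), which
  the whole metric panel handles in well under a minute per network.
- Convergence between successive sizes is $|M^k - M^{k-1}|/M^k$ with the
  *current* value in the denominator; a metric is converged once this stays
  below 0.05, and loop metrics converge by $(3$–$4 L_C)^3$ while
  permeability needs $(5.5 L_C)^3$, which sets the representative
  elementary volume. Metrics evaluated on (240 µm)³ = $(3.2 L_C)^3$ regions
  are therefore finite-size biased: permeability runs ≈ 25 % below its
  converged value there, loops per edge ≈ 15 % below.
- Point dedup in the tessellation merges coordinates within $10^{-7} L_C$
  using two offset roundings (no boundary-straddling misses); the
  degenerate exact-centre seed configuration is handled by an epsilon
  guard in the clipping predicate.
- The exchange closure solves its Poisson problem by Jacobi-preconditioned
  conjugate gradients to 10⁻⁸ relative residual.
- RNG: one stream per network, seeded from the configuration; ensembles
  use consecutive seeds, and identical configuration + seed is
  bit-reproducible.

## A short session

```{r example, eval = FALSE}
cfg <- generation_config(lc = 75, domain = c(240, 240, 240), seed = 1)
net <- generate_network(cfg)
summary(net)

morphometry(net, compute_evd(net, voxel = 2))
loop_statistics(find_shortest_loops(net), net)
permeability(net, "x")
occlusion_campaign(net)

write_spatialgraph(net, "s75_001.am")
```

## Known limitations

- The periodic three-connected lattice is a contract baseline (strict
  three-connectivity, period $3L$, cyclic-symmetric, density $10/L_C^2$);
  published foam-inspired variants differ in strut routing, so its
  geometric metrics are not comparable across implementations.
- Lattice loop metrics depend on shortest-path tie-breaking and boundary
  conventions and are excluded from reference comparisons.
- The exchange coefficient's absolute scale is closure-convention
  dependent; compare only ratios or trends across networks computed with
  the same settings.
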