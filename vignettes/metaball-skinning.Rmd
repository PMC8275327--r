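---
title: "Metaball skinning of astrocyte morphologies: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaball skinning of astrocyte morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroskin)
```

## The modelling problem

An astrocyte skeleton is a hybrid object: a tree of point samples with radii
(soma and arbors, SWC-style) plus open triangle patches with per-vertex
thickness (the perivascular endfeet, which have no graph representation).
Simulation-grade geometry requires a single closed 2-manifold surface around
all of it. Sweeping tubes along the skeleton fails exactly where astrocytes
are most complicated — acute branch angles, soma/arbor junctions, endfoot
sheets — producing self-intersections and non-manifold seams.

This package takes the implicit-surface route: every component contributes a
set of *metaballs*, point sources of a scalar field; fields sum, the summed
field is polygonized once, and the blending between components is then
automatic and seamless. Whatever the skeleton topology, the result is a level
set, which cannot self-intersect.

## Field model

Each ball with centre $c$ and influence radius $R$ contributes the Wyvill
soft-object kernel

$$ f(d) = \left(1 - \frac{d^2}{R^2}\right)^3, \quad d < R, $$

and exactly zero beyond $R$. The surface is the iso-contour at
`iso_level = 0.5` of the summed field. For an isolated ball the rendered
radius is

$$ r_s = R\,\sqrt{1 - 0.5^{1/3}} \approx 0.4542\,R, $$

so every constructor converts a morphological (surface) radius $r$ into an
influence radius $r / 0.4542$: rendered tube calibres equal skeleton
calibres. The choice of kernel is a design decision — any smooth, compactly
supported, monotone kernel would do — but compact support is load-bearing:
it makes field evaluation near-linear (each ball touches only the grid nodes
inside its own support) and lets a uniform hash grid over ball centres give
exactly the brute-force field sum, a contract the test suite enforces to
1e-9.

## Resampling (spacing_factor = 1, unitless)

Synthesized arbors are heavily oversampled (the generator emulates this with
0.05 µm sample spacing). Before skinning, each section is thinned by a greedy
arc walk: endpoints are kept verbatim, and an interior sample survives iff it
lies at least `spacing_factor` × (radius of the last kept sample) from that
sample. Kept samples are a *subset* of the originals (no refitting), so the
resampled polyline lies on the original one and the Hausdorff deviation is
bounded by `spacing_factor` × the local radius — below the polygonization
resolution, hence invisible in the mesh. The default factor 1.0 matches the
metaball marching step so no surface detail is lost; the operation is
idempotent, and on the default synthetic astrocyte it removes ~98% of samples
while changing total cable length by well under 2% (measured by
`morphometry_report()`).

## Segment and arbor skinning (step_factor = 1)

A segment between samples $(a, b)$ receives $\lceil L / (s\,r_{\min})
\rceil + 1$ evenly spaced balls ($L$ = segment length, $s$ = `step_factor`,
$r_{\min}$ = smaller endpoint radius), radii interpolated linearly. One ball
per local radius means adjacent influence regions overlap at least twofold,
which is what makes blending seamless; smaller steps only raise ball counts.
Arbors are traversed depth-first and segments concatenated without
deduplication — shared junction samples simply contribute twice, which
thickens joints slightly but keeps the operation order-independent and the
field finite.

## Soma reconstruction

Somata come as origin-plus-radius only, so a 3D profile must be invented.
Two methods:

**Marching (default).** One meta-soma at the somatic sample, plus a marched
segment from the soma to each arbor root with linearly tapering radii.
Guarantees a single partition after blending with the arbors. This is the
default because it is over an order of magnitude cheaper than the hybrid
route and sufficient whenever the soma is not the object of study.

**Hybrid.** Three stages:

1. *Mass-spring relaxation* (`soft_body_params()`: stiffness 0.1, 100 steps,
   damping 0.5, pull_fraction 0.4): an icosphere at the somatic radius is
   integrated by damped gradient descent; vertices within a cap facing each
   arbor root are pulled toward `pull_fraction` of the root distance while
   Hookean edge springs resist. The step size is set from a Lipschitz bound
   of the spring gradient, so spring energy is non-increasing once pulls
   freeze (the last 30% of steps); connectivity is never edited, so the
   surface stays closed and genus 0. This is a deliberately simple stand-in
   for full soft-body engines: only the plausible bulging toward processes
   matters downstream.
2. *Particle remeshing* (`uniform_remesh()`): area-weighted random samples,
   50 iterations of short-range repulsion (radius 2× target spacing, step
   0.25× spacing) with re-projection onto the surface each iteration. The
   contract is the uniformity of the result — nearest-neighbour spacing CV
   ≤ 0.35 (typically ~0.05 on a sphere) — not the particular algorithm.
3. *Displaced meta-patches* (`skin_soma_hybrid()`): one ball per cloud
   vertex with surface radius equal to the polygonization resolution,
   displaced inward along the normal. Overlapping balls inflate the blended
   isosurface well beyond a single ball's surface radius, so displacing by
   $r_s$ alone overshoots the input surface; instead the displacement is
   calibrated by root-finding the blended-field height $h^\*$ of an infinite
   hexagonal ball lattice at the cloud spacing, then shrunk by a 0.05 $r_s$
   margin so the exterior isosurface passes just *outside* the input
   vertices. Polygonized without pruning this yields exactly two nested
   shells; the exterior reproduces the input volume to within ~9% at the
   working resolution (part of that is outward discretization bias of the
   coarse grid, which shrinks under refinement) and encloses every input
   vertex, and `remove_interior_partition()` then verifies nesting by ray
   parity and drops the smaller shell.

The cloud spacing must stay below the global polygonization resolution —
otherwise the patches cannot blend smoothly with the meta-arbors — and the
function refuses to skin clouds that violate this.

## Endfeet (subdivision levels auto, cap 6)

Endfoot patches are tessellated far more coarsely than their thickness, so
one ball per raw vertex would produce disconnected blobs. `required_levels()`
returns the smallest number of midpoint subdivisions after which the longest
edge is at most the smallest per-vertex thickness; each level quadruples the
face count, hence the hard cap at 6. Subdivision is either `simple`
(midpoints only, geometry untouched) or `smooth` (Loop-style weights —
triangle-native smoothing standing in for quad-native schemes — with crease
rules so boundary vertices average only along the boundary and the outline is
not eroded). Thickness is midpoint-interpolated in both modes and therefore
never overshoots its bounds. Thickness is read as a diameter (balls get
radius thickness/2), consistent with diameters elsewhere in the skeleton; a
flag flips this reading if a data source disagrees.

## Polygonization and the resolution rule

The blended field is sampled on an axis-aligned grid. The spacing follows the
smallest radius anywhere in the morphology — including endfeet
half-thickness, since the rule exists precisely to keep the smallest balls
from falling between grid nodes and fragmenting — clamped to a user cap
(default 1 µm, the conventional starting resolution) and a floor (default
0.05 µm, guarding against pathological grids). Grid bounds cover every
ball's support plus two spacings, so the field is provably below the
iso-level on all boundary nodes.

Triangulation is marching tetrahedra on the Freudenthal (Kuhn) 6-tetrahedra
cell decomposition rather than table-based marching cubes: the decomposition
is globally face-consistent and a tetrahedron has no ambiguous sign
configurations, so every interior edge of the output is shared by exactly
two triangles *by construction* — the zero-non-manifold guarantee needs no
per-case disambiguation. The price is roughly double the triangle count,
which the decimation stage absorbs. Field values within 1e-4 of the
iso-level are nudged above it so no crossing lands exactly on a grid node;
this bounds interpolation parameters away from 0/1 and keeps sliver
triangles non-degenerate.

## Mesh post-processing and QC

- `decimate()` is quadric edge collapse with a link-condition check and a
  normal-flip rejection, so closed manifolds stay closed manifolds; boundary
  edges (should any exist) are pinned by constraint quadrics. If the target
  ratio is unreachable without breaking manifoldness it stops early and
  reports the achieved ratio.
- `repair_watertight()` runs: duplicate-vertex merge (1e-6 µm, far below any
  radius floor), degenerate-face removal, fin removal at edges with more
  than two faces, hole filling by boundary-loop triangulation (single
  triangle for 3-loops, centroid fan otherwise, wound against the existing
  boundary direction), coherent-orientation propagation with a global
  outward flip by signed volume, and largest-partition selection. It is
  idempotent on meshes it has repaired and a no-op on clean input.
- `mesh_metrics()` reports partitions, non-manifold edges/vertices, boundary
  edges, self-intersections, area and volume; `watertight` is the
  conjunction of single-partition, closedness, zero non-manifold elements
  and zero self-intersections.
- `detect_self_intersections()` counts penetrating non-adjacent triangle
  pairs with a scale-relative tolerance (~1e-7 of the pair extent):
  contacts that merely graze — unavoidable between near-degenerate
  neighbours on a polygonized level set — are touches, not intersections.
  The spatially indexed path must equal the all-pairs oracle.
- `hausdorff_rms()` samples area-weighted points on both meshes (100k per
  side in the acceptance setting, seeded), measures point-to-surface
  distances each way and normalizes the RMS by the *first* mesh's
  bounding-box diagonal (the Metro convention; swapping arguments changes
  only the normalization).

## The synthetic generator and what it does (not) show

`generate_astrocyte()` fixes the study conditions: 6 arbors, branch order 4,
soma radius 6 µm, radius taper 0.8 per order (continuous along sections, so
the smallest skeleton radius is exactly `6 × 0.8⁴ ≈ 2.46` µm), 0.05 µm
oversampling, and 2 endfeet wrapped 100° around a virtual 4 µm vessel at
arbor tips with thickness uniform in 0.5–1.5 µm. Section base length is 8 µm,
shrinking by 0.85 per order, with a gentle per-step directional wander —
values chosen once as a plausible cortical-astrocyte scale (a few tens of µm
reach, process calibres between soma-scale and sub-µm). Everything is driven
by one seed through an isolated RNG scope; the global RNG state is never
touched.

The generator reproduces the *shape class* that stresses the skinning
machinery — dense oversampling, tapering acute branches, sub-resolution
endfeet — but makes no claim of morphometric fidelity (no space colonization
toward synapses, no microdomain tiling, no vasculature coupling). Passing
tests therefore certify the geometric guarantees of the method (manifoldness,
partition behaviour, decimation fidelity) on astrocyte-like inputs, not
statistical realism of the cells themselves. Real reconstructions also bring
multi-sample somata (unsupported: only single-sample somata are accepted,
matching the origin-and-radius convention of synthetic data) and endfeet
formats other than the JSON sidecar documented in `read_endfeet_sidecar()`.

## Problem sizes and numerical choices

The default acceptance-scale runs polygonize a single astrocyte on a grid of
roughly 300³ nodes at 0.25 µm spacing (~1.4M triangles), decimate it to a
tenth, and compare surfaces with 100k samples per side; one full cycle takes
well under a minute on a single core. The grid is capped at 6×10⁸ nodes, and
polygonization aborts with guidance when no node reaches the iso-level
(resolution coarser than the smallest ball) rather than emitting an empty
mesh. Batch runs fan out per morphology with fork-based workers; each
morphology derives its own seed from the base seed, so results are invariant
to the worker count, and per-morphology failures are isolated in the run
report.

## Known limitations

- Junction balls are duplicated where sections meet, slightly thickening
  branch points; a calibre-exact treatment would deduplicate shared samples
  at the cost of order-dependence.
- Marching tetrahedra over-tessellates relative to marching cubes;
  downstream decimation is assumed.
- The hybrid soma's volume match is calibrated for clouds near the working
  resolution; very coarse grids inherit an outward discretization bias of a
  few percent.
- Genus is not controlled: arbors that brush each other legitimately fuse
  into handles (the field is a sum), which is faithful to the implicit model
  but irreversible afterwards.
- Tetrahedralization is out of scope; the watertight OBJ/PLY/OFF/STL output
  is the hand-off point to TetGen/Quartet/CGAL.
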