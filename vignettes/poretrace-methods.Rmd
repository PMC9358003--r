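---
title: "Channel detection and characterization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel detection and characterization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the geometric model behind `poretrace`, the
numerical choices it makes, and what its synthetic test fixtures do and do
not establish about real structures.

## The model

A molecule is a union of balls, one per atom. The package asks three
questions about the complement of that union: where are its cavities, which
cavity is a channel (an open passage with two or more entrances), and what
is the channel's shape along its axis?

### Weighted Delaunay triangulation and the alpha complex

Because atomic radii differ, the triangulation of the atom centers is the
*regular* (weighted Delaunay) triangulation with weights
$w_i = (r_i + r_p)^2$, where $r_p$ is the probe radius (default 1.4 Å, a
water molecule). Each tetrahedron has an *orthosphere* — the sphere with
equal power distance $\lVert x - c_i \rVert^2 - w_i$ to its four weighted
vertices — and a tetrahedron belongs to the molecule (the alpha complex at
$\alpha = 0$) exactly when its squared orthoradius is non-positive: the
inflated balls cover it. The remaining tetrahedra form the complement:
candidate solvent space.

The triangulation is built incrementally (Bowyer–Watson with the power
in-sphere predicate). Correctness is checked in the test suite against an
independent brute-force oracle that enumerates every 4-subset of points and
keeps those whose orthosphere is empty; on random weighted point sets the
two constructions agree exactly.

Degeneracies (cospherical and coplanar configurations, ubiquitous in
symmetric synthetic fixtures) are broken by a deterministic jitter with
relative amplitude $10^{-8}$ of the bounding-box diagonal. The displacement
directions are drawn from a fixed linear congruential generator seeded by
the atom count and expressed in a coordinate frame anchored on the centroid
and the first two atoms. Making the jitter covariant in this way means a
rotated, translated or uniformly scaled input yields the *same* perturbed
configuration up to that transform, so the triangulation combinatorics —
and everything downstream, including the centerline — are exactly
equivariant under rigid motions and scaling. The amplitude sits far above
double-precision rounding noise and far below any geometric feature of
molecular data.

### Discrete flow and cavity segmentation

Faces of the convex hull are conceptually connected to a point at infinity.
Complement tetrahedra are related by the discrete flow: a tetrahedron flows
into a neighbor when its orthocenter lies strictly beyond their shared
face. `flow_relation()` exposes these arcs.

Two details matter for robust segmentation:

* **Face-level blocking.** Two complement tetrahedra can share a triangle
  that is itself covered by the three inflated balls at its corners (the
  triangle's orthocircle has non-positive squared radius). Such a face
  belongs to the alpha complex and seals the passage even though both
  incident tetrahedra are complement. Without this test, any one-atom-thick
  wall is porous at the tetrahedron level and every enclosed cavity leaks.

* **Bulk layer.** The complement tetrahedra with an open hull face form the
  bulk solvent boundary — the layer the point at infinity flows into.
  Cavities are the remaining complement tetrahedra, grouped by face
  adjacency across open faces. Each component records whether the flow
  descending from infinity reaches it; enclosed voids never are.

A component's *mouths* are the edge-connected clusters of its open faces
into the bulk layer: zero mouths is a void, one a pocket, two or more a
channel. Two clusters touching only at a vertex stay distinct. The channel
is the largest-volume component with at least two mouths (volume ties break
on the smallest leading tetrahedron id); if none has two mouths the largest
cavity is returned with a warning, and a flag disables the mouth filter
entirely.

This reconstruction replaces an escape-to-infinity rule that was tried
first (bulk = tetrahedra whose flow chain exits through a hull face). That
rule fails in practice: the weighted orthocenters of surface sliver
tetrahedra do not reliably point outward, so large parts of the open
exterior were misread as cavity. The bulk-layer definition is coarser but
behaves correctly on every analytic fixture, which is the strongest
validation available without a reference implementation.

Mouth counting is only meaningful when a passage's entrances face the
convex hull. The helical-tube fixture is the documented counterexample: its
tube openings face the concave region between the coil and the hull, so the
component containing its lumen reports a single merged mouth. Its ground
truth therefore carries the closed-form axis geometry, not a cavity class.

### Molecular surface

The triangulated surface is the zero level set of
$f(x) = \min_i(\lVert x - c_i\rVert - r_i)$ — the boundary of the union of
balls at the stored radii — extracted by marching tetrahedra on a regular
grid (default spacing 0.5 Å). Each grid cube is split into five tetrahedra
with a parity-alternating pattern so face diagonals match between
neighboring cubes; vertices are welded on grid edges, which makes the mesh
closed and manifold (every edge borders exactly two triangles — a tested
invariant). Triangles are oriented outward using the local field gradient.
A rolling-probe solvent-excluded surface is *not* reimplemented: an
externally computed SES mesh in OFF or PLY format can be supplied and is
used identically downstream. On the cylindrical test fixture the
union-of-balls surface gives the analytic lumen radius $R - r$, which is
what the radius-recovery checks rely on.

Accuracy is controlled only by the grid spacing; mesh vertices are not
snapped to the analytic surface, which keeps the construction deterministic.
The channel surface is the subset of triangles whose *barycenter* lies
inside some channel tetrahedron (four signed volumes, relative tolerance
$10^{-9}$), with a bounding-box prefilter per tetrahedron standing in for a
spatial index; the test suite checks it against unfiltered brute force.

### Skeleton and pruning

The skeleton is the Delaunay-dual graph of the channel: one node per
channel tetrahedron at its orthocenter (clamped to the barycenter when the
orthocenter falls outside its tetrahedron), edges between face-adjacent
tetrahedra, and a per-node *clearance* — the distance to the nearest
probe-inflated ball. Nodes with non-positive clearance sit inside the
inflated atoms, in wall interstices no probe can occupy, and are dropped by
default; this concentrates the graph on the open lumen, whose well-cleared
core tracks the true axis. A mean-curvature-flow skeleton of the channel
mesh would serve the same role and can be imported from CSV
(`read_skeleton()`); everything downstream is skeleton-source-agnostic.

Pruning selects the core path as the all-pairs shortest path maximizing

$$ s(\gamma) = \frac{\mathrm{length}(\gamma)^2}{\mathrm{tortuousness}(\gamma)}, $$

where tortuousness is the mean distance of the path's nodes from the
straight line through its endpoints. Long straight paths score high; short
or curved paths score low. Three adaptations were necessary for this score
to behave on a dense Delaunay-dual graph (each was adopted after observing
the failure it fixes on the cylinder fixture):

1. **Tortuousness floor.** A chance-collinear two- or three-edge path has
   tortuousness near machine zero and would outscore any physically
   meaningful path by orders of magnitude. `prune_skeleton()` floors the
   tortuousness at half the median edge length — straightness below the
   node spacing is sampling noise. `path_score()` keeps the raw
   $10^{-6}$ Å guard of the score's definition.
2. **Routing metric.** Candidate paths are routed by Dijkstra over the
   clearance-weighted cost $\ell / \bar c^2$ (edge length over squared mean
   node clearance) rather than by edge count: unweighted shortest paths on
   a dense dual graph crawl along walls, where tetrahedra are small and
   plentiful. The edge-count formulation remains available
   (`metric = "hops"`, with lexicographically smallest shortest paths for
   reproducibility).
3. **Length in the score.** The score uses the Euclidean path length, which
   coincides with the edge count up to a constant on uniformly sampled
   curve skeletons but is sampling-independent on the dual graph.

The pruning search is exhaustive over all node pairs; the test suite
verifies it against an independent enumeration built on igraph shortest
paths, and a 2000-node graph prunes in about a second (the search is
$O(v \cdot e + v^2 \cdot d)$ for path reconstruction depth $d$).

### Centerline, Frenet frames and radius profile

The centerline between the pruned path's endpoints is the minimum-cost path
under the same clearance-weighted cost, smoothed and resampled at a uniform
arclength step (default 0.5 Å). Smoothing is a clearance²-weighted moving
average of window 5 followed by a plain pass: within each window the widest
(most medial) nodes dominate, which removes the off-axis bias that plain
averaging leaves when path nodes alternate between wide on-axis and narrow
off-axis tetrahedra (0.9 Å RMS off-axis plain vs. 0.27 Å weighted, on the
cylinder fixture).

Frenet frames come from central finite differences on the
arclength-parametrized points (one-sided at the ends):
$\kappa = \lVert c' \times c'' \rVert / \lVert c' \rVert^3$ and
$\tau = \det(c', c'', c''') / \lVert c' \times c'' \rVert^2$. Where
curvature falls below $10^{-9}$ the normal and binormal are undefined;
frames are flagged and torsion reported as zero. On an analytically sampled
circular helix with radius 5 Å and pitch parameter 2 Å the recovered
curvature and torsion match the closed forms $a/(a^2+b^2)$ and
$b/(a^2+b^2)$ to about 0.01 %.

The local pore radius at a centerline point is its distance to the nearest
channel-surface vertex. Radius profiles re-bin $(z, r)$ samples along the
Cartesian $z$ axis (membrane normal by the usual convention; bin width
1 Å) with per-bin mean, sample standard deviation and count.

### Cross-sections and the visible contour

At each centerline point $p$ with tangent $t_p$, the channel surface is cut
by the orthogonal plane: segment endpoints of triangle–plane intersections,
deduplicated at $10^{-6}$ Å, expressed in a deterministic in-plane basis.
A proximity graph connects points closer than a threshold (default three
times the median nearest-neighbor distance — scale-free in the mesh
resolution). Rays from $p$ (default 360) each select, among the points
within half a ray spacing of their direction, the one closest to $p$; the
union of the selected points' graph components is the *visible contour*,
the part of the section an observer at the centerline actually sees. The
half-ray-spacing angular tolerance is this package's choice. Per section
the package reports closest and farthest visible distances, and for five or
more visible points a direct least-squares ellipse fit (Fitzgibbon's
constrained conic) with eccentricity $e = \sqrt{1 - b^2/a^2}$; a
Hough-transform template fit is out of scope. `section_lobes()` bins the
visible contour's distance-to-anchor function by angle (5° bins), smooths
it circularly, and counts strict local maxima — on the five-lobed fixture
it returns exactly 5.

### Trajectories

Frame one runs the full pipeline. Each later frame reuses the previous
frame's centerline endpoints: they are snapped to the nearest nodes of the
new skeleton within a capture radius (default 5 Å) and pruning is skipped.
The carried endpoints are the unsmoothed skeleton node positions, so on a
static trajectory the snap is exact and warm starts reproduce cold starts
bit-for-bit. If snapping fails, or the new centerline deviates from the
previous one by more than a threshold (default 5 Å, symmetric mean
closest-point distance), the frame is reinitialized with a full pruning
pass. A failed frame is recorded with its reason and the run continues.
Both radii are tunable; neither has a canonical value, and the defaults are
of the order of an atomic diameter above frame-to-frame drift in a typical
nanosecond-spaced MD frame series.

## Synthetic fixtures: what they establish

`make_fixture()` builds walls from overlapping balls (center spacing 1.4
ball radii by default, within the 1.5 bound that keeps probe-inflated walls
watertight) with analytically known geometry:

| kind | truth |
|---|---|
| `cylinder_pore` | channel, 2 mouths, axis = z segment, lumen $R - r$ = 4.5 Å |
| `torus_channel` | channel, 2 mouths (through-hole) |
| `pocket` | open bowl, 1 mouth |
| `sealed_void` | closed shell, 0 mouths |
| `helical_tube` | axis = circular helix, $\kappa = 5/29$, $\tau = 2/29$ Å⁻¹ |
| `pentalobe_tube` | channel with five-fold wall modulation, 5 radial lobes |

Two defaults encode geometric constraints rather than taste: the pentalobe
tube's axis radius is 9 Å because at 6 Å the lobe throats are narrower
than two probe diameters and the alpha complex at the default probe seals
them; and the helical tube defaults to three-quarters of a turn so the coil
cannot stack onto itself (a full turn at pitch parameter 2 Å brings
adjacent coils within probe contact).

These fixtures have single-sphere wall atoms, perfect symmetry (up to the
jitter) and no side chains, disorder, or solvent. Passing them shows the
geometry engine is correct — triangulation, flow, mouth counting, medial
recovery, closed-form differential geometry — not that the biological
interpretation of any particular protein's cavities is settled. On real
structures the bulk/cavity boundary and the mouth decomposition inherit the
convex hull's crudeness for entrances that face concavities, as the helical
fixture demonstrates.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script run fixtures of a few hundred
atoms, meshes of tens of thousands of triangles, random oracle instances of
40 points (exhaustive enumeration is $\binom{40}{4} \approx 9 \times 10^4$
subsets), pruning oracles up to 60 nodes, and scaling probes up to 4000
atoms — sizes chosen so every check reruns from scratch in minutes while
still exercising each code path at a scale where its asymptotics are
visible (the measured triangulation scaling exponent is about 1.0–1.3).
Key tolerances: interior classification absorbs roundoff at
$10^{-9}$ Å² on the squared orthoradius; point-in-tetrahedron tests use a
$10^{-9}$ relative signed-volume tolerance; section points deduplicate at
$10^{-6}$ Å; degenerate tetrahedra are rejected below $10^{-12}$ Å³.

## Known limitations

* The surface is a union-of-balls boundary, not an SES; reentrant probe
  geometry is absent unless an external mesh is supplied. Radii derived
  from it are lower bounds near sharp crevices.
* Mouth counting relies on hull adjacency and undercounts entrances that
  face deep concavities.
* The Delaunay-dual skeleton is noisier than a mean-curvature-flow skeleton
  of the surface; the clearance machinery compensates along tubes but
  branch geometry near wide chambers is approximate.
* Predicates use double precision with deterministic jitter, not exact
  arithmetic; pathological near-degeneracies beyond the jitter scale are
  not guaranteed.
* No alpha filtration over scales: the probe radius fixes one alpha
  complex.
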